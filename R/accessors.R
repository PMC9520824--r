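#' @describeIn ScalarGrid-class Node values array.
#' @param x A ScalarGrid.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @export
setMethod("gridValues", "ScalarGrid", function(x) x@values)

#' @describeIn ScalarGrid-class Grid origin (Angstrom).
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @export
setMethod("gridOrigin", "ScalarGrid", function(x) x@origin)

#' @describeIn ScalarGrid-class Per-axis spacing (Angstrom).
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @export
setMethod("gridSpacing", "ScalarGrid", function(x) x@spacing)

#' @describeIn ScalarGrid-class Node counts per axis.
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @export
setMethod("gridShape", "ScalarGrid", function(x) dim(x@values))

#' @describeIn ScalarGrid-class Logical forbidden-node mask.
#' @export
setGeneric("gridForbidden", function(x) standardGeneric("gridForbidden"))
#' @export
setMethod("gridForbidden", "ScalarGrid", function(x) x@forbidden)

setMethod("show", "ScalarGrid", function(object) {
  d <- dim(object@values)
  fin <- object@values[!object@forbidden]
  cat(sprintf("ScalarGrid %d x %d x %d, spacing (%.3g, %.3g, %.3g) A\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) A; %d forbidden nodes\n",
              object@origin[1], object@origin[2], object@origin[3],
              sum(object@forbidden)))
  if (length(fin))
    cat(sprintf("  allowed values in [%.4g, %.4g]\n", min(fin), max(fin)))
})

#' @describeIn ProteinStructure-class Atom table.
#' @param x A ProteinStructure.
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))
#' @export
setMethod("atomRecords", "ProteinStructure", function(x) x@atoms)

#' @describeIn ProteinStructure-class Number of atoms.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @export
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))

#' Net charge of a structure
#'
#' Sum of per-atom partial charges, optionally rounded to the nearest
#' integer (the convention used when quoting protein net charges in |e|).
#'
#' @param x A [ProteinStructure-class].
#' @param rounded Round to the nearest integer?
#' @return Net charge in |e|.
#' @export
setGeneric("netCharge", function(x, rounded = FALSE) standardGeneric("netCharge"))
#' @export
setMethod("netCharge", "ProteinStructure", function(x, rounded = FALSE) {
  if (nrow(x@atoms) == 0) stop("empty structure: no atoms to sum")
  q <- sum(x@atoms$charge)
  if (rounded) round(q) else q
})

setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf("ProteinStructure: %d atoms, %d residues, net charge %+.3f |e|\n",
              nrow(object@atoms),
              length(unique(paste(object@atoms$chain, object@atoms$resid))),
              if (nrow(object@atoms)) sum(object@atoms$charge) else 0))
})

setMethod("show", "IonicSolvent", function(object) {
  cat(sprintf("IonicSolvent: %d species, I = %.4g mol/L, eps %g/%g, T = %g K\n",
              nrow(object@species), ionicStrength(object),
              object@epsWater, object@epsProtein, object@temperature))
})

setMethod("show", "BeadSpringLigand", function(object) {
  cat(sprintf("BeadSpringLigand: %s\n", paste(object@beadKinds, collapse = "-")))
  cat(sprintf("  l_eq = (%s) A; k = (%s) kJ/(mol A^2)\n",
              paste(signif(object@springEqLengths, 4), collapse = ", "),
              paste(signif(object@springConstants, 4), collapse = ", ")))
  cat(sprintf("  hard core a = %g A (reference T = %g K)\n",
              object@hardCore, object@referenceTemperature))
})

setMethod("show", "SAConfig", function(object) {
  cat(sprintf(
    "SAConfig: T0 = %g K, cooling %g, caps %d/%d, stop < %g%%, |move| <= %d nodes\n",
    object@t0, object@coolingFactor, object@levelMaxMoves,
    object@levelMaxAccepted, 100 * object@stopAcceptance,
    object@maxDisplacement))
})

setMethod("show", "SARunResult", function(object) {
  cat(sprintf(
    "SARunResult: AIE node (%d,%d,%d), final energy %.4f kJ/mol, %d levels (%s)\n",
    object@aieNode[1], object@aieNode[2], object@aieNode[3],
    object@finalEnergy, nrow(object@levels), object@terminatedBy))
})

#' @describeIn SARunResult-class Final total energy, kJ/mol.
#' @param x An SARunResult.
#' @export
setGeneric("finalEnergy", function(x) standardGeneric("finalEnergy"))
#' @export
setMethod("finalEnergy", "SARunResult", function(x) x@finalEnergy)

#' @describeIn SARunResult-class Final `5 x 3` bead node matrix.
#' @export
setGeneric("finalConformation", function(x) standardGeneric("finalConformation"))
#' @export
setMethod("finalConformation", "SARunResult", function(x) x@finalConformation)

#' @describeIn SARunResult-class Fixed AIE node of the run.
#' @export
setGeneric("aieNode", function(x) standardGeneric("aieNode"))
#' @export
setMethod("aieNode", "SARunResult", function(x) x@aieNode)

#' @describeIn SARunResult-class Per-level statistics data.frame.
#' @export
setGeneric("levelStats", function(x) standardGeneric("levelStats"))
#' @export
setMethod("levelStats", "SARunResult", function(x) x@levels)

setMethod("show", "ClusterSummary", function(object) {
  cat(sprintf("ClusterSummary: k = %d, total within-cluster distance %.4g A\n",
              object@k, object@cost))
  for (i in seq_len(object@k)) {
    cat(sprintf("  cluster %d: %d members, medoid (%.2f, %.2f, %.2f)\n",
                i, length(object@members[[i]]),
                object@medoids[i, 1], object@medoids[i, 2],
                object@medoids[i, 3]))
  }
})

setMethod("show", "PlantedInstance", function(object) {
  d <- gridShape(object@gcpGrid)
  cat(sprintf(
    "PlantedInstance: %d x %d x %d grid, %d GCP + %d Lys wells, %d AIE anchors\n",
    d[1], d[2], d[3], nrow(object@minima$gcpNodes),
    nrow(object@minima$lysNodes), nrow(object@aieNodes)))
})
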