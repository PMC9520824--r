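#' @import methods
NULL

#' ScalarGrid: a regular 3-D lattice of scalar values
#'
#' Represents energies (kJ/mol), electrostatic potentials (kJ/mol per |e|)
#' or affinity maps on a regular axis-aligned lattice. Node `(i, j, k)`
#' (1-based in R) is centered at `origin + spacing * (i-1, j-1, k-1)`.
#' Sterically excluded nodes are flagged in the `forbidden` mask and are
#' treated as `+Inf` by all energy lookups.
#'
#' @slot origin Cartesian position of the first node, Angstrom (length 3).
#' @slot spacing Per-axis node separation, Angstrom (length 3, all > 0).
#' @slot values 3-D numeric array of node values.
#' @slot forbidden 3-D logical array, same shape as `values`.
#'
#' @aliases ScalarGrid
#' @exportClass ScalarGrid
setClass("ScalarGrid",
  representation(origin = "numeric", spacing = "numeric",
                 values = "array", forbidden = "array"),
  validity = function(object) {
    msg <- character()
    if (length(object@origin) != 3) msg <- c(msg, "origin must have length 3")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
      msg <- c(msg, "spacing must have length 3 with all components > 0")
    d <- dim(object@values)
    if (length(d) != 3 || any(d < 1))
      msg <- c(msg, "values must be a 3-D array with all extents >= 1")
    if (!identical(dim(object@forbidden), d))
      msg <- c(msg, "forbidden mask must have the same shape as values")
    if (!is.logical(object@forbidden))
      msg <- c(msg, "forbidden mask must be logical")
    if (length(msg)) msg else TRUE
  })

#' Construct a ScalarGrid
#'
#' @param values 3-D numeric array of node values.
#' @param origin Cartesian position of node (1,1,1), Angstrom.
#' @param spacing Per-axis spacing, Angstrom (scalar recycled to 3).
#' @param forbidden Optional logical array; by default nodes whose value is
#'   `>= infSentinel` (or non-finite) are forbidden.
#' @param infSentinel Threshold above which a value marks a forbidden node.
#' @return A [ScalarGrid-class].
#' @examples
#' g <- ScalarGrid(array(0, c(4, 4, 4)), origin = c(0, 0, 0), spacing = 0.4)
#' gridShape(g)
#' @export
ScalarGrid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                       forbidden = NULL, infSentinel = .INF_SENTINEL) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  values <- as.array(values)
  if (is.null(forbidden)) {
    forbidden <- array(!is.finite(values) | values >= infSentinel,
                       dim = dim(values))
  }
  new("ScalarGrid", origin = as.numeric(origin), spacing = as.numeric(spacing),
      values = values, forbidden = forbidden)
}

#' ProteinStructure: atoms with partial charges and van der Waals radii
#'
#' Thin container around a PQR-style atom table (coordinates in Angstrom,
#' charge in |e|, radius in Angstrom).
#'
#' @slot atoms data.frame with columns `record`, `serial`, `name`, `resname`,
#'   `chain`, `resid`, `x`, `y`, `z`, `charge`, `radius`.
#' @slot metadata Free-form list (e.g. a declared symmetry axis for
#'   synthetic two-lobe structures).
#'
#' @aliases ProteinStructure
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(atoms = "data.frame", metadata = "list"),
  validity = function(object) {
    req <- c("record", "serial", "name", "resname", "chain", "resid",
             "x", "y", "z", "charge", "radius")
    msg <- character()
    if (!all(req %in% names(object@atoms)))
      msg <- c(msg, paste("atoms must have columns:", paste(req, collapse = ", ")))
    else {
      if (!all(vapply(object@atoms[c("x", "y", "z", "charge", "radius")],
                      is.numeric, logical(1))))
        msg <- c(msg, "x, y, z, charge, radius must be numeric")
      else if (any(object@atoms$radius < 0))
        msg <- c(msg, "atom radii must be >= 0")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a ProteinStructure
#'
#' @param atoms Atom table; see [ProteinStructure-class] for columns.
#' @param metadata Optional list of annotations.
#' @return A [ProteinStructure-class].
#' @export
ProteinStructure <- function(atoms, metadata = list()) {
  new("ProteinStructure", atoms = as.data.frame(atoms), metadata = metadata)
}

#' IonicSolvent: electrolyte composition and dielectric environment
#'
#' @slot species data.frame with columns `concentration` (mol/L) and
#'   `valence` (signed integer). The species list must be electroneutral.
#' @slot epsWater Relative permittivity of the solvent (default 79).
#' @slot epsProtein Relative permittivity of the protein interior (default 2).
#'   Accepted for interface completeness; the screened-Coulomb potential has
#'   no dielectric boundary and does not use it.
#' @slot temperature Temperature in K (default 300).
#'
#' @aliases IonicSolvent
#' @exportClass IonicSolvent
setClass("IonicSolvent",
  representation(species = "data.frame", epsWater = "numeric",
                 epsProtein = "numeric", temperature = "numeric"),
  validity = function(object) {
    msg <- character()
    s <- object@species
    if (!all(c("concentration", "valence") %in% names(s)))
      msg <- c(msg, "species needs columns concentration, valence")
    else {
      if (any(s$concentration < 0)) msg <- c(msg, "concentrations must be >= 0")
      if (nrow(s) && abs(sum(s$concentration * s$valence)) > 1e-8)
        msg <- c(msg, "species list must be electroneutral")
    }
    if (object@epsWater <= 0 || object@epsProtein <= 0)
      msg <- c(msg, "permittivities must be > 0")
    if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct an IonicSolvent
#'
#' @param species data.frame with `concentration` (mol/L) and `valence`
#'   columns, one row per ionic species. Must be electroneutral.
#' @param epsWater,epsProtein Relative permittivities.
#' @param temperature K.
#' @return An [IonicSolvent-class].
#' @examples
#' # 0.1 M NaCl
#' ionicSolvent(data.frame(concentration = c(0.1, 0.1), valence = c(1, -1)))
#' @export
ionicSolvent <- function(species, epsWater = 79, epsProtein = 2,
                         temperature = 300) {
  new("IonicSolvent", species = as.data.frame(species),
      epsWater = epsWater, epsProtein = epsProtein, temperature = temperature)
}

#' Reference solvent conditions
#'
#' 0.1 mol/L NaCl plus 0.01 mol/L MgCl2 with relative permittivities 79
#' (water) and 2 (protein) at 300 K.
#'
#' @return An [IonicSolvent-class].
#' @export
referenceSolvent <- function() {
  ionicSolvent(data.frame(
    concentration = c(0.1, 0.1, 0.01, 0.02),
    valence = c(1L, -1L, 2L, -1L)))
}

#' Probe: a rigid molecular fragment used to scan a potential grid
#'
#' @slot atoms data.frame with columns `dx`, `dy`, `dz` (offsets from the
#'   probe center, Angstrom), `charge` (|e|) and `radius` (Angstrom).
#' @slot label Fragment name, e.g. "GCP" or "Lys".
#'
#' @aliases Probe
#' @exportClass Probe
setClass("Probe",
  representation(atoms = "data.frame", label = "character"),
  validity = function(object) {
    msg <- character()
    req <- c("dx", "dy", "dz", "charge", "radius")
    if (!all(req %in% names(object@atoms)))
      msg <- c(msg, "probe atoms need columns dx, dy, dz, charge, radius")
    else if (nrow(object@atoms) < 1)
      msg <- c(msg, "probe must have at least one atom")
    else if (!all(is.finite(as.matrix(object@atoms[c("dx", "dy", "dz")]))))
      msg <- c(msg, "probe offsets must be finite")
    if (length(msg)) msg else TRUE
  })

#' Construct a Probe
#'
#' @param offsets `n x 3` matrix of atom offsets from the probe center (A).
#' @param charges Partial charges, |e|.
#' @param radii van der Waals radii, Angstrom.
#' @param label Fragment label.
#' @return A [Probe-class].
#' @export
Probe <- function(offsets, charges, radii = 1.5, label = "probe") {
  if (is.null(dim(offsets))) offsets <- matrix(offsets, ncol = 3, byrow = TRUE)
  n <- nrow(offsets)
  new("Probe",
      atoms = data.frame(dx = offsets[, 1], dy = offsets[, 2],
                         dz = offsets[, 3],
                         charge = rep_len(charges, n),
                         radius = rep_len(radii, n)),
      label = label)
}

#' Build a probe from a structure's atoms
#'
#' Offsets are taken relative to the geometric center of the atoms.
#'
#' @param structure A [ProteinStructure-class] (e.g. a small fragment PQR).
#' @param label Fragment label.
#' @return A [Probe-class].
#' @export
probeFromStructure <- function(structure, label = "probe") {
  a <- structure@atoms
  ctr <- colMeans(a[, c("x", "y", "z")])
  Probe(cbind(a$x - ctr[1], a$y - ctr[2], a$z - ctr[3]),
        a$charge, a$radius, label = label)
}

#' ScanConfig: settings for the rotational rigid-probe scan
#'
#' @slot nRotations Number of probe orientations (default 150).
#' @slot mode How per-rotation energies are combined at each node:
#'   `"boltzmann"` (log-mean-exp at `temperature`) or `"min"`.
#' @slot temperature Reference temperature (K) for the Boltzmann combination.
#' @slot seed RNG seed for the rotation set (NA = use current RNG state).
#'
#' @aliases ScanConfig
#' @exportClass ScanConfig
setClass("ScanConfig",
  representation(nRotations = "integer", mode = "character",
                 temperature = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nRotations < 1) msg <- c(msg, "nRotations must be >= 1")
    if (!object@mode %in% c("boltzmann", "min"))
      msg <- c(msg, "mode must be 'boltzmann' or 'min'")
    if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a ScanConfig
#' @param nRotations Number of rotations (>= 1).
#' @param mode `"boltzmann"` or `"min"`.
#' @param temperature Reference temperature, K.
#' @param seed Rotation seed (NA = current RNG state).
#' @return A [ScanConfig-class].
#' @export
scanConfig <- function(nRotations = 150, mode = c("boltzmann", "min"),
                       temperature = 300, seed = NA_real_) {
  new("ScanConfig", nRotations = as.integer(nRotations),
      mode = match.arg(mode), temperature = temperature,
      seed = as.numeric(seed))
}

#' BeadSpringLigand: five-bead coarse-grained ligand parameters
#'
#' A linear chain GCP-Lys-AIE-Lys-GCP. Consecutive beads are connected by
#' harmonic springs; all non-bonded bead pairs repel as hard spheres of a
#' common contact distance `a`.
#'
#' @slot beadKinds Bead labels along the chain (AIE is the fixed center).
#' @slot springEqLengths Equilibrium lengths of the four springs, Angstrom.
#' @slot springConstants Spring constants, kJ/(mol A^2).
#' @slot hardCore Hard-sphere contact distance `a`, Angstrom.
#' @slot referenceTemperature K; the temperature at which kBT-unit spring
#'   constants were converted to kJ/(mol A^2). The Hamiltonian itself is
#'   temperature-independent.
#'
#' @aliases BeadSpringLigand
#' @exportClass BeadSpringLigand
setClass("BeadSpringLigand",
  representation(beadKinds = "character", springEqLengths = "numeric",
                 springConstants = "numeric", hardCore = "numeric",
                 referenceTemperature = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@beadKinds)
    if (n < 2) msg <- c(msg, "ligand needs at least two beads")
    if (length(object@springEqLengths) != n - 1 ||
        any(object@springEqLengths <= 0))
      msg <- c(msg, "need n-1 positive equilibrium lengths")
    if (length(object@springConstants) != n - 1 ||
        any(object@springConstants <= 0))
      msg <- c(msg, "need n-1 positive spring constants")
    if (object@hardCore <= 0) msg <- c(msg, "hard-core distance must be > 0")
    if (object@referenceTemperature <= 0)
      msg <- c(msg, "reference temperature must be > 0")
    if (length(msg)) msg else TRUE
  })

#' SAConfig: simulated-annealing schedule parameters
#'
#' @slot t0 Starting temperature, K (default 3000).
#' @slot coolingFactor Geometric cooling factor in (0, 1) (default 0.95).
#' @slot levelMaxMoves Proposal cap per temperature level (default 10000).
#' @slot levelMaxAccepted Acceptance cap per level (default 1000).
#' @slot stopAcceptance Run terminates after a level whose acceptance ratio
#'   falls below this fraction (default 0.01).
#' @slot maxDisplacement Maximum bead displacement per axis, in grid lengths
#'   (default 6).
#' @slot maxLevels Safeguard cap on the number of levels (default 200).
#' @slot seed Master RNG seed (NA = use current RNG state).
#'
#' @aliases SAConfig
#' @exportClass SAConfig
setClass("SAConfig",
  representation(t0 = "numeric", coolingFactor = "numeric",
                 levelMaxMoves = "integer", levelMaxAccepted = "integer",
                 stopAcceptance = "numeric", maxDisplacement = "integer",
                 maxLevels = "integer", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@t0 <= 0) msg <- c(msg, "t0 must be > 0")
    if (object@coolingFactor <= 0 || object@coolingFactor >= 1)
      msg <- c(msg, "coolingFactor must be in (0, 1)")
    if (object@levelMaxMoves < 1 || object@levelMaxAccepted < 1 ||
        object@maxLevels < 1 || object@maxDisplacement < 1)
      msg <- c(msg, "caps must be positive")
    if (object@stopAcceptance <= 0 || object@stopAcceptance >= 1)
      msg <- c(msg, "stopAcceptance must be in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Construct an SAConfig
#'
#' Defaults follow the production annealing protocol: start at 3000 K, end a
#' level after 10000 proposals or 1000 acceptances, cool geometrically, stop
#' once a level's acceptance ratio drops below 1%, move a single bead by at
#' most 6 grid lengths per axis.
#'
#' @param t0 Starting temperature, K.
#' @param coolingFactor Geometric cooling factor in (0, 1).
#' @param levelMaxMoves,levelMaxAccepted Per-level caps.
#' @param stopAcceptance Stop threshold on the per-level acceptance ratio.
#' @param maxDisplacement Max per-axis displacement, grid lengths.
#' @param maxLevels Safeguard cap on levels.
#' @param seed RNG seed (NA = current RNG state).
#' @return An [SAConfig-class].
#' @export
saConfig <- function(t0 = 3000, coolingFactor = 0.95, levelMaxMoves = 10000,
                     levelMaxAccepted = 1000, stopAcceptance = 0.01,
                     maxDisplacement = 6, maxLevels = 200, seed = NA_real_) {
  new("SAConfig", t0 = t0, coolingFactor = coolingFactor,
      levelMaxMoves = as.integer(levelMaxMoves),
      levelMaxAccepted = as.integer(levelMaxAccepted),
      stopAcceptance = stopAcceptance,
      maxDisplacement = as.integer(maxDisplacement),
      maxLevels = as.integer(maxLevels), seed = as.numeric(seed))
}

#' SARunResult: outcome of one simulated-annealing run
#'
#' @slot aieNode Grid node (1-based triple) at which the AIE bead was fixed.
#' @slot finalConformation `5 x 3` integer matrix of final bead nodes.
#' @slot finalEnergy Final total energy, kJ/mol (re-evaluated from the
#'   stored conformation).
#' @slot levels data.frame of per-level statistics: `level`, `temperature`,
#'   `proposals`, `acceptances`, `acceptanceRatio`, `bestEnergy` (best
#'   total energy seen up to the end of that level).
#' @slot terminatedBy `"acceptance"` or `"max_levels"`.
#'
#' @aliases SARunResult
#' @exportClass SARunResult
setClass("SARunResult",
  representation(aieNode = "integer", finalConformation = "matrix",
                 finalEnergy = "numeric", levels = "data.frame",
                 terminatedBy = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@aieNode) != 3) msg <- c(msg, "aieNode must be length 3")
    if (!identical(dim(object@finalConformation), c(5L, 3L)))
      msg <- c(msg, "finalConformation must be 5 x 3")
    lv <- object@levels
    if (nrow(lv)) {
      if (any(lv$acceptances > lv$proposals))
        msg <- c(msg, "acceptances must be <= proposals")
    }
    if (length(msg)) msg else TRUE
  })

#' ClusterSummary: k-medoids partition of binding poses
#'
#' @slot medoids `k x 3` matrix of medoid Cartesian positions (Angstrom).
#' @slot assignment Integer cluster id per input position.
#' @slot members List of integer vectors: input indices per cluster.
#' @slot energyMin,energyMedian Per-cluster energy statistics (NA when no
#'   energies were supplied).
#' @slot k Number of clusters.
#' @slot cost Total within-cluster distance (sum over points of the
#'   Euclidean distance to their medoid).
#'
#' @aliases ClusterSummary
#' @exportClass ClusterSummary
setClass("ClusterSummary",
  representation(medoids = "matrix", assignment = "integer",
                 members = "list", energyMin = "numeric",
                 energyMedian = "numeric", k = "integer", cost = "numeric"))

#' PlantedInstance: a synthetic test system with known minima
#'
#' Bundles affinity grids with Gaussian wells planted at ligand-compatible
#' nodes, a steric mask carved by a toy protein, the feasible AIE anchor
#' nodes, and the full placement layer, so the whole search stack can be
#' validated against an exact brute-force oracle.
#'
#' @slot gcpGrid,lysGrid [ScalarGrid-class] affinity grids (kJ/mol).
#' @slot mask [ScalarGrid-class] carrying the steric mask in its forbidden
#'   slot (values 0).
#' @slot minima List with `gcpNodes`, `lysNodes` (node index matrices) and
#'   `gcpDepths`, `lysDepths` (kJ/mol, negative).
#' @slot protein The toy [ProteinStructure-class] that carved the mask.
#' @slot aieNodes Matrix of AIE anchor nodes from which the planted wells
#'   are reachable by the default ligand.
#' @slot layer Matrix of all feasible placement-layer nodes.
#' @slot axis `list(point, direction)` of the C2 axis for mirrored
#'   instances, or empty list.
#'
#' @aliases PlantedInstance
#' @exportClass PlantedInstance
setClass("PlantedInstance",
  representation(gcpGrid = "ScalarGrid", lysGrid = "ScalarGrid",
                 mask = "ScalarGrid", minima = "list",
                 protein = "ProteinStructure", aieNodes = "matrix",
                 layer = "matrix", axis = "list"))
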