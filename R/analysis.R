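# Pull final energies / AIE positions out of a result list.
.finalEnergies <- function(results) {
  vapply(results, function(r) r@finalEnergy, numeric(1))
}

.aiePositions <- function(results, grid) {
  do.call(rbind, lapply(results, function(r)
    nodeToCartesian(grid, r@aieNode)))
}

#' Histogram of final ensemble energies
#'
#' Counts of final total energies over an annealing ensemble; only finite
#' energies enter the histogram, so counts sum to the number of
#' finite-energy runs. Log-scaling (as in the usual presentation of such
#' ensembles) applies to the counts, not the energies.
#'
#' @param results List of [SARunResult-class] (or a numeric energy vector).
#' @param bins Number of bins, or an explicit vector of break points.
#' @param logCounts Also return `log10(counts)`?
#' @return `list(breaks, counts, mids[, logCounts])`.
#' @export
energyHistogram <- function(results, bins = 30, logCounts = FALSE) {
  e <- if (is.numeric(results)) results else .finalEnergies(results)
  e <- e[is.finite(e)]
  if (!length(e)) stop("all final energies are infinite")
  breaks <- if (length(bins) > 1) bins else {
    if (min(e) == max(e)) seq(min(e) - 0.5, max(e) + 0.5, length.out = bins + 1)
    else seq(min(e), max(e), length.out = bins + 1)
  }
  h <- graphics::hist(e, breaks = breaks, right = FALSE,
                      include.lowest = TRUE, plot = FALSE)
  out <- list(breaks = h$breaks, counts = h$counts, mids = h$mids)
  if (logCounts) out$logCounts <- log10(h$counts)
  out
}

#' Lowest-energy runs of an ensemble
#'
#' Runs sorted ascending by final total energy, ties broken by run index
#' (stable sort); returns the first `k`.
#'
#' @param results List of [SARunResult-class].
#' @param k Number of runs to return (`1 <= k <= length(results)`).
#' @return List of the `k` lowest-energy [SARunResult-class] objects.
#' @export
minEnergyConformations <- function(results, k) {
  stopifnot(k >= 1)
  if (k > length(results))
    stop("k exceeds the number of runs (", length(results), ")")
  e <- .finalEnergies(results)
  results[order(e)[seq_len(k)]]
}

#' k-medoids clustering of binding positions
#'
#' Partitions 3-D positions (typically the final AIE-bead positions of the
#' lowest-energy fraction of an ensemble) around medoids (PAM). `k = "auto"`
#' selects `k` in `[2, 10]` by the best average silhouette width.
#'
#' @param positions `n x 3` matrix of Cartesian positions, Angstrom.
#' @param k Cluster count, or `"auto"`.
#' @param energies Optional per-position energies for per-cluster
#'   statistics.
#' @param seed Unused (PAM is deterministic); accepted for interface
#'   stability.
#' @return A [ClusterSummary-class].
#' @export
clusterMedoids <- function(positions, k = "auto", energies = NULL,
                           seed = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (identical(k, "auto")) {
    ks <- 2:min(10, n - 1)
    if (length(ks) == 0 || n < 3)
      stop("need at least 3 positions for automatic k selection")
    sil <- vapply(ks, function(kk)
      cluster::pam(positions, kk, metric = "euclidean")$silinfo$avg.width,
      numeric(1))
    k <- ks[which.max(sil)]
  }
  k <- as.integer(k)
  if (n < k) stop("fewer positions (", n, ") than clusters (", k, ")")
  fit <- cluster::pam(positions, k, metric = "euclidean")
  assignment <- as.integer(fit$clustering)
  medoids <- positions[fit$id.med, , drop = FALSE]
  members <- lapply(seq_len(k), function(i) which(assignment == i))
  cost <- sum(sqrt(rowSums((positions - medoids[assignment, , drop = FALSE])^2)))
  eMin <- eMed <- rep(NA_real_, k)
  if (!is.null(energies)) {
    eMin <- vapply(members, function(m) min(energies[m]), numeric(1))
    eMed <- vapply(members, function(m) stats::median(energies[m]), numeric(1))
  }
  new("ClusterSummary", medoids = medoids, assignment = assignment,
      members = members, energyMin = eMin, energyMedian = eMed,
      k = k, cost = cost)
}

#' Two-fold (C2) symmetry score of a point set
#'
#' Applies a 180-degree rotation about the given axis to all positions and
#' reports the median, over rotated points, of the distance to the nearest
#' original point. A perfectly C2-symmetric set scores 0; a single point at
#' perpendicular distance `r` from the axis scores `2 r`.
#'
#' @param positions `n x 3` matrix of Cartesian positions.
#' @param axisPoint A point on the rotation axis.
#' @param axisDirection Direction of the axis (non-zero).
#' @return Score in Angstrom.
#' @export
c2SymmetryScore <- function(positions, axisPoint, axisDirection) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) >= 1)
  u <- as.numeric(axisDirection)
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("degenerate axis: zero direction vector")
  u <- u / nu
  R <- 2 * tcrossprod(u) - diag(3)   # rotation by pi about u
  centered <- sweep(positions, 2, axisPoint, "-")
  rotated <- sweep(centered %*% t(R), 2, axisPoint, "+")
  d2 <- outer(rowSums(rotated^2), rowSums(positions^2), "+") -
    2 * tcrossprod(rotated, positions)
  stats::median(sqrt(pmax(0, apply(d2, 1, min))))
}

#' Residue contacts of a conformation
#'
#' Residues of the protein having at least one atom strictly within
#' `cutoff` of any bead center, with the closest bead and the minimum
#' distance, sorted by distance.
#'
#' @param conf `5 x 3` conformation (node indices).
#' @param grid Grid geometry used to map nodes to Cartesian positions.
#' @param protein A [ProteinStructure-class].
#' @param cutoff Contact cutoff, Angstrom.
#' @param beadLabels Bead names in chain order.
#' @return data.frame with columns `resname`, `resid`, `chain`, `distance`,
#'   `bead`.
#' @export
contactReport <- function(conf, grid, protein, cutoff = 5,
                          beadLabels = c("GCP1", "Lys1", "AIE", "Lys2",
                                         "GCP2")) {
  beads <- nodeToCartesian(grid, conf)
  a <- protein@atoms
  d2 <- outer(a$x^2 + a$y^2 + a$z^2, rowSums(beads^2), "+") -
    2 * cbind(a$x, a$y, a$z) %*% t(beads)
  d <- sqrt(pmax(d2, 0))                      # atoms x beads
  atomMin <- apply(d, 1, min)
  atomBead <- apply(d, 1, which.min)
  key <- paste(a$chain, a$resid, a$resname, sep = "|")
  res <- data.frame(key = key, dist = atomMin, bead = atomBead,
                    stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(res, res$key), function(g) {
    i <- which.min(g$dist)
    g[i, ]
  }))
  agg <- agg[agg$dist < cutoff, , drop = FALSE]
  if (nrow(agg) == 0)
    return(data.frame(resname = character(), resid = integer(),
                      chain = character(), distance = numeric(),
                      bead = character(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(agg$key, "|", fixed = TRUE))
  out <- data.frame(resname = parts[, 3], resid = as.integer(parts[, 2]),
                    chain = parts[, 1], distance = agg$dist,
                    bead = beadLabels[agg$bead], stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
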