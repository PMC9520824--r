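# Shared in-code fixtures: tiny grids, probes and proteins built on the fly.

zeroGrid <- function(shape = c(7, 7, 7), spacing = 1, origin = NULL) {
  shape <- as.integer(rep_len(shape, 3))
  spacing <- rep_len(spacing, 3)
  if (is.null(origin)) origin <- -spacing * (shape - 1) / 2
  ScalarGrid(array(0, dim = shape), origin = origin, spacing = spacing)
}

valueGrid <- function(values, spacing = 1, origin = NULL) {
  shape <- dim(values)
  spacing <- rep_len(spacing, 3)
  if (is.null(origin)) origin <- -spacing * (shape - 1) / 2
  ScalarGrid(values, origin = origin, spacing = spacing)
}

singleAtomProtein <- function(x = 0, y = 0, z = 0, charge = 1, radius = 2) {
  ProteinStructure(data.frame(
    record = "ATOM", serial = 1L, name = "C", resname = "TOY", chain = "A",
    resid = 1L, x = x, y = y, z = z, charge = charge, radius = radius,
    stringsAsFactors = FALSE))
}

atomsProtein <- function(xyz, charges, radii = 1.5) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  ProteinStructure(data.frame(
    record = "ATOM", serial = seq_len(n), name = "C", resname = "TOY",
    chain = "A", resid = seq_len(n), x = xyz[, 1], y = xyz[, 2],
    z = xyz[, 3], charge = rep_len(charges, n), radius = rep_len(radii, n),
    stringsAsFactors = FALSE))
}

# A wide-open zero-energy world with a small forbidden blob far away, so
# placement layers exist but the ligand moves freely.
openWorld <- function(shape = c(41, 41, 41), spacing = 3) {
  g <- zeroGrid(shape, spacing)
  g
}

# Straight-line conformation at the ligand's equilibrium geometry on a
# 1-A grid centered at the origin of `shape` nodes (along x).
equilibriumConformation <- function(shape = c(81, 5, 5)) {
  grid <- zeroGrid(shape, 1)
  # bead x-offsets 0, 6, 19, 32, 38 from the first bead
  x0 <- (shape[1] - 38) %/% 2 + 1L
  conf <- conformation(rbind(
    c(x0, 3L, 3L), c(x0 + 6L, 3L, 3L), c(x0 + 19L, 3L, 3L),
    c(x0 + 32L, 3L, 3L), c(x0 + 38L, 3L, 3L)))
  list(grid = grid, conf = conf)
}
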