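# Physical constants. Units throughout the package: lengths in Angstrom,
# energies in kJ/mol, charges in proton charges |e|, temperatures in K.
.kB <- 0.008314462618          # Boltzmann/gas constant, kJ/(mol K)
.COULOMB <- 1389.35457644382   # N_A e^2 / (4 pi eps0), kJ A / (mol e^2)
.INF_SENTINEL <- 1e30          # serialized stand-in for +Inf in DX files

#' Thermal energy
#'
#' @param temperature Temperature in K.
#' @return `kB * T` in kJ/mol.
#' @examples
#' thermalEnergy(300)  # ~2.494 kJ/mol
#' @export
thermalEnergy <- function(temperature) .kB * temperature

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL evaluates with the current state.
.withSeed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Coerce node index input to an n x 3 integer matrix (1-based indices).
.asNodeMatrix <- function(idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3, byrow = TRUE)
  storage.mode(idx) <- "integer"
  dimnames(idx) <- NULL
  idx
}

# Accept either a ScalarGrid or a list/vector carrying geometry.
.gridGeometry <- function(x) {
  if (is(x, "ScalarGrid")) {
    list(origin = x@origin, spacing = x@spacing, shape = dim(x@values))
  } else if (is.list(x) && all(c("origin", "spacing", "shape") %in% names(x))) {
    list(origin = as.numeric(x$origin), spacing = as.numeric(x$spacing),
         shape = as.integer(x$shape))
  } else {
    stop("expected a ScalarGrid or a list(origin=, spacing=, shape=)")
  }
}

.sameGeometry <- function(a, b, tol = 1e-9) {
  ga <- .gridGeometry(a); gb <- .gridGeometry(b)
  identical(ga$shape, gb$shape) &&
    all(abs(ga$origin - gb$origin) <= tol) &&
    all(abs(ga$spacing - gb$spacing) <= tol)
}

#' Cartesian centers of grid nodes
#'
#' Node `(i, j, k)` (1-based) maps to `origin + spacing * (i-1, j-1, k-1)`;
#' the origin is the center of the first node.
#'
#' @param grid A [ScalarGrid-class] (or geometry list).
#' @param idx Integer node indices, an `n x 3` matrix or a length-3 vector.
#' @return An `n x 3` numeric matrix of Cartesian coordinates (Angstrom).
#' @export
nodeToCartesian <- function(grid, idx) {
  g <- .gridGeometry(grid)
  idx <- .asNodeMatrix(idx)
  sweep(sweep(idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
}

# Fractional (0-based) grid coordinates of Cartesian points.
.cartesianToFractional <- function(grid, xyz) {
  g <- .gridGeometry(grid)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  sweep(sweep(xyz, 2, g$origin, "-"), 2, g$spacing, "/")
}

# Node indices within grid bounds?
.inBounds <- function(shape, idx) {
  idx <- .asNodeMatrix(idx)
  idx[, 1] >= 1L & idx[, 1] <= shape[1] &
    idx[, 2] >= 1L & idx[, 2] <= shape[2] &
    idx[, 3] >= 1L & idx[, 3] <= shape[3]
}

# Enumerate all node indices of a shape as an n x 3 integer matrix
# (first axis varies fastest, matching R array linear order).
.allNodes <- function(shape) {
  as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                        k = seq_len(shape[3]), KEEP.OUT.ATTRS = FALSE))
}

#' Trilinear interpolation on a scalar grid
#'
#' Interpolates grid values at arbitrary Cartesian points. A point is
#' "blocked" if any interpolation corner with non-zero weight is a forbidden
#' node, or if the point needs support outside the grid.
#'
#' @param grid A [ScalarGrid-class].
#' @param xyz `n x 3` matrix of Cartesian points (Angstrom).
#' @return `list(values = numeric(n), blocked = logical(n))`; blocked points
#'   carry value `Inf`.
#' @export
interpolateGrid <- function(grid, xyz) {
  stopifnot(is(grid, "ScalarGrid"))
  frac <- .cartesianToFractional(grid, xyz)
  shape <- dim(grid@values)
  n <- nrow(frac)
  lo <- floor(frac)
  fr <- frac - lo
  # snap tiny fractional parts so node-centered points use a single corner
  hi <- fr > 1 - 1e-9
  lo[hi] <- lo[hi] + 1
  fr[hi] <- 0
  fr[fr < 1e-9] <- 0
  vals <- numeric(n)
  blocked <- logical(n)
  n1 <- shape[1]; n12 <- shape[1] * shape[2]
  v <- grid@values; fb <- grid@forbidden
  for (corner in 0:7) {
    ci <- bitwAnd(corner, 1L)
    cj <- bitwAnd(bitwShiftR(corner, 1L), 1L)
    ck <- bitwShiftR(corner, 2L)
    w <- (if (ci) fr[, 1] else 1 - fr[, 1]) *
         (if (cj) fr[, 2] else 1 - fr[, 2]) *
         (if (ck) fr[, 3] else 1 - fr[, 3])
    ii <- lo[, 1] + ci; jj <- lo[, 2] + cj; kk <- lo[, 3] + ck
    inb <- ii >= 0 & ii < shape[1] & jj >= 0 & jj < shape[2] &
           kk >= 0 & kk < shape[3]
    need <- w > 0
    blocked <- blocked | (need & !inb)
    use <- need & inb
    if (any(use)) {
      lin <- 1 + ii[use] + jj[use] * n1 + kk[use] * n12
      blocked[use] <- blocked[use] | fb[lin]
      vals[use] <- vals[use] + w[use] * v[lin]
    }
  }
  vals[blocked] <- Inf
  list(values = vals, blocked = blocked)
}
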