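#' Read an OpenDX scalar grid
#'
#' Parses the APBS dialect of the OpenDX format
#' (`gridpositions`/`gridconnections`/`array ... data follows`). Data values
#' follow the DX convention: the last (z) axis varies fastest. Nodes whose
#' value is at or above `infSentinel` are flagged forbidden.
#'
#' @param path Path to a DX file.
#' @param infSentinel Values `>= infSentinel` mark forbidden nodes.
#' @return A [ScalarGrid-class].
#' @seealso [writeDX()]
#' @export
readDX <- function(path, infSentinel = .INF_SENTINEL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  strip <- trimws(lines)
  keep <- !startsWith(strip, "#") & nzchar(strip)
  idx <- which(keep)

  .numTail <- function(line, lineNo, n, what) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[(length(toks) - n + 1):length(toks)]))
    if (length(vals) != n || any(is.na(vals)))
      stop(sprintf("malformed DX header (%s) at line %d: '%s'",
                   what, lineNo, line))
    vals
  }

  posLine <- idx[grepl("class gridpositions counts", strip[idx])][1]
  if (is.na(posLine)) stop("malformed DX header: no 'gridpositions counts' object")
  shape <- as.integer(.numTail(lines[posLine], posLine, 3, "counts"))
  if (any(shape < 1)) stop("malformed DX header: counts must be >= 1")

  originLine <- idx[startsWith(strip[idx], "origin")][1]
  if (is.na(originLine)) stop("malformed DX header: no 'origin' line")
  origin <- .numTail(lines[originLine], originLine, 3, "origin")

  deltaLines <- idx[startsWith(strip[idx], "delta")]
  if (length(deltaLines) != 3)
    stop("malformed DX header: expected 3 'delta' lines, found ",
         length(deltaLines))
  deltas <- t(vapply(deltaLines, function(i) .numTail(lines[i], i, 3, "delta"),
                     numeric(3)))
  if (any(abs(deltas - diag(diag(deltas))) > 1e-12))
    stop("malformed DX header: non-axis-aligned delta rows at line ",
         deltaLines[1])
  spacing <- diag(deltas)
  if (any(spacing <= 0)) stop("malformed DX header: non-positive delta")

  dataLine <- idx[grepl("data follows", strip[idx])][1]
  if (is.na(dataLine)) stop("malformed DX header: no 'data follows' object")
  nExpected <- prod(shape)

  dataEnd <- length(lines)
  trailer <- which(seq_along(strip) > dataLine &
                   (startsWith(strip, "attribute") |
                    startsWith(strip, "component") |
                    startsWith(strip, "object")))
  if (length(trailer)) dataEnd <- min(trailer) - 1
  dataToks <- unlist(strsplit(trimws(lines[(dataLine + 1):dataEnd]), "\\s+"),
                     use.names = FALSE)
  dataToks <- dataToks[nzchar(dataToks)]
  vals <- suppressWarnings(as.numeric(dataToks))
  if (anyNA(vals))
    stop("non-numeric data value in DX body: '",
         dataToks[which(is.na(vals))[1]], "'")
  if (length(vals) != nExpected)
    stop(sprintf("DX size mismatch: header promises %d values, found %d",
                 nExpected, length(vals)))

  # DX order is z-fastest; R arrays are x-fastest (column-major).
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  ScalarGrid(arr, origin = origin, spacing = spacing,
             infSentinel = infSentinel)
}

#' Write an OpenDX scalar grid
#'
#' Emits the APBS dialect accepted by [readDX()] and standard DX consumers.
#' Forbidden nodes are serialized as `infSentinel` (DX has no mask channel).
#'
#' @param grid A [ScalarGrid-class].
#' @param path Output path.
#' @param infSentinel Value written at forbidden nodes.
#' @return Invisibly, `path`.
#' @export
writeDX <- function(grid, path, infSentinel = .INF_SENTINEL) {
  stopifnot(is(grid, "ScalarGrid"))
  shape <- dim(grid@values)
  if (any(shape < 1)) stop("grid has an empty shape")
  vals <- grid@values
  vals[grid@forbidden] <- infSentinel
  vals[!is.finite(vals)] <- infSentinel
  flat <- as.vector(aperm(vals, c(3, 2, 1)))  # z fastest

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid written by annealbind",
    sprintf("object 1 class gridpositions counts %d %d %d",
            shape[1], shape[2], shape[3]),
    sprintf("origin %.12g %.12g %.12g",
            grid@origin[1], grid@origin[2], grid@origin[3]),
    sprintf("delta %.12g 0 0", grid@spacing[1]),
    sprintf("delta 0 %.12g 0", grid@spacing[2]),
    sprintf("delta 0 0 %.12g", grid@spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            shape[1], shape[2], shape[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(flat))), con)
  n <- length(flat)
  nFull <- n %/% 3L
  body <- character(0)
  if (nFull > 0) {
    m <- matrix(flat[seq_len(3L * nFull)], nrow = 3)
    body <- sprintf("%.10g %.10g %.10g", m[1, ], m[2, ], m[3, ])
  }
  if (n %% 3L != 0) {
    rest <- flat[(3L * nFull + 1L):n]
    body <- c(body, paste(sprintf("%.10g", rest), collapse = " "))
  }
  writeLines(body, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
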