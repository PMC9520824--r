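#' Read a PQR structure
#'
#' Accepts both whitespace-tokenized and fixed-column PQR dialects
#' (PDB2PQR versions differ), detecting the dialect per record. Only
#' `ATOM`/`HETATM` records are parsed.
#'
#' @param path Path to a PQR file.
#' @return A [ProteinStructure-class].
#' @export
readPQR <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- which(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))
  if (!length(recs)) stop("empty structure: no ATOM/HETATM records in ", path)

  parseOne <- function(line, lineNo) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    out <- NULL
    if (length(toks) %in% c(10L, 11L)) {
      hasChain <- length(toks) == 11L
      num <- suppressWarnings(as.numeric(toks[(length(toks) - 5):length(toks)]))
      serial <- suppressWarnings(as.integer(toks[2]))
      if (!anyNA(num) && !is.na(serial)) {
        out <- list(record = toks[1], serial = serial, name = toks[3],
                    resname = toks[4],
                    chain = if (hasChain) toks[5] else "",
                    resid = as.integer(num[1]),
                    x = num[2], y = num[3], z = num[4],
                    charge = num[5], radius = num[6])
      }
    }
    if (is.null(out)) {
      # fixed-column (PDB-like) fallback: coordinates at 31-54, then
      # whitespace-separated charge and radius
      wide <- formatC(line, width = 54, flag = "-")
      num <- suppressWarnings(c(
        as.integer(substr(wide, 7, 11)),
        as.integer(substr(wide, 23, 26)),
        as.numeric(substr(wide, 31, 38)),
        as.numeric(substr(wide, 39, 46)),
        as.numeric(substr(wide, 47, 54))))
      tail2 <- strsplit(trimws(substr(line, 55, nchar(line))), "\\s+")[[1]]
      qr <- suppressWarnings(as.numeric(tail2))
      if (anyNA(num) || length(qr) < 2 || anyNA(qr[1:2]))
        stop(sprintf("cannot parse PQR record at line %d: '%s'", lineNo, line))
      out <- list(record = trimws(substr(line, 1, 6)), serial = num[1],
                  name = trimws(substr(wide, 13, 16)),
                  resname = trimws(substr(wide, 18, 21)),
                  chain = trimws(substr(wide, 22, 22)),
                  resid = num[2], x = num[3], y = num[4], z = num[5],
                  charge = qr[1], radius = qr[2])
    }
    out
  }

  parsed <- lapply(seq_along(recs),
                   function(i) parseOne(lines[recs[i]], recs[i]))
  atoms <- do.call(rbind, lapply(parsed, function(p)
    data.frame(p, stringsAsFactors = FALSE)))
  ProteinStructure(atoms)
}

#' Write a PQR structure
#'
#' Emits whitespace-separated PQR records re-readable by [readPQR()].
#'
#' @param structure A [ProteinStructure-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePQR <- function(structure, path) {
  stopifnot(is(structure, "ProteinStructure"))
  a <- structure@atoms
  hasChain <- any(nzchar(a$chain))
  lines <- vapply(seq_len(nrow(a)), function(i) {
    if (hasChain) {
      sprintf("%-6s %4d %-4s %-4s %1s %4d %11.6f %11.6f %11.6f %8.4f %7.4f",
              a$record[i], a$serial[i], a$name[i], a$resname[i],
              ifelse(nzchar(a$chain[i]), a$chain[i], "A"), a$resid[i],
              a$x[i], a$y[i], a$z[i], a$charge[i], a$radius[i])
    } else {
      sprintf("%-6s %4d %-4s %-4s %4d %11.6f %11.6f %11.6f %8.4f %7.4f",
              a$record[i], a$serial[i], a$name[i], a$resname[i], a$resid[i],
              a$x[i], a$y[i], a$z[i], a$charge[i], a$radius[i])
    }
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Concatenate structures
#'
#' @param ... [ProteinStructure-class] objects.
#' @return A single [ProteinStructure-class]; net charge is additive over
#'   concatenation.
#' @export
combineStructures <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, is, logical(1), "ProteinStructure")))
  ProteinStructure(do.call(rbind, lapply(parts, function(p) p@atoms)))
}
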