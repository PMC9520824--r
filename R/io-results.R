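#' Export simulated-annealing run results
#'
#' Writes a CSV table (one row per run: run id, AIE node, final bead nodes,
#' final total energy, level count, termination reason) and/or a JSON file
#' with the full per-level statistics.
#'
#' @param results List of [SARunResult-class] objects.
#' @param csvPath,jsonPath Output paths; either may be `NULL` to skip.
#' @return Invisibly, the run table as a data.frame.
#' @export
writeRunResults <- function(results, csvPath = NULL, jsonPath = NULL) {
  stopifnot(length(results) > 0,
            all(vapply(results, is, logical(1), "SARunResult")))
  beadCols <- paste0("bead_",
                     as.vector(t(outer(c("gcp1", "lys1", "aie", "lys2",
                                         "gcp2"),
                                       c("i", "j", "k"), paste, sep = "_"))))
  tab <- do.call(rbind, lapply(seq_along(results), function(r) {
    x <- results[[r]]
    row <- data.frame(run = r, aie_i = x@aieNode[1], aie_j = x@aieNode[2],
                      aie_k = x@aieNode[3])
    beads <- as.vector(t(x@finalConformation))
    row[beadCols] <- as.list(beads)
    row$final_energy <- x@finalEnergy
    row$n_levels <- nrow(x@levels)
    row$terminated_by <- x@terminatedBy
    row
  }))
  if (!is.null(csvPath)) utils::write.csv(tab, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    full <- lapply(seq_along(results), function(r) {
      x <- results[[r]]
      list(run = r, aie_node = as.integer(x@aieNode),
           final_conformation = x@finalConformation,
           final_energy = x@finalEnergy,
           terminated_by = x@terminatedBy,
           levels = x@levels)
    })
    jsonlite::write_json(full, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(tab)
}

#' Read a run-results CSV
#'
#' Rebuilds [SARunResult-class] objects from a table written by
#' [writeRunResults()]. Per-level statistics are not stored in the CSV, so
#' the `levels` slot of the rebuilt objects is empty.
#'
#' @param csvPath Path to the CSV file.
#' @return List of [SARunResult-class] objects.
#' @export
readRunResults <- function(csvPath) {
  tab <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
  beadCols <- grep("^bead_", names(tab), value = TRUE)
  lapply(seq_len(nrow(tab)), function(r) {
    conf <- matrix(as.integer(unlist(tab[r, beadCols])), nrow = 5,
                   byrow = TRUE)
    new("SARunResult",
        aieNode = as.integer(unlist(tab[r, c("aie_i", "aie_j", "aie_k")])),
        finalConformation = conf,
        finalEnergy = tab$final_energy[r],
        levels = data.frame(),
        terminatedBy = tab$terminated_by[r])
  })
}
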