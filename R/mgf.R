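#' Export MS/MS events to a Mascot Generic Format file
#'
#' One `BEGIN IONS`/`END IONS` block per MS/MS event, carrying the
#' precursor m/z and charge, retention time (s), the mobility position
#' as an `ION_MOBILITY` header, and the centroid list.
#'
#' @param acq an `acquisition` (events + spectra).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(acq, path) {
  ev <- acq$events
  sp <- split(acq$spectra, acq$spectra$event_id)
  con <- file(path, "w")
  on.exit(close(con))
  pol <- if (acq$config$polarity == "positive") "+" else "-"
  for (i in seq_len(nrow(ev))) {
    s <- sp[[as.character(ev$event_id[i])]]
    if (is.null(s) || nrow(s) == 0) next
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=event=", ev$event_id[i], " cycle=", ev$cycle[i],
             " ramp=", ev$ramp[i]),
      paste0("PEPMASS=", format(ev$mono_mz[i], digits = 10)),
      paste0("CHARGE=", ev$z[i], pol),
      paste0("RTINSECONDS=", format(ev$time_s[i], digits = 8)),
      paste0("ION_MOBILITY=", format(ev$ook0[i], digits = 8)),
      paste(format(s$mz, digits = 10), format(s$intensity, digits = 8))
    ), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Write / read the tabular artifacts of a run
#'
#' Plain TSV writers for ground truth, features, acquisition log,
#' annotations and libraries, with `NA`-safe round-tripping.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
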