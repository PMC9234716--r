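#' Write and read paired current traces
#'
#' Paired recordings are stored as one long tab-separated table
#' (`recording_id`, `which` in {a, b}, `time_s`, `current_uA`) plus a JSON
#' sidecar holding the application windows and any protocol metadata, so the
#' raw traces stay in a plain-text, tool-agnostic format.
#'
#' @param pairs List of recordings as produced by
#'   [simulate_potency_ratio_traces()] or [simulate_enhancement_traces()].
#' @param path Output path without extension; `.tsv` and `.json` are written.
#' @param metadata Optional named list merged into the sidecar.
#' @return Invisibly, the two paths.
#' @export
write_paired_traces <- function(pairs, path, metadata = list()) {
  rows <- lapply(pairs, function(p) {
    rbind(
      data.frame(recording_id = p$recording_id, which = "a",
                 time_s = p$trace_a$time, current_uA = p$trace_a$current),
      data.frame(recording_id = p$recording_id, which = "b",
                 time_s = p$trace_b$time, current_uA = p$trace_b$current)
    )
  })
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(do.call(rbind, rows), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- c(list(
    window = list(start = pairs[[1]]$trace_a$windows$start[1],
                  end = pairs[[1]]$trace_a$windows$end[1]),
    sign_convention = "inward currents negative; statistics on magnitudes"
  ), metadata)
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}

#' @rdname write_paired_traces
#' @return `read_paired_traces` returns a list of recordings with elements
#'   `recording_id`, `trace_a`, `trace_b`.
#' @export
read_paired_traces <- function(path) {
  df <- utils::read.delim(paste0(path, ".tsv"), stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  win <- data.frame(start = side$window$start, end = side$window$end)
  lapply(split(df, df$recording_id), function(d) {
    mk <- function(w) {
      dd <- d[d$which == w, , drop = FALSE]
      structure(list(time = dd$time_s, current = dd$current_uA, windows = win),
                class = "current_trace")
    }
    list(recording_id = d$recording_id[1], trace_a = mk("a"), trace_b = mk("b"))
  })
}
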