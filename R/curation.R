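#' Length-window filter for channel sequences
#'
#' Removes sequences whose gap-stripped length falls outside the window used
#' when assembling DEG/ENaC superfamily alignments: anything shorter than
#' `min_length` or longer than `max_length` residues is dropped (bounds
#' inclusive, so a 300 aa or a 1000 aa sequence survives). Lengths are always
#' computed after removing gap characters, so the same filter applies to
#' aligned and unaligned input.
#'
#' @param seqs Named character vector of sequences (gapped or not).
#' @param min_length Minimum ungapped length kept (default 300).
#' @param max_length Maximum ungapped length kept (default 1000).
#' @return List with `kept` and `removed` (named character vectors preserving
#'   input order) and `report`, a data frame of id, ungapped length and fate.
#' @examples
#' seqs <- c(a = strrep("A", 299), b = strrep("A", 300))
#' filter_by_length(seqs)$report
#' @export
filter_by_length <- function(seqs, min_length = 300, max_length = 1000) {
  if (length(seqs) == 0L) stop("no sequences supplied", call. = FALSE)
  assert_scalar(min_length, "min_length", positive = TRUE)
  assert_scalar(max_length, "max_length", positive = TRUE)
  if (min_length > max_length) stop("min_length must be <= max_length", call. = FALSE)
  len <- nchar(gsub("-", "", seqs, fixed = TRUE))
  keep <- len >= min_length & len <= max_length
  list(
    kept = seqs[keep],
    removed = seqs[!keep],
    report = data.frame(
      id = names(seqs),
      length = unname(len),
      kept = unname(keep),
      reason = ifelse(keep, "", ifelse(len < min_length, "too_short", "too_long")),
      stringsAsFactors = FALSE
    )
  )
}

#' Pairwise identity between two aligned sequences
#'
#' Fraction of matching positions over the columns where neither sequence has
#' a gap. Columns where either member is gapped contribute to neither the
#' numerator nor the denominator — the convention used when screening aligned
#' sets for redundancy. Inputs must be pre-aligned (equal length).
#'
#' @param a,b Aligned sequences (single strings of equal length).
#' @return Identity in `[0, 1]`.
#' @examples
#' pairwise_identity("ACDE", "ACDF")  # 0.75
#' pairwise_identity("AC-E", "ACDE")  # 1.0: 3 comparable columns, 3 matches
#' @export
pairwise_identity <- function(a, b) {
  a <- unlist(strsplit(as.character(a), "", fixed = TRUE))
  b <- unlist(strsplit(as.character(b), "", fixed = TRUE))
  if (length(a) != length(b)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  comparable <- a != "-" & b != "-"
  if (!any(comparable)) {
    stop("no comparable (mutually ungapped) columns", call. = FALSE)
  }
  sum(a[comparable] == b[comparable]) / sum(comparable)
}

#' Collapse redundant aligned sequences
#'
#' Greedy sweep in input order: each sequence is kept unless its identity to
#' an already-kept sequence strictly exceeds `identity_threshold` (the
#' redundancy rule is ">90% identical", so a pair at exactly the threshold is
#' retained). Deterministic given input order; after the sweep no kept pair
#' exceeds the threshold.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param identity_threshold Identity above which a sequence is considered
#'   redundant (default 0.90, strict).
#' @return List with `kept`, `removed` and `mapping` (data frame
#'   removed_id, kept_id, identity).
#' @export
collapse_redundant <- function(seqs, identity_threshold = 0.90) {
  if (length(seqs) == 0L) stop("no sequences supplied", call. = FALSE)
  assert_scalar(identity_threshold, "identity_threshold")
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must lie in (0, 1]", call. = FALSE)
  }
  ids <- names(seqs)
  kept_idx <- integer(0)
  removed_idx <- integer(0)
  map <- list()
  for (i in seq_along(seqs)) {
    absorbed <- FALSE
    for (j in kept_idx) {
      idy <- pairwise_identity(seqs[[j]], seqs[[i]])
      if (idy > identity_threshold) {
        map[[length(map) + 1L]] <- data.frame(
          removed_id = ids[i], kept_id = ids[j], identity = idy,
          stringsAsFactors = FALSE
        )
        absorbed <- TRUE
        break
      }
    }
    if (absorbed) removed_idx <- c(removed_idx, i) else kept_idx <- c(kept_idx, i)
  }
  list(
    kept = seqs[kept_idx],
    removed = seqs[removed_idx],
    mapping = if (length(map)) do.call(rbind, map) else
      data.frame(removed_id = character(0), kept_id = character(0),
                 identity = numeric(0), stringsAsFactors = FALSE)
  )
}

#' Drop gap-rich alignment columns
#'
#' Optional, clearly approximate stand-in for the manual removal of
#' poor-aligning segments: columns where more than `max_gap_frac` of rows are
#' gapped are dropped. This is a coarse occupancy mask, not a reproduction of
#' any curator's judgement.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param max_gap_frac Maximum tolerated gap fraction per column (default 0.5).
#' @return Named character vector of masked sequences; the surviving column
#'   indices are attached as attribute `"columns"`.
#' @export
mask_sparse_columns <- function(seqs, max_gap_frac = 0.5) {
  assert_proportion(max_gap_frac, "max_gap_frac")
  m <- aln_matrix(seqs)
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= max_gap_frac)
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  structure(stats::setNames(out, names(seqs)), columns = keep)
}

#' Full curation sweep: length window then redundancy collapse
#'
#' @inheritParams filter_by_length
#' @inheritParams collapse_redundant
#' @return List with `kept`, `removed`, and `report` (id, action, detail).
#' @export
curate_sequences <- function(seqs, min_length = 300, max_length = 1000,
                             identity_threshold = 0.90) {
  len <- filter_by_length(seqs, min_length, max_length)
  red <- collapse_redundant(len$kept, identity_threshold)
  report <- rbind(
    if (length(len$removed)) data.frame(
      id = names(len$removed),
      action = "removed",
      detail = len$report$reason[!len$report$kept],
      stringsAsFactors = FALSE
    ),
    if (nrow(red$mapping)) data.frame(
      id = red$mapping$removed_id,
      action = "removed",
      detail = paste0("redundant_with:", red$mapping$kept_id),
      stringsAsFactors = FALSE
    ),
    data.frame(
      id = names(red$kept), action = "kept", detail = "",
      stringsAsFactors = FALSE
    )
  )
  list(kept = red$kept, removed = c(len$removed, red$removed), report = report)
}
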