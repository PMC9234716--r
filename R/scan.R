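#' Scan configuration
#'
#' Thresholds operationalizing "reasonably conserved in the foreground clade
#' but divergent in the background". The thresholds are deliberately exposed:
#' the underlying biological rule is informal and different corpora may need
#' different stringency.
#'
#' @param reference_id Id of the alignment row used for residue numbering
#'   (counted from the initiator methionine of the full-length sequence).
#' @param fg_conservation_min Minimum foreground conservation (default 0.90).
#' @param bg_match_max Maximum fraction of background residues matching the
#'   foreground consensus (default 0.20).
#' @param mode `"identity"`, `"class"`, or `"either"` (default): in `either`
#'   mode a column passes if it passes the identity rule or the
#'   physicochemical-class rule.
#' @param fg_gap_max Maximum foreground gap fraction per column (default 0.5).
#' @param region_of_interest Optional two-column matrix or list of
#'   `c(start, end)` reference-position ranges restricting the scan (e.g. the
#'   extracellular and upper transmembrane domains).
#' @return A `scan_config` list.
#' @export
scan_config <- function(reference_id,
                        fg_conservation_min = 0.90,
                        bg_match_max = 0.20,
                        mode = c("either", "identity", "class"),
                        fg_gap_max = 0.50,
                        region_of_interest = NULL) {
  mode <- match.arg(mode)
  assert_proportion(fg_conservation_min, "fg_conservation_min")
  assert_proportion(bg_match_max, "bg_match_max")
  assert_proportion(fg_gap_max, "fg_gap_max")
  if (!is.null(region_of_interest)) {
    region_of_interest <- do.call(rbind, lapply(region_of_interest, function(r) {
      stopifnot(length(r) == 2L, r[1] <= r[2])
      as.numeric(r)
    }))
  }
  structure(
    list(reference_id = reference_id,
         fg_conservation_min = fg_conservation_min,
         bg_match_max = bg_match_max,
         mode = mode,
         fg_gap_max = fg_gap_max,
         region_of_interest = region_of_interest),
    class = "scan_config"
  )
}

#' Per-column conservation within one clade
#'
#' Consensus and conservation score of one alignment column restricted to the
#' rows carrying `label`. Gaps are excluded from both numerator and
#' denominator; the ambiguity character `X` stays in the denominator but never
#' forms a consensus. In identity mode the consensus is the modal residue; in
#' class mode it is the modal physicochemical class.
#'
#' @param alignment A [clade_alignment()].
#' @param column 1-based alignment column.
#' @param label `"foreground"` or `"background"`.
#' @param mode `"identity"` or `"class"`.
#' @param scheme Physicochemical scheme, see [physchem_scheme()].
#' @return List with `consensus` (residue or class label), `score`
#'   (modal count / ungapped count) and `n_ungapped`.
#' @export
column_conservation <- function(alignment, column, label,
                                mode = c("identity", "class"),
                                scheme = physchem_scheme()) {
  mode <- match.arg(mode)
  m <- aln_matrix(alignment$seqs)
  if (column < 1L || column > ncol(m)) stop("column out of bounds", call. = FALSE)
  res <- m[alignment$labels == label, column]
  res <- res[res != "-"]
  if (length(res) == 0L) {
    stop(sprintf("column %d is all-gap for label '%s'", column, label),
         call. = FALSE)
  }
  if (mode == "identity") {
    counts <- table(res[res != "X"])
    if (length(counts) == 0L) {
      return(list(consensus = NA_character_, score = 0, n_ungapped = length(res)))
    }
    list(consensus = names(counts)[which.max(counts)],
         score = max(counts) / length(res),
         n_ungapped = length(res))
  } else {
    cls <- physchem_class(res, scheme)
    counts <- table(cls[!is.na(cls)])
    if (length(counts) == 0L) {
      return(list(consensus = NA_character_, score = 0, n_ungapped = length(res)))
    }
    list(consensus = names(counts)[which.max(counts)],
         score = max(counts) / length(res),
         n_ungapped = length(res))
  }
}

#' Map an alignment column to reference numbering (and back)
#'
#' `column_to_ref` counts the non-gap reference characters in columns
#' `1..column`; `ref_to_column` inverts it. The pair round-trips exactly for
#' every column where the reference is ungapped.
#'
#' @param alignment A [clade_alignment()].
#' @param column 1-based alignment column.
#' @param reference_id Id of the reference row.
#' @return 1-based residue number in the ungapped reference.
#' @examples
#' aln <- clade_alignment(
#'   c(r = "M-KL", f = "MAKL", b1 = "MAQL", b2 = "MAQI"),
#'   c(r = "foreground", f = "foreground",
#'     b1 = "background", b2 = "background")
#' )
#' column_to_ref(aln, 3, "r")  # 2
#' @export
column_to_ref <- function(alignment, column, reference_id) {
  ref <- ref_chars(alignment, reference_id)
  if (column < 1L || column > length(ref)) stop("column out of bounds", call. = FALSE)
  if (ref[column] == "-") {
    stop(sprintf("reference '%s' is gapped at column %d", reference_id, column),
         call. = FALSE)
  }
  sum(ref[seq_len(column)] != "-")
}

#' @rdname column_to_ref
#' @param ref_number 1-based position in the ungapped reference.
#' @export
ref_to_column <- function(alignment, ref_number, reference_id) {
  ref <- ref_chars(alignment, reference_id)
  pos <- cumsum(ref != "-")
  hit <- which(pos == ref_number & ref != "-")
  if (length(hit) == 0L) stop("ref_number beyond reference length", call. = FALSE)
  hit[1L]
}

ref_chars <- function(alignment, reference_id) {
  if (!reference_id %in% names(alignment$seqs)) {
    stop(sprintf("reference id '%s' not in alignment", reference_id), call. = FALSE)
  }
  unlist(strsplit(alignment$seqs[[reference_id]], "", fixed = TRUE))
}

#' Clade-contrast scan for specificity-determining positions
#'
#' Scores every alignment column for conservation in the foreground clade
#' versus divergence in the background, and returns the columns that pass as
#' candidate residues in reference numbering, each with a proposed mutation.
#'
#' A column is a candidate iff all of the following hold:
#' * foreground gap fraction is at most `fg_gap_max`;
#' * foreground conservation reaches `fg_conservation_min` in the configured
#'   mode (`either` accepts the identity rule or the class rule);
#' * the fraction of background residues matching the foreground consensus
#'   (same residue in identity mode; same physicochemical class in class
#'   mode) is at most `bg_match_max`;
#' * the reference row is ungapped at the column (otherwise the column is
#'   dropped with a warning — never silently renumbered);
#' * if a region of interest is set, the reference position falls inside it.
#'
#' @param alignment A [clade_alignment()].
#' @param config A [scan_config()].
#' @param scheme Physicochemical scheme shared with the generator.
#' @return Data frame of class `candidate_residues`, sorted by `ref_number`,
#'   with columns `column`, `ref_number`, `ref_residue`, `fg_consensus`,
#'   `fg_class`, `fg_conservation`, `bg_match_fraction`, `mode_passed`,
#'   `proposed_mutation`.
#' @export
scan_alignment <- function(alignment, config, scheme = physchem_scheme()) {
  stopifnot(inherits(alignment, "clade_alignment"), inherits(config, "scan_config"))
  validate_scheme(scheme)
  m <- aln_matrix(alignment$seqs)
  fg <- m[alignment$labels == "foreground", , drop = FALSE]
  bg <- m[alignment$labels == "background", , drop = FALSE]
  ref <- ref_chars(alignment, config$reference_id)
  ref_pos <- cumsum(ref != "-")

  cls_lut <- stats::setNames(
    rep(names(scheme), lengths(scheme)),
    unlist(scheme, use.names = FALSE)
  )

  rows <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    fg_col <- fg[, j]
    gap_frac <- mean(fg_col == "-")
    if (gap_frac > config$fg_gap_max) next
    fg_ung <- fg_col[fg_col != "-"]
    if (length(fg_ung) == 0L) next
    bg_ung <- bg[, j][bg[, j] != "-"]

    # identity rule
    id_counts <- table(fg_ung[fg_ung != "X"])
    pass_id <- FALSE
    cons_res <- NA_character_
    score_id <- 0
    bg_id <- NA_real_
    if (length(id_counts)) {
      cons_res <- names(id_counts)[which.max(id_counts)]
      score_id <- max(id_counts) / length(fg_ung)
      bg_id <- if (length(bg_ung)) mean(bg_ung == cons_res) else 0
      pass_id <- score_id >= config$fg_conservation_min && bg_id <= config$bg_match_max
    }

    # class rule
    fg_cls <- unname(cls_lut[fg_ung])
    cls_counts <- table(fg_cls[!is.na(fg_cls)])
    pass_cls <- FALSE
    cons_cls <- NA_character_
    score_cls <- 0
    bg_cls_match <- NA_real_
    if (length(cls_counts)) {
      cons_cls <- names(cls_counts)[which.max(cls_counts)]
      score_cls <- max(cls_counts) / length(fg_ung)
      bg_cls <- unname(cls_lut[bg_ung])
      bg_cls_match <- if (length(bg_ung))
        sum(!is.na(bg_cls) & bg_cls == cons_cls) / length(bg_ung) else 0
      pass_cls <- score_cls >= config$fg_conservation_min &&
        bg_cls_match <= config$bg_match_max
    }

    passed <- switch(config$mode,
      identity = pass_id,
      class = pass_cls,
      either = pass_id || pass_cls
    )
    if (!passed) next

    if (ref[j] == "-") {
      warning(sprintf(
        "column %d passes the scan but the reference is gapped there; dropped", j
      ), call. = FALSE)
      next
    }
    rn <- ref_pos[j]
    if (!is.null(config$region_of_interest)) {
      roi <- config$region_of_interest
      if (!any(rn >= roi[, 1] & rn <= roi[, 2])) next
    }

    mode_passed <- if (pass_id && pass_cls) "both" else if (pass_id) "identity" else "class"
    rows[[j]] <- data.frame(
      column = j,
      ref_number = rn,
      ref_residue = ref[j],
      fg_consensus = cons_res,
      fg_class = if (pass_cls) cons_cls else unname(cls_lut[cons_res]),
      fg_conservation = if (pass_id) score_id else score_cls,
      bg_match_fraction = if (pass_id) bg_id else bg_cls_match,
      mode_passed = mode_passed,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(
      column = integer(0), ref_number = integer(0), ref_residue = character(0),
      fg_consensus = character(0), fg_class = character(0),
      fg_conservation = numeric(0), bg_match_fraction = numeric(0),
      mode_passed = character(0), stringsAsFactors = FALSE
    )
  }
  out <- out[order(out$ref_number), , drop = FALSE]
  rownames(out) <- NULL
  out$proposed_mutation <- vapply(seq_len(nrow(out)), function(i) {
    propose_mutation(alignment, out$column[i], out$ref_residue[i],
                     out$ref_number[i])
  }, character(1))
  class(out) <- c("candidate_residues", "data.frame")
  out
}

#' Propose a mutation for a candidate column
#'
#' The candidate position is mutated toward the background: if the modal
#' ungapped background residue at the column reaches a frequency of 0.5 it is
#' the target ("an equivalent residue from channels lacking the foreground
#' phenotype"); if the background is too heterogeneous — or the modal residue
#' equals the reference residue — the target falls back to alanine.
#'
#' @param alignment A [clade_alignment()].
#' @param column 1-based alignment column of the candidate.
#' @param ref_residue Reference residue at the column.
#' @param ref_number Reference position of the column.
#' @return Mutation string such as `"A319Q"`.
#' @export
propose_mutation <- function(alignment, column, ref_residue, ref_number) {
  m <- aln_matrix(alignment$seqs)
  bg <- m[alignment$labels == "background", column]
  bg <- bg[bg != "-"]
  target <- "A"
  if (length(bg)) {
    counts <- table(bg[bg != "X"])
    if (length(counts)) {
      modal <- names(counts)[which.max(counts)]
      if (max(counts) / length(bg) >= 0.5 && modal != ref_residue) target <- modal
    }
  }
  if (target == ref_residue) target <- "A"
  sprintf("%s%d%s", ref_residue, ref_number, target)
}

#' Group vicinal candidates for combined mutagenesis
#'
#' Single-linkage grouping of candidate positions whose reference numbers
#' differ by at most `max_gap`, split greedily left-to-right into groups of at
#' most three residues — the "one or two vicinal residues combined for
#' efficiency" construction rule.
#'
#' @param ref_numbers Sorted integer vector of candidate reference positions.
#' @param max_gap Maximum spacing joining two candidates (default 2).
#' @return List of integer vectors.
#' @examples
#' group_vicinal(c(270, 272))        # one pair
#' group_vicinal(c(10, 11, 12, 13))  # {10,11,12}, {13}
#' @export
group_vicinal <- function(ref_numbers, max_gap = 2) {
  if (length(ref_numbers) == 0L) return(list())
  ref_numbers <- sort(ref_numbers)
  runs <- split(ref_numbers, cumsum(c(1, diff(ref_numbers) > max_gap)))
  out <- list()
  for (run in runs) {
    while (length(run) > 3L) {
      out[[length(out) + 1L]] <- run[1:3]
      run <- run[-(1:3)]
    }
    out[[length(out) + 1L]] <- run
  }
  unname(out)
}

#' Map a residue position between two aligned sequences
#'
#' Finds the alignment column holding `ref_number` of `from_id` and returns
#' the ungapped position of `to_id` at the same column — the operation behind
#' cross-channel residue equivalences. If `to_id` is gapped at the column a
#' `NA` sentinel is returned rather than a silently shifted number.
#'
#' @param alignment A [clade_alignment()].
#' @param from_id,to_id Sequence ids.
#' @param ref_number Ungapped position in `from_id`.
#' @return List with `ref_number` (integer or `NA`), `residue` (of `to_id` at
#'   the column, `"-"` if gapped) and `column`.
#' @export
map_equivalent_residue <- function(alignment, from_id, ref_number, to_id) {
  col <- ref_to_column(alignment, ref_number, from_id)
  to <- ref_chars(alignment, to_id)
  if (to[col] == "-") {
    return(list(ref_number = NA_integer_, residue = "-", column = col))
  }
  list(ref_number = sum(to[seq_len(col)] != "-"), residue = to[col], column = col)
}

#' Write candidate residues to TSV and JSON
#' @param candidates A `candidate_residues` data frame from [scan_alignment()].
#' @param path Output path without extension; `.tsv` and `.json` are written.
#' @return Invisibly, the two paths.
#' @export
write_candidates <- function(candidates, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(candidates, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(candidates, json, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(tsv, json))
}
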