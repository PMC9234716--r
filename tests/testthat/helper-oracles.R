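# Independent oracles and fixture builders used across test files.

# Naive per-column recount of the clade-contrast rule, written as plain
# loops so it shares no code path with scan_alignment(). Returns passing columns
# (alignment coordinates), applying the reference-ungapped requirement.
brute_scan_columns <- function(aln, fg_min, bg_max, mode, reference_id,
                               fg_gap_max = 0.5) {
  scheme <- physchem_scheme()
  class_of <- function(r) {
    for (nm in names(scheme)) if (r %in% scheme[[nm]]) return(nm)
    NA_character_
  }
  seqs <- aln$seqs
  ids <- names(seqs)
  fg_ids <- ids[aln$labels == "foreground"]
  bg_ids <- ids[aln$labels == "background"]
  nc <- nchar(seqs[[1]])
  hits <- integer(0)
  for (j in seq_len(nc)) {
    fg <- vapply(fg_ids, function(id) substr(seqs[[id]], j, j), "")
    bg <- vapply(bg_ids, function(id) substr(seqs[[id]], j, j), "")
    if (mean(fg == "-") > fg_gap_max) next
    fgu <- fg[fg != "-"]
    bgu <- bg[bg != "-"]
    if (length(fgu) == 0L) next
    pass_rule <- function(kind) {
      if (kind == "identity") {
        tab <- table(fgu[fgu != "X"])
        if (length(tab) == 0L) return(FALSE)
        cons <- names(tab)[which.max(tab)]
        sc <- max(tab) / length(fgu)
        bm <- if (length(bgu)) sum(bgu == cons) / length(bgu) else 0
      } else {
        cl <- vapply(fgu, class_of, "")
        tab <- table(cl[!is.na(cl)])
        if (length(tab) == 0L) return(FALSE)
        cons <- names(tab)[which.max(tab)]
        sc <- max(tab) / length(fgu)
        bcl <- vapply(bgu, class_of, "")
        bm <- if (length(bgu))
          sum(!is.na(bcl) & bcl == cons) / length(bgu) else 0
      }
      sc >= fg_min && bm <= bg_max
    }
    ok <- switch(mode,
      identity = pass_rule("identity"),
      class = pass_rule("class"),
      either = pass_rule("identity") || pass_rule("class")
    )
    if (ok && substr(seqs[[reference_id]], j, j) != "-") hits <- c(hits, j)
  }
  hits
}

# random alignment (possibly with gaps and X) for oracle comparisons
random_small_alignment <- function(n_fg = 3, n_bg = 3, n_col = 10,
                                   gap_prob = 0.05, x_prob = 0.03) {
  alphabet <- amino_acids()
  draw_row <- function() {
    r <- sample(alphabet, n_col, replace = TRUE)
    r[stats::runif(n_col) < x_prob] <- "X"
    r[stats::runif(n_col) < gap_prob] <- "-"
    paste(r, collapse = "")
  }
  ids <- c(sprintf("f%d", seq_len(n_fg)), sprintf("b%d", seq_len(n_bg)))
  seqs <- stats::setNames(vapply(ids, function(i) draw_row(), ""), ids)
  # reference row kept gap-free so every column is reportable
  seqs[1] <- gsub("-", "A", seqs[1], fixed = TRUE)
  labels <- stats::setNames(
    c(rep("foreground", n_fg), rep("background", n_bg)), ids
  )
  clade_alignment(seqs, labels)
}

# uniformly random rotation matrix (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force min distance between a residue's CA and all CAs of other chains
brute_min_interchain <- function(structure, chain, resno) {
  at <- structure$atoms[structure$atoms$elety == "CA", ]
  a <- at[at$chain == chain & at$resno == resno, ]
  b <- at[at$chain != chain, ]
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

# four-row alignment with a single controllable contrast column
contrast_alignment <- function(fg_col, bg_col, n_fg = 5, n_bg = 10,
                               flank = "MKTL") {
  stopifnot(length(fg_col) == n_fg, length(bg_col) == n_bg)
  ids <- c(sprintf("f%d", seq_len(n_fg)), sprintf("b%d", seq_len(n_bg)))
  seqs <- stats::setNames(
    paste0(flank, c(fg_col, bg_col), flank), ids
  )
  labels <- stats::setNames(
    c(rep("foreground", n_fg), rep("background", n_bg)), ids
  )
  clade_alignment(seqs, labels)
}
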