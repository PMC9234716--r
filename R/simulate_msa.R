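#' Configuration for the synthetic alignment generator
#'
#' @param n_foreground,n_background Numbers of foreground/background rows
#'   (defaults 20 and 50, the scale of a curated channel-family alignment
#'   restricted to one clade versus the rest of the superfamily).
#' @param n_columns Alignment width (default 560, the approximate length of a
#'   DEG/ENaC subunit, so reference numbering reaches the upper extracellular
#'   domain).
#' @param planted_columns 1-based columns to plant as specificity-determining
#'   positions: foreground-conserved, background-divergent.
#' @param within_class_noise Probability that a planted foreground residue is
#'   replaced by another residue of the same physicochemical class — degrades
#'   identity-level but not class-level conservation.
#' @param background_profile Residue frequency vector over [amino_acids()]
#'   (recycled across columns) or a 20 x `n_columns` matrix; default uniform.
#' @param n_redundant_duplicates Exact copies of existing rows to append.
#' @param n_length_outliers Short gap-padded rows (<300 ungapped residues) to
#'   append; rows longer than the curation window cannot be embedded in an
#'   alignment whose width is itself inside the window, so planted outliers
#'   are always short.
#' @param seed RNG seed; equal seed and config give byte-identical output.
#' @return `msa_sim_config` list.
#' @export
msa_sim_config <- function(n_foreground = 20, n_background = 50,
                           n_columns = 560, planted_columns = integer(0),
                           within_class_noise = 0,
                           background_profile = NULL,
                           n_redundant_duplicates = 0,
                           n_length_outliers = 0, seed = 1) {
  stopifnot(n_foreground >= 2, n_background >= 2, n_columns >= 1)
  planted_columns <- sort(unique(as.integer(planted_columns)))
  if (length(planted_columns) &&
      (min(planted_columns) < 1L || max(planted_columns) > n_columns)) {
    stop("planted_columns must lie in [1, n_columns]", call. = FALSE)
  }
  assert_proportion(within_class_noise, "within_class_noise")
  aa <- amino_acids()
  if (is.null(background_profile)) {
    background_profile <- stats::setNames(rep(1 / 20, 20), aa)
  }
  if (is.matrix(background_profile)) {
    stopifnot(nrow(background_profile) == 20, ncol(background_profile) == n_columns)
    if (any(abs(colSums(background_profile) - 1) > 1e-9)) {
      stop("background_profile columns must sum to 1", call. = FALSE)
    }
  } else {
    stopifnot(length(background_profile) == 20)
    if (abs(sum(background_profile) - 1) > 1e-9) {
      stop("background_profile must sum to 1", call. = FALSE)
    }
  }
  structure(
    list(n_foreground = n_foreground, n_background = n_background,
         n_columns = n_columns, planted_columns = planted_columns,
         within_class_noise = within_class_noise,
         background_profile = background_profile,
         n_redundant_duplicates = n_redundant_duplicates,
         n_length_outliers = n_length_outliers, seed = seed),
    class = "msa_sim_config"
  )
}

#' Simulate a clade-labeled alignment with planted SDP columns
#'
#' Generates a gapless foreground/background alignment in which the planted
#' columns carry the contrast the scan is built to detect: at
#' `within_class_noise = 0` every foreground residue at a planted column is
#' identical, and every background residue there is drawn from a different
#' physicochemical class than the foreground consensus, so both the identity
#' rule and the class rule separate the clades perfectly. All other columns
#' are drawn iid from the background profile for both partitions — no
#' phylogenetic autocorrelation, matching the column-wise logic of the scan
#' itself. Requested exact duplicates and short length outliers are appended
#' and flagged in the returned truth.
#'
#' @param config An [msa_sim_config()].
#' @param scheme Physicochemical scheme shared with the scan.
#' @return List with `alignment` (a [clade_alignment()]) and `truth`, a
#'   `planted_truth` list holding `sdp_columns`, per-column foreground
#'   consensus and class, `duplicate_ids` and `outlier_ids`.
#' @export
simulate_msa <- function(config, scheme = physchem_scheme()) {
  stopifnot(inherits(config, "msa_sim_config"))
  validate_scheme(scheme)
  if (length(scheme) < 2L && length(config$planted_columns)) {
    stop("planting requires at least two physicochemical classes", call. = FALSE)
  }
  aa <- amino_acids()
  with_seed(config$seed, {
    n_fg <- config$n_foreground
    n_bg <- config$n_background
    n_col <- config$n_columns
    prof <- config$background_profile
    m <- matrix("", n_fg + n_bg, n_col)
    for (j in seq_len(n_col)) {
      p <- if (is.matrix(prof)) prof[, j] else prof
      m[, j] <- sample(aa, n_fg + n_bg, replace = TRUE, prob = p)
    }
    fg_rows <- seq_len(n_fg)
    bg_rows <- n_fg + seq_len(n_bg)
    cons <- character(length(config$planted_columns))
    cls <- character(length(config$planted_columns))
    for (k in seq_along(config$planted_columns)) {
      j <- config$planted_columns[k]
      cls[k] <- sample(names(scheme), 1L)
      members <- scheme[[cls[k]]]
      cons[k] <- sample(members, 1L)
      fg_res <- rep(cons[k], n_fg)
      if (config$within_class_noise > 0 && length(members) > 1L) {
        flip <- stats::runif(n_fg) < config$within_class_noise
        n_flip <- sum(flip)
        if (n_flip) {
          fg_res[flip] <- sample(setdiff(members, cons[k]), n_flip, replace = TRUE)
        }
      }
      m[fg_rows, j] <- fg_res
      pool <- setdiff(aa, members)
      m[bg_rows, j] <- sample(pool, n_bg, replace = TRUE)
    }
    ids <- c(sprintf("fg_%03d", seq_len(n_fg)), sprintf("bg_%03d", seq_len(n_bg)))
    labels <- stats::setNames(
      c(rep("foreground", n_fg), rep("background", n_bg)), ids
    )
    seqs <- stats::setNames(apply(m, 1L, paste, collapse = ""), ids)

    dup_ids <- character(0)
    if (config$n_redundant_duplicates > 0) {
      src <- sample(ids, config$n_redundant_duplicates, replace = TRUE)
      dup_ids <- sprintf("%s_dup%02d", src, seq_along(src))
      seqs[dup_ids] <- seqs[src]
      labels[dup_ids] <- labels[src]
    }
    out_ids <- character(0)
    if (config$n_length_outliers > 0) {
      n_res <- min(250L, max(1L, n_col %/% 2L))
      for (k in seq_len(config$n_length_outliers)) {
        id <- sprintf("outlier_%02d", k)
        res <- sample(aa, n_res, replace = TRUE, prob = if (is.matrix(prof)) NULL else prof)
        seqs[id] <- paste0(paste(res, collapse = ""), strrep("-", n_col - n_res))
        labels[id] <- "excluded"
        out_ids <- c(out_ids, id)
      }
    }
    truth <- structure(
      list(sdp_columns = config$planted_columns,
           fg_consensus = cons, fg_class = cls,
           duplicate_ids = dup_ids, outlier_ids = out_ids),
      class = "planted_truth"
    )
    list(alignment = clade_alignment(seqs, labels), truth = truth)
  })
}
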