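# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after seeding the RNG, then restores the caller's RNG state so
#' that seeded generators have no side effects on the session.
#'
#' @param seed Single finite integer-like seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# standard error of the mean
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# single scalar check
assert_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

assert_proportion <- function(x, name) {
  assert_scalar(x, name)
  if (x < 0 || x > 1) stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# alignment as character matrix, rows named by sequence id
aln_matrix <- function(seqs) {
  stopifnot(length(seqs) > 0L)
  n <- unique(nchar(seqs))
  if (length(n) != 1L) stop("sequences are not all the same length", call. = FALSE)
  m <- do.call(rbind, strsplit(unname(as.character(seqs)), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}
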