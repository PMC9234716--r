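#' Peak current within an application window
#'
#' Baseline-subtracted extremum of the current within the application
#' window. The baseline is the median of the 1 s immediately preceding the
#' window (robust to noise and slow drift); the peak is the windowed sample
#' of largest magnitude after baseline subtraction, returned sign-preserved
#' (inward currents are negative; downstream statistics work on magnitudes).
#'
#' @param trace A `current_trace` (list with `time`, `current`, `windows`).
#' @param window Optional `c(start, end)` in seconds; defaults to the first
#'   application window stored in the trace.
#' @return Signed peak in uA, with the baseline as attribute `"baseline"`.
#' @export
measure_peak <- function(trace, window = NULL) {
  if (is.null(window)) {
    if (is.null(trace$windows) || nrow(trace$windows) == 0L) {
      stop("trace carries no application window", call. = FALSE)
    }
    window <- c(trace$windows$start[1], trace$windows$end[1])
  }
  stopifnot(length(window) == 2L, window[1] < window[2])
  t <- trace$time
  if (window[1] - t[1] < 1 - 1e-9) {
    stop("need >= 1 s of pre-application baseline before the window",
         call. = FALSE)
  }
  pre <- t >= window[1] - 1 & t < window[1]
  inside <- t >= window[1] & t <= window[2]
  if (sum(inside) < 3L) stop("window shorter than 3 samples", call. = FALSE)
  baseline <- stats::median(trace$current[pre])
  seg <- trace$current[inside] - baseline
  peak <- seg[which.max(abs(seg))]
  structure(peak, baseline = baseline)
}

#' Fit the Hill equation to one recording
#'
#' Bounded least-squares fit of
#' `I = Imax * c^n / (c^n + EC50^n)`
#' to one recording's (concentration, peak) pairs, parameterized in
#' log10(EC50) so the optimizer works on the scale on which dose-response
#' data are linear. EC50 is bounded to `[min(conc)/100, max(conc)*100]`, the
#' Hill coefficient to `[0.3, 10]`. Initialization: Imax from the largest
#' response, EC50 from linear interpolation of the half-maximum crossing in
#' log-concentration, n = 1. Non-convergence is reported honestly via
#' `converged = FALSE`, never silently.
#'
#' @param concentration Molar concentrations (>= 3 distinct values).
#' @param response Peak responses (signed or magnitudes; fitted on
#'   magnitudes).
#' @return A `hill_fit` list: `ec50` (M), `hill_n`, `imax`, `rss`,
#'   `converged`, `message`.
#' @examples
#' conc <- 10^seq(-7.5, -4, 0.5)
#' resp <- conc / (conc + 1e-6)
#' fit_hill(conc, resp)
#' @export
fit_hill <- function(concentration, response) {
  if (any(concentration <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (length(unique(concentration)) < 3L) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  y <- abs(response)
  lx <- log10(concentration)
  lo <- c(lec50 = min(lx) - 2, nh = 0.3, imax = 1e-12)
  hi <- c(lec50 = max(lx) + 2, nh = 10, imax = 10 * max(y) + 1e-12)

  imax0 <- max(y)
  half <- imax0 / 2
  ord <- order(lx)
  ys <- y[ord]; lxs <- lx[ord]
  lec50_0 <- stats::median(lx)
  crossing <- which(ys[-1] >= half & ys[-length(ys)] < half)
  if (length(crossing)) {
    i <- crossing[1]
    frac <- (half - ys[i]) / (ys[i + 1] - ys[i])
    lec50_0 <- lxs[i] + frac * (lxs[i + 1] - lxs[i])
  }
  start <- c(lec50 = min(max(lec50_0, lo[["lec50"]]), hi[["lec50"]]),
             nh = 1, imax = imax0)

  df <- data.frame(lx = lx, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ imax / (1 + 10^(nh * (lec50 - lx))),
      data = df, start = as.list(start),
      lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(ec50 = NA_real_, hill_n = NA_real_, imax = NA_real_,
           rss = NA_real_, converged = FALSE, message = conditionMessage(fit)),
      class = "hill_fit"
    ))
  }
  cf <- stats::coef(fit)
  structure(
    list(ec50 = 10^cf[["lec50"]], hill_n = cf[["nh"]], imax = cf[["imax"]],
         rss = sum(stats::resid(fit)^2),
         converged = isTRUE(fit$convInfo$isConv), message = ""),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit: EC50 = %.3g M, nH = %.2f, Imax = %.3g (converged: %s)\n",
              x$ec50, x$hill_n, x$imax, x$converged))
  invisible(x)
}

#' Per-recording Hill fits with across-recording summary
#'
#' Fits each recording separately and aggregates as mean +/- SEM of EC50
#' across converged fits — the per-recording-then-average convention for
#' reporting concentration-response parameters. A display fit to the mean
#' normalized responses is returned alongside (for figures only; reported
#' parameters come from the per-recording fits).
#'
#' @param data Data frame with columns `recording_id`, `concentration_M`,
#'   `peak_uA`.
#' @return List with `fits` (named list of `hill_fit`), `summary` (data
#'   frame: n, mean/sem/median of EC50 in M, mean nH), and `display_fit`.
#' @export
fit_hill_by_recording <- function(data) {
  stopifnot(all(c("recording_id", "concentration_M", "peak_uA") %in% names(data)))
  fits <- lapply(split(data, data$recording_id), function(d) {
    fit_hill(d$concentration_M, d$peak_uA)
  })
  ec50 <- vapply(fits, function(f) if (f$converged) f$ec50 else NA_real_, numeric(1))
  nh <- vapply(fits, function(f) if (f$converged) f$hill_n else NA_real_, numeric(1))
  ok <- !is.na(ec50)
  # display fit: mean response per concentration, each recording normalized
  # to its own maximum
  norm <- do.call(rbind, lapply(split(data, data$recording_id), function(d) {
    d$norm <- abs(d$peak_uA) / max(abs(d$peak_uA))
    d
  }))
  mean_resp <- stats::aggregate(norm ~ concentration_M, norm, mean)
  display_fit <- fit_hill(mean_resp$concentration_M, mean_resp$norm)
  list(
    fits = fits,
    summary = data.frame(
      n = sum(ok),
      n_failed = sum(!ok),
      ec50_mean = mean(ec50[ok]),
      ec50_sem = sem(ec50[ok]),
      ec50_median = stats::median(ec50[ok]),
      hill_n_mean = mean(nh[ok])
    ),
    display_fit = display_fit
  )
}

#' Normalize responses to a per-batch reference
#'
#' Divides every peak by the mean maximal-concentration response of the
#' reference construct recorded in the same batch (e.g. "normalized to mean
#' maximum WT current on the same day"), so the reference's batch-mean
#' maximal response maps to 1.0 and day-to-day expression differences cancel.
#'
#' @param data Data frame with columns `construct`, `batch_id`,
#'   `recording_id`, `concentration_M`, `peak_uA`.
#' @param reference Construct name serving as reference (e.g. `"WT"`).
#' @return `data` with an added `peak_norm` column.
#' @export
normalize_to_reference <- function(data, reference = "WT") {
  need <- c("construct", "batch_id", "recording_id", "concentration_M", "peak_uA")
  stopifnot(all(need %in% names(data)))
  out <- vector("list", length(unique(data$batch_id)))
  batches <- unique(data$batch_id)
  for (i in seq_along(batches)) {
    b <- data[data$batch_id == batches[i], , drop = FALSE]
    ref <- b[b$construct == reference, , drop = FALSE]
    if (nrow(ref) == 0L) {
      stop(sprintf("batch '%s' has no recordings of reference '%s'",
                   batches[i], reference), call. = FALSE)
    }
    # maximal response of each reference recording, averaged over recordings
    ref_max <- vapply(split(ref, ref$recording_id),
                      function(d) max(abs(d$peak_uA)), numeric(1))
    scale <- mean(ref_max)
    b$peak_norm <- abs(b$peak_uA) / scale
    out[[i]] <- b
  }
  do.call(rbind, out)
}

#' Paired potency ratio
#'
#' Per-recording ratio of two paired responses from the same oocyte (test
#' concentration over near-saturating concentration; magnitudes), averaged
#' as mean +/- SEM across recordings. Recordings whose denominator response
#' falls below the noise floor are excluded and counted, never silently
#' dropped.
#'
#' @param peaks Data frame with columns `recording_id`, `peak_a`, `peak_b`
#'   (signed uA; a = test concentration, b = saturating concentration).
#' @param noise_floor Magnitude below which `peak_b` marks a non-responding
#'   recording (default 0; set to 3x baseline SD when known).
#' @return `potency_ratio` list: `ratio` (mean), `sem`, `n`, `n_excluded`,
#'   `per_recording`.
#' @examples
#' potency_ratio(data.frame(recording_id = "r1", peak_a = -3.2, peak_b = -5))
#' @export
potency_ratio <- function(peaks, noise_floor = 0) {
  stopifnot(all(c("recording_id", "peak_a", "peak_b") %in% names(peaks)))
  ok <- abs(peaks$peak_b) >= noise_floor & abs(peaks$peak_b) > 0
  r <- abs(peaks$peak_a[ok]) / abs(peaks$peak_b[ok])
  structure(
    list(ratio = mean(r), sem = sem(r), n = sum(ok),
         n_excluded = sum(!ok),
         per_recording = data.frame(
           recording_id = peaks$recording_id[ok], ratio = r,
           stringsAsFactors = FALSE
         )),
    class = "potency_ratio"
  )
}

#' @export
print.potency_ratio <- function(x, ...) {
  cat(sprintf("potency ratio: %.3f +/- %.3f (n = %d, excluded = %d)\n",
              x$ratio, x$sem, x$n, x$n_excluded))
  invisible(x)
}

#' Paired fold-enhancement
#'
#' Per-recording fold `|peak_b| / |peak_a|` for paired conditioning
#' protocols (test pulse after conditioning plus peptide over test pulse
#' after conditioning alone), averaged as mean +/- SEM. Recordings whose
#' control response is below the noise floor are flagged and their fold is
#' computed against the floor, with a warning.
#'
#' @param peaks Data frame with `recording_id`, `peak_a` (control),
#'   `peak_b` (conditioned + peptide), signed uA.
#' @param noise_floor Magnitude floor for `peak_a` (default 0 = disabled).
#' @return `enhancement_result` list: `fold` (mean), `sem`, `n`,
#'   `n_flagged`, `per_recording`.
#' @export
enhancement_ratio <- function(peaks, noise_floor = 0) {
  stopifnot(all(c("recording_id", "peak_a", "peak_b") %in% names(peaks)))
  a <- abs(peaks$peak_a)
  flagged <- noise_floor > 0 & a < noise_floor
  if (any(flagged)) {
    warning(sprintf(
      "%d recording(s) with control response below the noise floor; fold computed against the floor",
      sum(flagged)
    ), call. = FALSE)
    a[flagged] <- noise_floor
  }
  fold <- abs(peaks$peak_b) / a
  structure(
    list(fold = mean(fold), sem = sem(fold), n = nrow(peaks),
         n_flagged = sum(flagged),
         per_recording = data.frame(
           recording_id = peaks$recording_id, fold = fold,
           flagged = flagged, stringsAsFactors = FALSE
         )),
    class = "enhancement_result"
  )
}

#' @export
print.enhancement_result <- function(x, ...) {
  cat(sprintf("fold enhancement: %.2f +/- %.2f (n = %d)\n", x$fold, x$sem, x$n))
  invisible(x)
}

#' pH / proton-concentration adapters
#'
#' Convert pH to molar proton concentration and back, so the Hill machinery
#' covers proton-gated dose-response data unchanged.
#'
#' @param ph pH value(s).
#' @return Molar concentration(s) `10^-pH`.
#' @examples
#' ph_to_concentration(5.3)
#' concentration_to_ph(ph_to_concentration(7))
#' @export
ph_to_concentration <- function(ph) {
  stopifnot(all(is.finite(ph)))
  10^(-ph)
}

#' @rdname ph_to_concentration
#' @param concentration Molar proton concentration(s).
#' @export
concentration_to_ph <- function(concentration) {
  stopifnot(all(is.finite(concentration) & concentration > 0))
  -log10(concentration)
}
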