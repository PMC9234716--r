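test_that("peak measurement subtracts the pre-application baseline", {
  flat <- structure(list(
    time = seq(0, 10, 0.01), current = rep(0, 1001),
    windows = data.frame(start = 2, end = 7)
  ), class = "current_trace")
  expect_equal(as.numeric(measure_peak(flat)), 0)

  tr <- simulate_trace(trace_sim_config(peak_amplitude = -4, noise_sd = 0))
  pk <- measure_peak(tr)
  expect_equal(as.numeric(pk), attr(tr, "true_peak"), tolerance = 1e-6)

  # a constant offset moves the baseline, not the peak
  tr_off <- tr
  tr_off$current <- tr$current + 0.5
  expect_equal(as.numeric(measure_peak(tr_off)), as.numeric(pk),
               tolerance = 1e-9)
  expect_equal(attr(measure_peak(tr_off), "baseline"), 0.5)

  expect_error(measure_peak(tr, window = c(0.5, 5)), "baseline")
  expect_error(measure_peak(tr, window = c(2, 2.001)), "3 samples")
})

test_that("Hill fitting recovers exact parameters from noiseless data", {
  conc <- 10^seq(-7.5, -4, 0.5)
  resp <- 1 * conc / (conc + 1e-6)
  fit <- fit_hill(conc, resp)
  expect_true(fit$converged)
  expect_equal(fit$ec50, 1e-6, tolerance = 1e-4)
  expect_equal(fit$hill_n, 1, tolerance = 1e-4)
  expect_equal(fit$imax, 1, tolerance = 1e-4)

  # predicted response at c = EC50 is Imax/2
  pred <- fit$imax / (1 + (fit$ec50 / 1e-6)^fit$hill_n)
  expect_equal(pred, 0.5, tolerance = 1e-4)

  # steeper curve, different amplitude
  resp2 <- 3 * conc^2 / (conc^2 + (2e-6)^2)
  fit2 <- fit_hill(conc, resp2)
  expect_equal(fit2$ec50, 2e-6, tolerance = 1e-4)
  expect_equal(fit2$hill_n, 2, tolerance = 1e-3)

  expect_error(fit_hill(c(1e-6, 1e-5), c(0.1, 0.5)), "3 distinct")
})

test_that("statistics are invariant to overall current scale", {
  conc <- 10^seq(-7.5, -4, 0.5)
  set.seed(4)
  resp <- conc / (conc + 3e-6) * (1 + rnorm(length(conc), 0, 0.05))
  f1 <- fit_hill(conc, resp)
  f2 <- fit_hill(conc, 7.3 * resp)
  expect_equal(f2$ec50, f1$ec50, tolerance = 1e-6)
  expect_equal(f2$hill_n, f1$hill_n, tolerance = 1e-6)
  expect_equal(f2$imax, 7.3 * f1$imax, tolerance = 1e-6)

  peaks <- data.frame(recording_id = c("r1", "r2"), peak_a = c(-3.2, -3.0),
                      peak_b = c(-5.0, -4.8))
  scaled <- transform(peaks, peak_a = 2.5 * peak_a, peak_b = 2.5 * peak_b)
  expect_equal(potency_ratio(scaled)$ratio, potency_ratio(peaks)$ratio)
  expect_equal(enhancement_ratio(scaled)$fold, enhancement_ratio(peaks)$fold)
})

test_that("batch normalization maps the reference batch-mean maximum to 1", {
  dr <- data.frame(
    construct = c("WT", "WT", "mut", "WT", "mut"),
    batch_id = c("d1", "d1", "d1", "d2", "d2"),
    recording_id = c("r1", "r2", "r3", "r4", "r5"),
    concentration_M = 1e-4,
    peak_uA = c(-8, -12, -5, -2, -5)
  )
  norm <- normalize_to_reference(dr, "WT")
  # day 1 reference scale: mean(8, 12) = 10; day 2: 2
  expect_equal(norm$peak_norm[norm$recording_id == "r3"], 0.5)
  expect_equal(norm$peak_norm[norm$recording_id == "r5"], 2.5)
  wt1 <- norm[norm$construct == "WT" & norm$batch_id == "d1", ]
  expect_equal(mean(vapply(split(wt1, wt1$recording_id),
                           function(d) max(d$peak_norm), numeric(1))), 1.0)
  expect_error(normalize_to_reference(dr, "absent"), "no recordings")
})

test_that("potency ratio averages per-recording ratios and counts exclusions", {
  same <- data.frame(recording_id = c("r1", "r2"), peak_a = c(-2, -3),
                     peak_b = c(-2, -3))
  expect_equal(potency_ratio(same)$ratio, 1.0)

  one <- data.frame(recording_id = "r1", peak_a = -3.2, peak_b = -5.0)
  expect_equal(potency_ratio(one)$ratio, 0.64)

  mixed <- data.frame(recording_id = c("r1", "r2"), peak_a = c(-3.2, -0.01),
                      peak_b = c(-5.0, -0.02))
  pr <- potency_ratio(mixed, noise_floor = 0.1)
  expect_identical(pr$n, 1L)
  expect_identical(pr$n_excluded, 1L)
  expect_equal(pr$ratio, 0.64)
})

test_that("fold enhancement handles the noise floor with a warning", {
  same <- data.frame(recording_id = "r1", peak_a = -0.5, peak_b = -0.5)
  expect_equal(enhancement_ratio(same)$fold, 1.0)

  ten <- data.frame(recording_id = "r1", peak_a = -0.1, peak_b = -1.0)
  expect_equal(enhancement_ratio(ten)$fold, 10)

  tiny <- data.frame(recording_id = "r1", peak_a = -0.001, peak_b = -1.0)
  expect_warning(er <- enhancement_ratio(tiny, noise_floor = 0.05),
                 "noise floor")
  expect_equal(er$fold, 20)  # fold against the floor, not the raw value
  expect_identical(er$n_flagged, 1L)
})

test_that("pH adapters round-trip and match the log scale", {
  expect_equal(ph_to_concentration(7), 1e-7)
  expect_equal(ph_to_concentration(5.3), 10^-5.3)
  expect_equal(concentration_to_ph(ph_to_concentration(6.4)), 6.4)
})

test_that("Monte-Carlo Dunnett critical value matches multivariate-t quadrature", {
  n <- rep(5L, 4)           # control + 3 treatments
  df <- sum(n) - length(n)  # 16
  crit_mc <- dunnett_critical(n, df, alpha = 0.05, ndraws = 200000, seed = 2)
  corr <- matrix(0.5, 3, 3); diag(corr) <- 1
  crit_ref <- mvtnorm::qmvt(0.95, tail = "lower.tail", df = df, corr = corr,
                            seed = 1)$quantile
  expect_equal(crit_mc, crit_ref, tolerance = 0.02)
})

test_that("mutant classification applies the zero-response and Dunnett stages", {
  set.seed(31)
  spread <- c(-0.04, -0.02, 0, 0.02, 0.04)
  ratios <- data.frame(
    construct = rep(c("WT", "dead", "loss", "same"), each = 5),
    ratio = c(0.64 + spread, 1.0 + 10 * spread, 0.10 + spread, 0.64 + spread)
  )
  amps <- data.frame(
    construct = rep(c("dead", "loss", "same"), each = 5),
    # "dead" amplitudes are pure zero-mean noise
    peak_a = c(c(-0.01, 0.01, -0.005, 0.005, 0),
               rnorm(5, -0.5, 0.05), rnorm(5, -3, 0.3)),
    peak_b = c(c(0.008, -0.008, 0.004, -0.004, 0),
               rnorm(5, -4, 0.4), rnorm(5, -5, 0.5))
  )
  cls <- classify_mutants(ratios, amps, wt = "WT", seed = 9)
  get <- function(cc) cls$label[cls$construct == cc]
  expect_identical(get("WT"), "reference")
  expect_identical(get("dead"), "no_response")
  expect_identical(get("loss"), "reduced")
  expect_identical(get("same"), "unchanged_or_greater")

  expect_error(classify_mutants(data.frame(construct = "m", ratio = 1:3)),
               "wild-type")
  expect_error(
    classify_mutants(data.frame(construct = c("WT", "WT", "WT", "m", "m"),
                                ratio = c(1, 1, 1, 1, 1))),
    ">= 3 replicates"
  )
})

test_that("a strong planted loss is detected with high power", {
  set.seed(17)
  hits <- 0L
  n_rep <- 100L
  for (i in seq_len(n_rep)) {
    ratios <- data.frame(
      construct = rep(c("WT", "mut"), each = 5),
      ratio = c(rnorm(5, 0.64, 0.64 * 0.05), rnorm(5, 0.10, 0.10 * 0.05))
    )
    cls <- classify_mutants(ratios, wt = "WT", seed = 3)
    hits <- hits + (cls$label[cls$construct == "mut"] == "reduced")
  }
  expect_gte(hits / n_rep, 0.95)
})
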