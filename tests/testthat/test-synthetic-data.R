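test_that("alignment generator is deterministic and plants the stated contrast", {
  cfg <- msa_sim_config(
    n_foreground = 8, n_background = 12, n_columns = 60,
    planted_columns = c(5, 17, 43), within_class_noise = 0,
    n_redundant_duplicates = 2, n_length_outliers = 1, seed = 7
  )
  a <- simulate_msa(cfg)
  b <- simulate_msa(cfg)
  expect_identical(a$alignment$seqs, b$alignment$seqs)
  expect_identical(a$truth, b$truth)

  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(a$alignment$seqs, f1)
  write_fasta(b$alignment$seqs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  m <- do.call(rbind, strsplit(a$alignment$seqs, ""))
  rownames(m) <- names(a$alignment$seqs)
  fg <- m[a$alignment$labels == "foreground" &
            !grepl("_dup", rownames(m)), , drop = FALSE]
  bg <- m[a$alignment$labels == "background" &
            !grepl("_dup", rownames(m)), , drop = FALSE]
  for (k in seq_along(a$truth$sdp_columns)) {
    j <- a$truth$sdp_columns[k]
    expect_length(unique(fg[, j]), 1L)  # noiseless: all foreground identical
    fg_class <- physchem_class(fg[1, j])
    expect_false(any(physchem_class(bg[, j]) == fg_class))
  }

  # duplicates are exact copies; outliers fall below the length window
  for (d in a$truth$duplicate_ids) {
    src <- sub("_dup\\d+$", "", d)
    expect_identical(a$alignment$seqs[[d]], a$alignment$seqs[[src]])
  }
  for (o in a$truth$outlier_ids) {
    expect_lt(nchar(gsub("-", "", a$alignment$seqs[[o]])), 300)
    expect_identical(unname(a$alignment$labels[o]), "excluded")
  }
})

test_that("planted-column truth has the requested size (43-column default benchmark)", {
  set.seed(3)
  planted <- sort(sample(1:560, 43))
  sim <- simulate_msa(msa_sim_config(planted_columns = planted, seed = 11))
  expect_length(sim$truth$sdp_columns, 43L)
  expect_identical(sim$truth$sdp_columns, planted)
})

test_that("toy trimer geometry honors the planted interface contract", {
  ir <- 8
  pocket <- c(231, 281, 288, 316, 447, 529)
  sim <- simulate_trimer(560, pocket, interface_radius = ir, seed = 2)
  st <- sim$structure

  for (rn in pocket) {
    expect_lte(min_interchain_distance(st, "A", rn)$distance, ir)
  }
  for (rn in c(1, 100, 230, 232, 560)) {
    expect_gt(min_interchain_distance(st, "A", rn)$distance, 1.5 * ir)
  }

  # C3 symmetry: per-chain centroids equidistant from the z axis
  cent_r <- vapply(c("A", "B", "C"), function(ch) {
    at <- st$atoms[st$atoms$chain == ch, ]
    sqrt(mean(at$x)^2 + mean(at$y)^2)
  }, numeric(1))
  expect_equal(max(cent_r) - min(cent_r), 0, tolerance = 1e-9)

  # empty planting: nothing within the interface radius of another chain
  empty <- simulate_trimer(40, integer(0), interface_radius = ir, seed = 5)
  dists <- vapply(1:40, function(rn)
    min_interchain_distance(empty$structure, "A", rn)$distance, numeric(1))
  expect_true(all(dists > ir))

  expect_error(simulate_trimer(100, pocket_residues = 200), "pocket_residues")
})

test_that("dose-response generator matches Hill closed forms", {
  # half-max identity at c = EC50, noiseless
  d <- simulate_dose_response(1e-6, 1, 2, concentrations = 1e-6,
                              n_recordings = 1, noise_sd_fraction = 0, seed = 1)
  expect_equal(d$peak_uA, 1, tolerance = 1e-12)

  # saturation limit: c = 1e6 * EC50 with n = 1
  d2 <- simulate_dose_response(1e-6, 1, 1, concentrations = 1,
                               n_recordings = 1, noise_sd_fraction = 0, seed = 1)
  expect_equal(d2$peak_uA, 0.999999, tolerance = 1e-9)

  # default ladder: half-log steps spanning ~30 nM to 100 uM
  ladder <- default_concentration_ladder()
  expect_equal(min(ladder), 10^-7.5)
  expect_equal(max(ladder), 1e-4)
  expect_equal(unique(round(diff(log10(ladder)), 9)), 0.5)

  expect_error(simulate_dose_response(1e-6, concentrations = c(1e-6, -1)),
               "concentrations")
})

test_that("trace generator peaks match the biexponential analysis", {
  # monoexponential rise: long window approaches the planted amplitude
  cfg <- trace_sim_config(duration_s = 12, window = c(2, 11),
                          tau_activation = 0.2, peak_amplitude = -3,
                          noise_sd = 0, seed = 1)
  tr <- simulate_trace(cfg)
  expect_equal(max(abs(tr$current)), 3, tolerance = 1e-6)
  expect_true(all(tr$current[tr$time < 2] == 0))

  # with desensitization the max sits at t* = tau_a * log(1 + tau_d / tau_a)
  cfg2 <- trace_sim_config(duration_s = 10, window = c(2, 9),
                           tau_activation = 0.3, tau_desensitization = 1.5,
                           peak_amplitude = -2, noise_sd = 0, seed = 1)
  tr2 <- simulate_trace(cfg2)
  t_star <- 2 + 0.3 * log(1 + 1.5 / 0.3)
  t_max <- tr2$time[which.max(abs(tr2$current))]
  expect_lte(abs(t_max - t_star), 1 / cfg2$sampling_rate)
  # sampled extremum sits within one time step of the analytic peak
  expect_equal(min(tr2$current), -2, tolerance = 1e-5)
  expect_equal(attr(tr2, "true_peak"), -2)

  # noiseless paired protocol: planted fold recovered exactly
  pairs <- simulate_enhancement_traces(true_fold = 10, n_recordings = 3,
                                       noise_sd_fraction = 0, seed = 4)
  er <- enhancement_ratio(peaks_from_pairs(pairs))
  expect_equal(er$fold, 10, tolerance = 1e-6)

  pairs2 <- simulate_potency_ratio_traces(true_ratio = 0.64, n_recordings = 3,
                                          noise_sd_fraction = 0, seed = 4)
  pr <- potency_ratio(peaks_from_pairs(pairs2))
  expect_equal(pr$ratio, 0.64, tolerance = 1e-6)
})

test_that("generator configs reject impossible settings", {
  expect_error(msa_sim_config(planted_columns = 100, n_columns = 50),
               "planted_columns")
  expect_error(msa_sim_config(within_class_noise = 1.2), "within_class_noise")
  expect_error(msa_sim_config(background_profile = rep(0.06, 20)), "sum to 1")
  expect_error(trace_sim_config(window = c(5, 2)))
  expect_error(trace_sim_config(tau_activation = -1), "tau_activation")
})
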