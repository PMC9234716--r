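#' Default concentration ladder
#'
#' Half-log (sqrt(10)-step) agonist ladder spanning roughly 30 nM to 100 uM,
#' the range used in concentration-response experiments on peptide-gated
#' channels.
#'
#' @return Numeric vector of concentrations in molar: `10^seq(-7.5, -4, 0.5)`.
#' @export
default_concentration_ladder <- function() {
  10^seq(-7.5, -4, by = 0.5)
}

#' Simulate per-recording dose-response tables
#'
#' Peak responses follow the Hill equation with multiplicative Gaussian
#' noise,
#' `peak = Imax * c^n / (c^n + EC50^n) * (1 + eps)`,
#' `eps ~ N(0, noise_sd_fraction^2)` independently per point per recording.
#' Noise is multiplicative because oocyte responses scale with expression
#' level. Each recording is assigned a recording and batch id.
#'
#' @param true_ec50 Molar EC50 of the generative curve.
#' @param true_hill Hill coefficient (default 1).
#' @param true_imax Maximal response in uA (magnitude; default 1).
#' @param concentrations Molar concentrations tested per recording.
#' @param n_recordings Number of recordings (oocytes).
#' @param noise_sd_fraction Multiplicative noise SD (default 0.05).
#' @param seed RNG seed.
#' @param recordings_per_batch Recordings per experiment day (default 5).
#' @return Data frame `recording_id`, `batch_id`, `concentration_M`,
#'   `peak_uA`, with the generative parameters attached as attribute
#'   `"truth"`.
#' @export
simulate_dose_response <- function(true_ec50, true_hill = 1, true_imax = 1,
                                   concentrations = default_concentration_ladder(),
                                   n_recordings = 5,
                                   noise_sd_fraction = 0.05, seed = 1,
                                   recordings_per_batch = 5) {
  assert_scalar(true_ec50, "true_ec50", positive = TRUE)
  assert_scalar(true_hill, "true_hill", positive = TRUE)
  assert_scalar(true_imax, "true_imax", positive = TRUE)
  if (any(concentrations <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (noise_sd_fraction < 0) stop("noise_sd_fraction must be >= 0", call. = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(n_recordings), function(r) {
      mu <- true_imax * concentrations^true_hill /
        (concentrations^true_hill + true_ec50^true_hill)
      eps <- stats::rnorm(length(concentrations), 0, noise_sd_fraction)
      data.frame(
        recording_id = sprintf("rec_%03d", r),
        batch_id = sprintf("batch_%02d", (r - 1) %/% recordings_per_batch + 1),
        concentration_M = concentrations,
        peak_uA = mu * (1 + eps),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(true_ec50 = true_ec50, true_hill = true_hill,
                               true_imax = true_imax)
    out
  })
}

#' Configuration for the current-trace simulator
#'
#' @param duration_s Trace length in seconds.
#' @param sampling_rate Hz (default 500, within the 0.5-1 kHz range used for
#'   two-electrode voltage-clamp acquisition).
#' @param window `c(start, end)` of the agonist application, seconds.
#' @param tau_activation Activation time constant, seconds (> 0).
#' @param tau_desensitization Optional desensitization time constant,
#'   seconds; `NULL` for non-desensitizing responses.
#' @param peak_amplitude Peak current in uA; negative for inward currents.
#' @param noise_sd Additive Gaussian noise SD in uA.
#' @param seed RNG seed.
#' @return `trace_sim_config` list.
#' @export
trace_sim_config <- function(duration_s = 10, sampling_rate = 500,
                             window = c(2, 7), tau_activation = 0.3,
                             tau_desensitization = NULL,
                             peak_amplitude = -5, noise_sd = 0, seed = 1) {
  assert_scalar(duration_s, "duration_s", positive = TRUE)
  assert_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot(length(window) == 2L, window[1] < window[2],
            window[1] >= 0, window[2] <= duration_s)
  assert_scalar(tau_activation, "tau_activation", positive = TRUE)
  if (!is.null(tau_desensitization)) {
    assert_scalar(tau_desensitization, "tau_desensitization", positive = TRUE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(duration_s = duration_s, sampling_rate = sampling_rate,
         window = window, tau_activation = tau_activation,
         tau_desensitization = tau_desensitization,
         peak_amplitude = peak_amplitude, noise_sd = noise_sd, seed = seed),
    class = "trace_sim_config"
  )
}

#' Simulate a current trace
#'
#' Baseline zero outside the application window. Inside, the current follows
#' a mono-exponential rise `(1 - exp(-t/tau_act))`, optionally multiplied by
#' an `exp(-t/tau_des)` desensitizing decay; white Gaussian noise is added
#' over the whole trace. With desensitization the biexponential is rescaled
#' so its analytic peak — at `t* = tau_act * log(1 + tau_des/tau_act)` after
#' application onset — equals `peak_amplitude` exactly; without it the
#' response asymptotes to `peak_amplitude`.
#'
#' @param config A [trace_sim_config()].
#' @return A `current_trace`: list with `time` (s), `current` (uA), `windows`
#'   (data frame start/end), and attribute `"true_peak"` (the noiseless
#'   analytic peak, signed).
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  with_seed(config$seed, {
    time <- seq(0, config$duration_s, by = 1 / config$sampling_rate)
    current <- numeric(length(time))
    inside <- time >= config$window[1] & time <= config$window[2]
    s <- time[inside] - config$window[1]
    ta <- config$tau_activation
    td <- config$tau_desensitization
    if (is.null(td)) {
      shape <- 1 - exp(-s / ta)
      true_peak <- config$peak_amplitude *
        (1 - exp(-diff(config$window) / ta))
      current[inside] <- config$peak_amplitude * shape
    } else {
      shape <- (1 - exp(-s / ta)) * exp(-s / td)
      t_star <- ta * log(1 + td / ta)
      peak_shape <- (1 - exp(-t_star / ta)) * exp(-t_star / td)
      current[inside] <- config$peak_amplitude * shape / peak_shape
      true_peak <- config$peak_amplitude
    }
    if (config$noise_sd > 0) {
      current <- current + stats::rnorm(length(current), 0, config$noise_sd)
    }
    structure(
      list(time = time, current = current,
           windows = data.frame(start = config$window[1], end = config$window[2])),
      class = "current_trace", true_peak = true_peak
    )
  })
}

#' Simulate paired-application recordings for the potency-ratio statistic
#'
#' Each recording holds two traces from the same simulated oocyte: a test
#' concentration (`conc_a`, default 3 uM) and a near-saturating concentration
#' (`conc_b`, default 30 uM). The true paired-response ratio is planted via
#' the trace amplitudes; amplitudes carry independent multiplicative noise.
#'
#' @param true_ratio Planted `|peak_a| / |peak_b|`.
#' @param n_recordings Number of paired recordings.
#' @param noise_sd_fraction Multiplicative amplitude noise SD.
#' @param base_peak_uA Amplitude at the saturating concentration
#'   (negative = inward; default -5).
#' @param conc_a,conc_b Molar concentrations, metadata only.
#' @param seed RNG seed.
#' @return List of recordings, each a list with `recording_id`, `trace_a`,
#'   `trace_b`, `conc_a`, `conc_b`.
#' @export
simulate_potency_ratio_traces <- function(true_ratio = 0.64, n_recordings = 14,
                                          noise_sd_fraction = 0.05,
                                          base_peak_uA = -5,
                                          conc_a = 3e-6, conc_b = 30e-6,
                                          seed = 1) {
  if (true_ratio < 0) stop("true_ratio must be >= 0", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_recordings), function(r) {
      amp_b <- base_peak_uA * (1 + stats::rnorm(1, 0, noise_sd_fraction))
      amp_a <- true_ratio * base_peak_uA * (1 + stats::rnorm(1, 0, noise_sd_fraction))
      seeds <- sample.int(1e6, 2)
      list(
        recording_id = sprintf("rec_%03d", r),
        trace_a = simulate_trace(trace_sim_config(
          peak_amplitude = amp_a, seed = seeds[1]
        )),
        trace_b = simulate_trace(trace_sim_config(
          peak_amplitude = amp_b, seed = seeds[2]
        )),
        conc_a = conc_a, conc_b = conc_b
      )
    })
  })
}

#' Simulate paired conditioning recordings for the fold-enhancement statistic
#'
#' Emulates the ASIC modulation protocol: per recording, a test-pulse current
#' after conditioning alone (`trace_a`) and after conditioning in the
#' presence of peptide (`trace_b`), with the planted fold
#' `|peak_b| / |peak_a|` and independent multiplicative amplitude noise.
#'
#' @param true_fold Planted enhancement (>= 0).
#' @param n_recordings Number of paired recordings.
#' @param noise_sd_fraction Multiplicative amplitude noise SD (default 0.10).
#' @param control_peak_uA Conditioned-alone test-pulse amplitude
#'   (default -0.1 uA, a strongly desensitized response).
#' @param seed RNG seed.
#' @return List of recordings, each with `recording_id`, `trace_a`, `trace_b`.
#' @export
simulate_enhancement_traces <- function(true_fold = 10, n_recordings = 7,
                                        noise_sd_fraction = 0.10,
                                        control_peak_uA = -0.1, seed = 1) {
  if (true_fold < 0) stop("true_fold must be >= 0", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_recordings), function(r) {
      amp_a <- control_peak_uA * (1 + stats::rnorm(1, 0, noise_sd_fraction))
      amp_b <- true_fold * control_peak_uA * (1 + stats::rnorm(1, 0, noise_sd_fraction))
      seeds <- sample.int(1e6, 2)
      list(
        recording_id = sprintf("rec_%03d", r),
        trace_a = simulate_trace(trace_sim_config(
          peak_amplitude = amp_a, seed = seeds[1]
        )),
        trace_b = simulate_trace(trace_sim_config(
          peak_amplitude = amp_b, seed = seeds[2]
        ))
      )
    })
  })
}

#' Extract paired peaks from paired-trace recordings
#'
#' Runs [measure_peak()] on both traces of every recording.
#'
#' @param pairs Output of [simulate_potency_ratio_traces()] or
#'   [simulate_enhancement_traces()] (or any list of the same shape).
#' @return Data frame `recording_id`, `peak_a`, `peak_b` (signed uA).
#' @export
peaks_from_pairs <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(
      recording_id = p$recording_id,
      peak_a = measure_peak(p$trace_a),
      peak_b = measure_peak(p$trace_b),
      stringsAsFactors = FALSE
    )
  }))
}
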