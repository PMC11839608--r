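#' Emotional-state labels and the activity-adjustment rule table
#'
#' The rule engine links spectral EEG features to five affective states and
#' each state to one activity adjustment with an intended outcome: elevated
#' beta power reads as stress/anxiety (prescribe relaxation), elevated alpha
#' as relaxation/low engagement (team sports), a depressed theta/alpha ratio
#' as cognitive overload or fatigue (lower intensity / rest), elevated theta
#' as focus (structured skill tasks), and jointly depressed beta and alpha as
#' lack of interest (high-energy activities).
#'
#' @return `emotion_states()`: character vector of the five labels.
#'   `adjustment_rules()`: tibble with columns `state`, `feature`,
#'   `direction`, `adjustment`, `target_outcome`.
#' @export
emotion_states <- function() {
  c("STRESS_ANXIETY", "RELAX_LOW_ENGAGEMENT", "OVERLOAD_FATIGUE",
    "FOCUS", "LACK_OF_INTEREST")
}

#' @rdname emotion_states
#' @export
adjustment_rules <- function() {
  tibble(
    state = c("STRESS_ANXIETY", "RELAX_LOW_ENGAGEMENT", "OVERLOAD_FATIGUE",
              "FOCUS", "LACK_OF_INTEREST"),
    feature = c("beta", "alpha", "ta_ratio", "theta", "beta_and_alpha"),
    direction = c("up", "up", "down", "up", "down"),
    adjustment = c("RELAXATION", "TEAM_SPORTS", "LOWER_INTENSITY_REST",
                   "STRUCTURED_SKILL", "HIGH_ENERGY"),
    target_outcome = c("Stress reduction", "Improved engagement",
                       "Prevent burnout", "Maintain engagement",
                       "Stimulate interest")
  )
}

#' Export the rule table as JSON for audit
#'
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rule_table <- function(path) {
  jsonlite::write_json(adjustment_rules(), path, pretty = TRUE)
  invisible(path)
}

#' Conventional EEG band definitions
#'
#' Theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz.
#'
#' @return named list of `c(lower, upper)` Hz pairs.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Per-state band-power signature of the synthetic EEG generator
#'
#' Rows are affective states (plus `REST`, the resting baseline), columns the
#' theta/alpha/beta band-power multipliers relative to rest. Values are
#' chosen so that, under the default 1.5x "up" and 0.67x "down" thresholds
#' and fatigue-first rule precedence, each state trips exactly its own rule:
#' e.g. the relaxation signature raises theta mildly (x1.35) alongside alpha
#' (x1.8) so the theta/alpha ratio does not dip below the fatigue threshold.
#'
#' @return numeric matrix 6 x 3 with dimnames.
#' @export
default_eeg_signature <- function() {
  m <- rbind(
    STRESS_ANXIETY       = c(1.00, 1.00, 4.00),
    RELAX_LOW_ENGAGEMENT = c(1.35, 1.80, 1.00),
    OVERLOAD_FATIGUE     = c(0.50, 1.20, 1.00),
    FOCUS                = c(2.50, 1.00, 1.00),
    LACK_OF_INTEREST     = c(0.40, 0.40, 0.40),
    REST                 = c(1.00, 1.00, 1.00)
  )
  colnames(m) <- c("theta", "alpha", "beta")
  m
}

new_eeg_trace <- function(samples, fs) {
  structure(list(samples = samples, fs = fs), class = "eeg_trace")
}

#' @export
print.eeg_trace <- function(x, ...) {
  cat(sprintf("<eeg_trace> %d samples x %d channel(s) @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' Synthesize an EEG trace with a state-specific band signature
#'
#' Builds band-limited oscillations (tones at 6, 10 and 20 Hz for theta,
#' alpha and beta) whose powers follow the row of `signature` for `state`,
#' plus optional broadband Gaussian noise at the requested signal-to-noise
#' ratio. Phases are randomized per channel from `seed`, so traces are
#' bit-reproducible for a fixed seed.
#'
#' @param state one of [emotion_states()] or `"REST"`.
#' @param duration seconds (`duration * fs >= 2` samples required).
#' @param fs sampling rate, Hz; must exceed 100 Hz so the 1-50 Hz content is
#'   well below Nyquist.
#' @param snr signal-to-broadband-noise power ratio; `Inf` for noiseless.
#' @param seed integer seed.
#' @param n_channels number of channels.
#' @param signature band-power multiplier matrix, see
#'   [default_eeg_signature()].
#' @param base_amplitude resting per-band tone amplitude, microvolts.
#' @return an `eeg_trace` object.
#' @export
synthesize_eeg <- function(state, duration = 8, fs = 256, snr = Inf,
                           seed = 1L, n_channels = 2L,
                           signature = default_eeg_signature(),
                           base_amplitude = 5) {
  if (!state %in% rownames(signature)) {
    abort(sprintf("unknown state `%s`.", state), class = "apeo_invalid_argument")
  }
  if (fs <= 100) {
    abort("`fs` must exceed 100 Hz to avoid aliasing of 1-50 Hz content.",
          class = "apeo_domain_error")
  }
  if (duration * fs < 2) {
    abort("`duration * fs` must be at least 2 samples.",
          class = "apeo_invalid_argument")
  }
  if (is.na(snr) || snr < 0) {
    abort("`snr` must be >= 0 (Inf for noiseless).",
          class = "apeo_invalid_argument")
  }
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  tone_freq <- c(theta = 6, alpha = 10, beta = 20)
  amps <- base_amplitude * sqrt(signature[state, ])
  with_seed(seed, {
    samples <- vapply(seq_len(n_channels), function(ch) {
      phases <- runif(3, 0, 2 * pi)
      sig <- amps["theta"] * sin(2 * pi * tone_freq["theta"] * tt + phases[1]) +
        amps["alpha"] * sin(2 * pi * tone_freq["alpha"] * tt + phases[2]) +
        amps["beta"] * sin(2 * pi * tone_freq["beta"] * tt + phases[3])
      if (is.finite(snr)) {
        sig_power <- sum(amps^2) / 2
        noise_sd <- if (snr == 0) 0 else sqrt(sig_power / snr)
        sig <- sig + rnorm(n, 0, noise_sd)
      }
      sig
    }, numeric(n))
    new_eeg_trace(samples, fs)
  })
}

#' Band-pass filter an EEG trace
#'
#' Zero-phase (forward-backward) Butterworth filtering, implemented as a
#' cascade of a 2nd-order high-pass at `low` and a 2nd-order low-pass at
#' `high`. The cascade is numerically stabler than a single high-order
#' band-pass at the very small normalized lower edge typical for EEG
#' (1 Hz at 256 Hz sampling) and attenuates by more than 20 dB one octave
#' outside the band.
#'
#' @param trace an `eeg_trace`.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @return filtered `eeg_trace`.
#' @export
bandpass_filter <- function(trace, low = 1, high = 50) {
  fs <- trace$fs
  if (!(low > 0 && high > low && high < fs / 2)) {
    abort("band edges must satisfy 0 < low < high < fs/2.",
          class = "apeo_domain_error")
  }
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  lp <- signal::butter(2, high / (fs / 2), type = "low")
  filt <- apply(trace$samples, 2, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  })
  new_eeg_trace(matrix(filt, nrow = nrow(trace$samples)), fs)
}

# Welch power spectral density: Hann-windowed overlapping segments, one-sided
# density normalized so that sum(psd) * df equals the signal's mean power.
psd_welch <- function(x, fs, window_sec = 2, overlap = 0.5) {
  nper <- round(window_sec * fs)
  nper <- min(nper, length(x))
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nper) - 1) / (nper - 1))
  u <- sum(w^2)
  nfreq <- nper %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)] * w
    sp <- abs(fft(seg))^2
    acc <- acc + sp[seq_len(nfreq)]
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double all bins except DC (and Nyquist when nper is even)
  scale2 <- rep(2, nfreq)
  scale2[1] <- 1
  if (nper %% 2 == 0) scale2[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1) * fs / nper, psd = psd * scale2,
       df = fs / nper)
}

#' Band powers and the theta/alpha ratio
#'
#' Integrates the Welch power spectral density (2 s Hann windows, 50 %
#' overlap) over each requested band, averaged across channels.
#'
#' @param trace an `eeg_trace`, at least 2 s long.
#' @param bands named list of `c(lower, upper)` Hz pairs; defaults to
#'   [eeg_bands()].
#' @return a one-row tibble with `<band>_power` columns (uV^2) and
#'   `ta_ratio` (NA when alpha power is exactly zero, flagged by the
#'   `"ta_undefined"` attribute rather than silently reported as 0).
#' @export
band_powers <- function(trace, bands = eeg_bands()) {
  if (length(bands) == 0) {
    abort("`bands` must name at least one band.", class = "apeo_invalid_argument")
  }
  fs <- trace$fs
  if (nrow(trace$samples) < 2 * fs) {
    abort("trace must be at least 2 seconds long for spectral estimation.",
          class = "apeo_invalid_argument")
  }
  hi <- max(vapply(bands, max, numeric(1)))
  if (hi >= fs / 2 || min(vapply(bands, min, numeric(1))) <= 0) {
    abort("bands must lie strictly within (0, fs/2).", class = "apeo_domain_error")
  }
  per_channel <- apply(trace$samples, 2, function(x) {
    sp <- psd_welch(x, fs)
    vapply(bands, function(b) {
      sel <- sp$freq >= b[1] & sp$freq < b[2]
      sum(sp$psd[sel]) * sp$df
    }, numeric(1))
  })
  pow <- rowMeans(matrix(per_channel, nrow = length(bands)))
  names(pow) <- names(bands)
  out <- as_tibble(as.list(pow))
  names(out) <- paste0(names(bands), "_power")
  ta_undefined <- FALSE
  if (all(c("theta", "alpha") %in% names(bands))) {
    if (pow[["alpha"]] > 0) {
      out$ta_ratio <- pow[["theta"]] / pow[["alpha"]]
    } else {
      out$ta_ratio <- NA_real_
      ta_undefined <- TRUE
    }
  }
  attr(out, "ta_undefined") <- ta_undefined
  out
}

#' Threshold multipliers for the rule engine
#'
#' A feature counts as elevated when its ratio to the resting baseline
#' exceeds `up`, depressed when below `down`.
#'
#' @param up,down ratio thresholds (`down < 1 < up`).
#' @return named list.
#' @export
emotion_thresholds <- function(up = 1.5, down = 0.67) {
  stopifnot(down < 1, up > 1)
  list(up = up, down = down)
}

#' Classify affective state from band-power features
#'
#' Applies the rule table of [adjustment_rules()] with a fixed precedence
#' (configurable): the fatigue rule (theta/alpha ratio depressed) fires
#' first as the safety-critical condition, then elevated beta (stress),
#' elevated theta (focus), elevated alpha (relaxation / low engagement), and
#' finally jointly depressed beta and alpha (lack of interest). Elevation
#' and depression are ratios of the measured band power to a per-participant
#' resting baseline. When no rule fires, the neutral sentinel `"NONE"` is
#' returned with a warning.
#'
#' @param features,baseline one-row tibbles from [band_powers()]; baseline
#'   powers must be strictly positive.
#' @param thresholds from [emotion_thresholds()].
#' @param precedence character vector ordering the five states.
#' @return a single state label (or `"NONE"`).
#' @export
classify_emotion <- function(features, baseline,
                             thresholds = emotion_thresholds(),
                             precedence = c("OVERLOAD_FATIGUE",
                                            "STRESS_ANXIETY", "FOCUS",
                                            "RELAX_LOW_ENGAGEMENT",
                                            "LACK_OF_INTEREST")) {
  base <- c(theta = baseline$theta_power, alpha = baseline$alpha_power,
            beta = baseline$beta_power)
  if (any(base <= 0)) {
    abort("baseline band powers must be strictly positive.",
          class = "apeo_domain_error")
  }
  rel <- c(
    theta = features$theta_power / base[["theta"]],
    alpha = features$alpha_power / base[["alpha"]],
    beta = features$beta_power / base[["beta"]]
  )
  base_ta <- base[["theta"]] / base[["alpha"]]
  rel_ta <- if (!is.null(features$ta_ratio) && !is.na(features$ta_ratio)) {
    features$ta_ratio / base_ta
  } else {
    NA_real_
  }
  fires <- function(state) {
    switch(state,
      OVERLOAD_FATIGUE = !is.na(rel_ta) && rel_ta < thresholds$down,
      STRESS_ANXIETY = rel[["beta"]] > thresholds$up,
      FOCUS = rel[["theta"]] > thresholds$up,
      RELAX_LOW_ENGAGEMENT = rel[["alpha"]] > thresholds$up,
      LACK_OF_INTEREST = rel[["beta"]] < thresholds$down &&
        rel[["alpha"]] < thresholds$down,
      FALSE
    )
  }
  for (state in precedence) {
    if (fires(state)) return(state)
  }
  warn("no classification rule fired; returning sentinel NONE.")
  "NONE"
}

#' Activity adjustment for an affective state
#'
#' Bijective map from state to adjustment per the rule table. The `"NONE"`
#' sentinel yields a no-recommendation row (NA adjustment) rather than an
#' error.
#'
#' @param state a state label.
#' @return one-row tibble with `state`, `adjustment`, `target_outcome`.
#' @export
recommend_adjustment <- function(state) {
  if (identical(state, "NONE")) {
    return(tibble(state = "NONE", adjustment = NA_character_,
                  target_outcome = NA_character_))
  }
  rules <- adjustment_rules()
  row <- rules[rules$state == state, ]
  if (nrow(row) == 0) {
    abort(sprintf("unknown state `%s`.", state), class = "apeo_invalid_argument")
  }
  dplyr::select(row, "state", "adjustment", "target_outcome")
}

#' Write / read an EEG trace as CSV
#'
#' Channels are columns with a header row; the sampling rate is carried in a
#' leading `# fs: <Hz>` comment line.
#'
#' @param trace an `eeg_trace`.
#' @param path CSV file path.
#' @return `write_eeg_csv` returns `path` invisibly; `read_eeg_csv` an
#'   `eeg_trace`.
#' @export
write_eeg_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %g", trace$fs), con)
  df <- as.data.frame(trace$samples)
  names(df) <- paste0("ch", seq_len(ncol(df)))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @param fs sampling rate override when the sidecar comment is absent.
#' @export
read_eeg_csv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^# fs:", first)) {
    fs <- as.numeric(sub("^# fs:\\s*", "", first))
    df <- utils::read.csv(path, comment.char = "#")
  } else {
    if (is.null(fs)) {
      abort("no `# fs:` sidecar line; supply `fs`.", class = "apeo_config_error")
    }
    df <- utils::read.csv(path)
  }
  new_eeg_trace(as.matrix(df), fs)
}
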