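#' Simulation configuration
#'
#' Assembles the parameter blocks of every module into one validated run
#' configuration. `policy` selects how interventions are chosen each step:
#' `"random"` (uniform over the action grid), `"pid_only"` (PID tracking of
#' the fitness target, modality from the rule engine), `"rl"` (online
#' epsilon-greedy Q-learning over classified affective states), or
#' `"rl_feedback"` (`"rl+feedback"` is accepted as an alias: Q-learning
#' plus fatigue-risk gating of intensity).
#'
#' @param horizon number of steps (>= 0).
#' @param n cohort size.
#' @param seed master seed; every stream in the run derives from it.
#' @param policy see above.
#' @param cohort an [cohort_config()].
#' @param gains PID gains, see [pid_gains()].
#' @param gamification a [gamification_params()].
#' @param fb a [feedback_params()].
#' @param weights a [reward_weights()].
#' @param eeg list with `duration` (s), `fs` (Hz), `snr`, `n_channels` for
#'   the per-step EEG synthesis.
#' @param disturbance_scale standard deviation of the fitness disturbance.
#' @param target_fitness constant fitness target tracked by the loop.
#' @param e_min engagement floor counted as a constraint violation.
#' @param intensities intensity grid available to the policies.
#' @param gate_fatigue logical; `NULL` derives it from the policy
#'   (`TRUE` only for `rl_feedback`).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(horizon = 100L, n = 5L, seed = 1L,
                              policy = c("rl", "random", "pid_only",
                                         "rl_feedback", "rl+feedback"),
                              cohort = cohort_config(),
                              gains = pid_gains(kp = 0.5, ki = 0.1, dt = 1,
                                                i_max = 1),
                              gamification = gamification_params(alpha_decay = 0.7),
                              fb = feedback_params(tau_fatigue = 0.8),
                              weights = reward_weights(),
                              eeg = list(duration = 2, fs = 128, snr = 25,
                                         n_channels = 1L),
                              disturbance_scale = 0.01,
                              target_fitness = 0.2,
                              e_min = 0.2,
                              intensities = c(0.2, 0.5, 0.8),
                              gate_fatigue = NULL) {
  policy <- match.arg(policy)
  if (policy == "rl+feedback") policy <- "rl_feedback"
  check_scalar_number(horizon, "horizon", lower = 0)
  check_scalar_number(n, "n", lower = 1)
  bad_eeg <- setdiff(names(eeg), c("duration", "fs", "snr", "n_channels"))
  if (length(bad_eeg) > 0) {
    abort(sprintf("unknown eeg config key(s): %s",
                  paste(bad_eeg, collapse = ", ")),
          class = "apeo_config_error")
  }
  if (is.null(gate_fatigue)) gate_fatigue <- policy == "rl_feedback"
  structure(list(horizon = as.integer(horizon), n = as.integer(n),
                 seed = seed, policy = policy, cohort = cohort,
                 gains = gains, gamification = gamification, fb = fb,
                 weights = weights, eeg = eeg,
                 disturbance_scale = disturbance_scale,
                 target_fitness = target_fitness, e_min = e_min,
                 intensities = intensities, gate_fatigue = gate_fatigue),
            class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys mirror the arguments of [simulation_config()]; unknown
#' keys are rejected.
#'
#' @param path YAML file.
#' @return a `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- normalize_yaml_names(yaml::read_yaml(path))
  known <- c("horizon", "n", "seed", "policy", "disturbance_scale",
             "target_fitness", "e_min", "intensities", "gate_fatigue", "eeg")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown simulation config key(s): %s",
                  paste(bad, collapse = ", ")),
          class = "apeo_config_error")
  }
  do.call(simulation_config, raw)
}

adjustment_to_modality <- function(adjustment) {
  if (is.null(adjustment) || is.na(adjustment)) return("aerobic")
  switch(adjustment,
         RELAXATION = "relaxation", TEAM_SPORTS = "team",
         LOWER_INTENSITY_REST = "relaxation", STRUCTURED_SKILL = "skill",
         HIGH_ENERGY = "high_energy", "aerobic")
}

# Latent affective state of the participant model: fatigue dominates, then
# over-intense prescriptions read as stress, disengagement as lack of
# interest, high engagement as focus, the rest as relaxed/low engagement.
latent_emotion <- function(engagement, fatigue, intensity_prev, comfort) {
  if (fatigue > 0.7) return("OVERLOAD_FATIGUE")
  if (intensity_prev - comfort > 0.25) return("STRESS_ANXIETY")
  if (engagement < 0.35) return("LACK_OF_INTEREST")
  if (engagement > 0.75) return("FOCUS")
  "RELAX_LOW_ENGAGEMENT"
}

#' Run the closed-loop simulation
#'
#' Executes the monitor-classify-act cycle for `horizon` steps: per
#' participant, a synthetic EEG trace reflecting the latent affective state
#' is synthesized, band-pass filtered to 1-50 Hz, reduced to band powers,
#' classified against the participant's resting baseline, and mapped to an
#' activity adjustment; the configured policy then selects intensity and
#' modality, fatigue gating optionally intervenes, states evolve under the
#' linear intervention/disturbance dynamics with gamified reward-driven
#' engagement decay, and everything is logged. Bit-reproducible for a fixed
#' configuration (all randomness derives from `config$seed`).
#'
#' @param config a [simulation_config()].
#' @return an `apeo_run`: `timeseries` tibble (one row per participant per
#'   step), `summary` list, `config`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n
  horizon <- config$horizon
  cohort <- generate_profiles(n, config$cohort, seed = config$seed)
  comfort <- pmin(0.9, pmax(0.1, 0.2 + 0.6 * cohort$enjoyment))
  mods <- activity_modalities()
  n_mod <- length(mods)
  ints <- config$intensities
  n_act <- n_mod * length(ints)
  emo_levels <- c(emotion_states(), "NONE")

  # resting baselines, one per participant, from each private stream
  baselines <- lapply(seq_len(n), function(i) {
    tr <- synthesize_eeg("REST", config$eeg$duration, config$eeg$fs,
                         config$eeg$snr, seed = derive_seed(cohort$rng_seed[i], 0),
                         n_channels = config$eeg$n_channels,
                         signature = cohort$eeg_signature[[i]])
    band_powers(bandpass_filter(tr))
  })

  disturb <- generate_disturbances(max(1L, horizon), config$disturbance_scale,
                                   seed = derive_seed(config$seed, 999983L),
                                   dim = n)

  dyn <- state_dynamics(
    w_s = matrix(c(0.04, 0, 0, 0, 0, 0.05), nrow = 3),  # u = (intensity, E - 0.5)
    d_s = matrix(c(1, 0, 0), nrow = 3)
  )

  fitness <- rep(0, n)
  engagement <- rep(0.5, n)
  adherence <- rep(0.8, n)
  fatigue <- rep(0, n)
  cum_reward <- rep(0, n)
  last_r_norm <- rep(0.5, n)
  intensity_prev <- rep(0.5, n)
  err_hist <- rep(list(numeric()), n)
  pending <- rep(list(NULL), n)
  q <- q_table(length(emo_levels), n_act, eta_lr = 0.5, gamma_discount = 0.3)
  emo_counts <- stats::setNames(rep(0, length(emo_levels)), emo_levels)

  rows <- vector("list", horizon * n)
  risk_steps <- 0L
  ri <- 0L

  with_seed(derive_seed(config$seed, 424243L), {
    for (t in seq_len(horizon)) {
      eps <- max(0.05, 0.5 * 0.97^t)
      for (i in seq_len(n)) {
        true_emotion <- latent_emotion(engagement[i], fatigue[i],
                                       intensity_prev[i], comfort[i])
        tr <- synthesize_eeg(true_emotion, config$eeg$duration, config$eeg$fs,
                             config$eeg$snr,
                             seed = derive_seed(cohort$rng_seed[i], t),
                             n_channels = config$eeg$n_channels,
                             signature = cohort$eeg_signature[[i]])
        feats <- band_powers(bandpass_filter(tr))
        obs_emotion <- suppressWarnings(classify_emotion(feats, baselines[[i]]))
        rec <- recommend_adjustment(obs_emotion)
        rec_mod <- adjustment_to_modality(rec$adjustment %||% NA_character_)
        s_now <- match(obs_emotion, emo_levels)
        emo_counts[obs_emotion] <- emo_counts[obs_emotion] + 1

        # settle any pending individual Q-learning transition
        if (!is.null(pending[[i]])) {
          p <- pending[[i]]
          q <- q_update(q, p$s, p$a, p$r, s_now)
          pending[i] <- list(NULL)
        }

        e_fit <- performance_error(config$target_fitness, fitness[i])
        err_hist[[i]] <- c(err_hist[[i]], e_fit)

        action <- NA_integer_
        if (config$policy == "random") {
          action <- sample.int(n_act, 1L)
          modality <- mods[(action - 1L) %% n_mod + 1L]
          intensity <- ints[(action - 1L) %/% n_mod + 1L]
        } else if (config$policy == "pid_only") {
          u_pid <- pid_control(utils::tail(err_hist[[i]], 100L), config$gains)
          intensity <- as.numeric(clamp(0.5 + u_pid, min(ints), max(ints)))
          modality <- rec_mod
        } else {
          action <- if (runif(1) < eps) sample.int(n_act, 1L)
                    else greedy_action(q, s_now)
          modality <- mods[(action - 1L) %% n_mod + 1L]
          intensity <- ints[(action - 1L) %/% n_mod + 1L]
        }

        risk <- fatigue_risk(fatigue[i], abs(intensity_prev[i] - comfort[i]),
                             last_r_norm[i], config$fb)
        if (risk > config$fb$tau_fatigue) risk_steps <- risk_steps + 1L
        gated <- FALSE
        if (config$gate_fatigue && risk > config$fb$tau_fatigue) {
          intensity <- as.numeric(adjust_intensity(
            intensity, abs(intensity - comfort[i]) + fatigue[i], risk,
            config$fb))
          gated <- TRUE
        }

        task <- as.numeric(clamp(
          0.3 * (1 - abs(intensity - comfort[i]) / 0.8) +
            0.7 * (modality == rec_mod), 0, 1))
        rew <- compute_reward(task, engagement[i], config$gamification)
        r_norm <- as.numeric(clamp(rew$reward / 2, 0, 1))
        cum_reward[i] <- cum_reward[i] + rew$reward
        last_r_norm[i] <- r_norm

        s_state <- participant_state(fitness[i], engagement[i], adherence[i],
                                     t = t - 1L)
        s_new <- evolve_state(s_state,
                              u = c(intensity, engagement[i] - 0.5),
                              d = disturb[t, i], dyn)
        # controlled update summed with the autonomous first-order
        # relaxation toward baseline at the participant's time constant
        fitness[i] <- relax_towards_target(s_new$fitness, 0,
                                           tau = cohort$tau[i], t = 1)
        adherence[i] <- s_new$adherence
        engagement[i] <- as.numeric(clamp(
          decay_engagement(s_new$engagement, r_norm,
                           config$gamification$alpha_decay), 0, 1))
        fatigue[i] <- max(0, 0.9 * fatigue[i] + 0.3 * intensity - 0.05)
        intensity_prev[i] <- intensity

        r_rl <- step_reward(engagement[i], scalarize_fitness(fitness[i]),
                            config$weights$gamma1 * intensity^2 +
                              config$weights$gamma2 * 30,
                            config$weights)
        if (config$policy %in% c("rl", "rl_feedback") && !is.na(action)) {
          pending[[i]] <- list(s = s_now, a = action, r = r_rl)
        }

        ri <- ri + 1L
        rows[[ri]] <- tibble(
          t = t, participant_id = cohort$id[i],
          emotion_true = true_emotion, emotion_observed = obs_emotion,
          adjustment = rec$adjustment, modality = modality,
          intensity = intensity, duration = 30,
          fitness = fitness[i], engagement = engagement[i],
          adherence = adherence[i], fatigue = fatigue[i],
          u_intensity = intensity, d = disturb[t, i], e_fitness = e_fit,
          task_score = task, reward = rew$reward, risk = risk, gated = gated
        )
      }
    }
    # flush pending transitions (terminal, no bootstrap)
    for (i in seq_len(n)) {
      if (!is.null(pending[[i]])) {
        p <- pending[[i]]
        q <- q_update(q, p$s, p$a, p$r, NA)
      }
    }
  })

  ts <- if (ri > 0) dplyr::bind_rows(rows[seq_len(ri)]) else empty_timeseries()

  summary <- summarize_run(ts, emo_counts, config, risk_steps)
  structure(list(timeseries = ts, summary = summary, config = config, q = q),
            class = "apeo_run")
}

empty_timeseries <- function() {
  tibble(t = integer(), participant_id = integer(), emotion_true = character(),
         emotion_observed = character(), adjustment = character(),
         modality = character(), intensity = numeric(), duration = numeric(),
         fitness = numeric(), engagement = numeric(), adherence = numeric(),
         fatigue = numeric(), u_intensity = numeric(), d = numeric(),
         e_fitness = numeric(), task_score = numeric(), reward = numeric(),
         risk = numeric(), gated = logical())
}

summarize_run <- function(ts, emo_counts, config, risk_steps) {
  if (nrow(ts) == 0) {
    return(list(mean_engagement = 0, mean_cohesion = 0,
                constraint_violations = 0, cumulative_reward = 0,
                mental_health_index = 0, risk_steps = 0,
                horizon = config$horizon, n = config$n,
                policy = config$policy, seed = config$seed))
  }
  coh <- ts |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(l = cohesion_loss(cbind(.data$fitness, .data$engagement,
                                             .data$adherence)),
                     .groups = "drop")
  hist <- rep(names(emo_counts), emo_counts)
  list(
    mean_engagement = mean(ts$engagement),
    mean_cohesion = mean(coh$l),
    constraint_violations = sum(ts$engagement < config$e_min),
    cumulative_reward = sum(ts$reward),
    mental_health_index = mental_health_index(hist),
    risk_steps = risk_steps,
    horizon = config$horizon, n = config$n,
    policy = config$policy, seed = config$seed
  )
}

#' Occupancy-weighted mental-health index
#'
#' Reduces a history of classified affective states to a `[0, 1]` index:
#' the state occupancies (relative frequencies) are weighted and summed.
#' Default weights rank stress/anxiety and overload/fatigue as adverse and
#' focus as most favourable. The mapping from affective states to a mental
#' health score is a deliberately simple stand-in read-out: no validated
#' model links the two, and the index should be interpreted only as a
#' monotone summary of the state mix.
#'
#' @param emotion_history character vector of state labels (may include
#'   `"NONE"`).
#' @param weights named weight vector over states, each in `[0, 1]`.
#' @return index in `[0, 1]`.
#' @export
mental_health_index <- function(emotion_history,
                                weights = c(STRESS_ANXIETY = 0,
                                            OVERLOAD_FATIGUE = 0.2,
                                            LACK_OF_INTEREST = 0.35,
                                            RELAX_LOW_ENGAGEMENT = 0.7,
                                            FOCUS = 1, NONE = 0.6)) {
  if (length(emotion_history) == 0) {
    abort("`emotion_history` must be non-empty.",
          class = "apeo_invalid_argument")
  }
  occ <- table(factor(emotion_history, levels = names(weights)))
  occ <- occ / sum(occ)
  sum(weights * as.numeric(occ))
}

#' Write a run report to disk
#'
#' Emits `timeseries.csv` and `summary.json` (full-precision, so the JSON
#' round-trips to the in-memory summary exactly) and, optionally, an
#' engagement plot.
#'
#' @param run an `apeo_run`.
#' @param out_dir output directory (created if missing).
#' @param plots also write `engagement.pdf`.
#' @return named character vector of the files written, invisibly.
#' @export
report <- function(run, out_dir, plots = FALSE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create `%s`.", out_dir), class = "apeo_io_error")
  }
  ts_path <- file.path(out_dir, "timeseries.csv")
  sm_path <- file.path(out_dir, "summary.json")
  readr::write_csv(run$timeseries, ts_path)
  jsonlite::write_json(run$summary, sm_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(timeseries = ts_path, summary = sm_path)
  if (plots && nrow(run$timeseries) > 0) {
    p_path <- file.path(out_dir, "engagement.pdf")
    ggplot2::ggsave(p_path, autoplot(run), width = 7, height = 4)
    files <- c(files, plot = p_path)
  }
  invisible(files)
}
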