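#' Activity modalities
#'
#' The default modality set mirrors the activity adjustments of the rule
#' table: aerobic, team, skill, relaxation and high-energy activities.
#'
#' @return character vector of modalities.
#' @export
activity_modalities <- function() {
  c("aerobic", "team", "skill", "relaxation", "high_energy")
}

#' Box constraints on activity parameters
#'
#' @param i_min,i_max intensity bounds (unitless, default `[0, 1]`).
#' @param d_min,d_max duration bounds in minutes.
#' @param modalities allowed modality set.
#' @return an `activity_bounds` list.
#' @export
activity_bounds <- function(i_min = 0, i_max = 1, d_min = 5, d_max = 60,
                            modalities = activity_modalities()) {
  stopifnot(i_min < i_max, d_min < d_max, length(modalities) >= 1)
  structure(list(i_min = i_min, i_max = i_max, d_min = d_min, d_max = d_max,
                 modalities = modalities),
            class = "activity_bounds")
}

#' Activity parameter triple
#'
#' Intensity, duration and modality, validated against box constraints at
#' construction.
#'
#' @param intensity,duration numeric parameters.
#' @param modality member of the bounds' modality set.
#' @param bounds an [activity_bounds()].
#' @return an `activity_params` list.
#' @export
activity_params <- function(intensity, duration, modality,
                            bounds = activity_bounds()) {
  if (intensity < bounds$i_min || intensity > bounds$i_max) {
    abort(sprintf("intensity %.3g outside [%g, %g].", intensity,
                  bounds$i_min, bounds$i_max),
          class = "apeo_constraint_error")
  }
  if (duration < bounds$d_min || duration > bounds$d_max) {
    abort(sprintf("duration %.3g outside [%g, %g].", duration,
                  bounds$d_min, bounds$d_max),
          class = "apeo_constraint_error")
  }
  if (!modality %in% bounds$modalities) {
    abort(sprintf("modality `%s` not in {%s}.", modality,
                  paste(bounds$modalities, collapse = ", ")),
          class = "apeo_constraint_error")
  }
  structure(list(intensity = intensity, duration = duration,
                 modality = modality, bounds = bounds),
            class = "activity_params")
}

#' Activity loss against a fitness target
#'
#' `L = sum_k ||F_target - F_actual(I_k, D_k, M_k)||^2` over a sequence of
#' activities.
#'
#' @param f_target target fitness vector.
#' @param f_actual_fn function `activity_params -> fitness vector`.
#' @param activities list of [activity_params()].
#' @return non-negative loss.
#' @export
activity_loss <- function(f_target, f_actual_fn, activities) {
  sum(vapply(activities, function(a) {
    fa <- f_actual_fn(a)
    check_same_length(f_target, fa, "f_target", "f_actual")
    sum((f_target - fa)^2)
  }, numeric(1)))
}

#' Reward weights for the personalization agent
#'
#' @param alpha1,alpha2 weights on engagement and (scalarized) fitness.
#' @param beta_effort weight on the effort cost.
#' @param gamma1,gamma2 effort scaling for intensity (quadratic) and
#'   duration (linear).
#' @return a `reward_weights` list.
#' @export
reward_weights <- function(alpha1 = 1, alpha2 = 1, beta_effort = 0.1,
                           gamma1 = 1, gamma2 = 0.01) {
  for (nm in c("alpha1", "alpha2", "beta_effort", "gamma1", "gamma2")) {
    check_scalar_number(get(nm), nm, lower = 0)
  }
  structure(list(alpha1 = alpha1, alpha2 = alpha2, beta_effort = beta_effort,
                 gamma1 = gamma1, gamma2 = gamma2),
            class = "reward_weights")
}

#' Physical-effort cost of activities
#'
#' `C = sum_k (gamma1 I_k^2 + gamma2 D_k)`; strictly increasing in
#' intensity and duration for positive scalings.
#'
#' @param params one [activity_params()] or a list of them.
#' @param weights a [reward_weights()].
#' @return non-negative cost.
#' @export
effort_cost <- function(params, weights = reward_weights()) {
  if (inherits(params, "activity_params")) params <- list(params)
  sum(vapply(params, function(a) {
    weights$gamma1 * a$intensity^2 + weights$gamma2 * a$duration
  }, numeric(1)))
}

#' Immediate personalization reward
#'
#' Reward `alpha1 E + alpha2 F - beta C_effort`, with `F` the scalarized
#' fitness (mean of standardized components, see [scalarize_fitness()]).
#'
#' @param engagement engagement level `E`.
#' @param fitness_scalar scalarized fitness `F`.
#' @param effort effort cost `C_effort`.
#' @param weights a [reward_weights()].
#' @return scalar reward.
#' @export
step_reward <- function(engagement, fitness_scalar, effort,
                        weights = reward_weights()) {
  weights$alpha1 * engagement + weights$alpha2 * fitness_scalar -
    weights$beta_effort * effort
}

#' Scalarize a fitness vector
#'
#' The reward uses a scalar fitness term while states carry a vector; the
#' reduction used throughout is the mean of the (already standardized)
#' components.
#'
#' @param fitness fitness vector.
#' @return scalar.
#' @export
scalarize_fitness <- function(fitness) mean(fitness)

#' Tabular state-action value function
#'
#' Dense table over discretized states and actions; unseen pairs hold the
#' configured initial value.
#'
#' @param n_states,n_actions table dimensions.
#' @param eta_lr learning rate in (0, 1].
#' @param gamma_discount discount factor in `[0, 1)`.
#' @param init initial value for every entry.
#' @return an `apeo_qtable`.
#' @export
q_table <- function(n_states, n_actions, eta_lr = 0.5, gamma_discount = 0.9,
                    init = 0) {
  if (eta_lr <= 0 || eta_lr > 1) {
    abort("`eta_lr` must lie in (0, 1].", class = "apeo_invalid_argument")
  }
  if (gamma_discount < 0 || gamma_discount >= 1) {
    abort("`gamma_discount` must lie in [0, 1).", class = "apeo_invalid_argument")
  }
  structure(list(values = matrix(init, n_states, n_actions),
                 eta_lr = eta_lr, gamma_discount = gamma_discount),
            class = "apeo_qtable")
}

#' One-step Q-learning update
#'
#' `Q(s,a) <- Q(s,a) + eta [r + gamma max_a' Q(s',a') - Q(s,a)]`; only the
#' `(s, a)` entry changes. With learning rate 1 and deterministic
#' transitions repeated sweeps coincide with asynchronous value iteration.
#'
#' @param q an [q_table()].
#' @param s,a current state and action indices (1-based).
#' @param r immediate reward.
#' @param s_next successor state index, or `NA` for terminal transitions
#'   (no bootstrap term).
#' @return the updated `apeo_qtable`.
#' @export
q_update <- function(q, s, a, r, s_next) {
  v <- q$values
  if (s < 1 || s > nrow(v) || a < 1 || a > ncol(v)) {
    abort("state or action index outside the table.", class = "apeo_index_error")
  }
  boot <- if (is.na(s_next)) 0 else q$gamma_discount * max(v[s_next, ])
  v[s, a] <- v[s, a] + q$eta_lr * (r + boot - v[s, a])
  q$values <- v
  q
}

#' Greedy action with deterministic tie-breaking
#'
#' Ties resolve to the lowest action index; `mask` (logical) excludes
#' infeasible actions from the argmax.
#'
#' @param q an `apeo_qtable`; `s` state index.
#' @param s state index.
#' @param mask optional logical vector over actions (TRUE = allowed).
#' @return action index.
#' @export
greedy_action <- function(q, s, mask = NULL) {
  vals <- q$values[s, ]
  if (!is.null(mask)) {
    if (!any(mask)) {
      abort("no feasible action remains after masking.",
            class = "apeo_infeasible_error")
    }
    vals[!mask] <- -Inf
  }
  which.max(vals)  # which.max returns the first (lowest index) maximum
}

#' Exponentially decaying epsilon schedule
#'
#' @param eps0 initial exploration rate; `eps_min` floor; `rate` per-episode
#'   decay multiplier.
#' @param eps_min,rate see above.
#' @return function `episode -> epsilon`.
#' @export
eps_exp_decay <- function(eps0 = 0.5, eps_min = 0.05, rate = 0.97) {
  if (eps0 < 0 || eps0 > 1 || eps_min < 0 || eps_min > eps0 ||
      rate <= 0 || rate > 1) {
    abort("invalid epsilon schedule.", class = "apeo_config_error")
  }
  function(episode) max(eps_min, eps0 * rate^(episode - 1))
}

#' Train a personalization policy by epsilon-greedy Q-learning
#'
#' Runs episodic Q-learning against a simulated environment. An environment
#' is a list with `n_states`, `n_actions`, `reset()` returning the initial
#' state index, and `step(s, a)` returning
#' `list(state =, reward =, done =)`. Exploration follows the supplied
#' epsilon schedule; behaviour is deterministic for a fixed seed.
#'
#' @param env environment list as described above.
#' @param episodes number of episodes (>= 1).
#' @param steps_per_episode horizon per episode.
#' @param q initial [q_table()] (default 5 x `n_actions`-sized from env).
#' @param epsilon_schedule function `episode -> epsilon`, e.g.
#'   [eps_exp_decay()].
#' @param seed integer seed.
#' @return an `apeo_policy`: `q` (trained table) and `returns` tibble
#'   (`episode`, `return`, `epsilon`); supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
train_policy <- function(env, episodes, steps_per_episode = 50L, q = NULL,
                         epsilon_schedule = eps_exp_decay(), seed = 1L) {
  if (episodes < 1) {
    abort("`episodes` must be >= 1.", class = "apeo_invalid_argument")
  }
  if (!is.function(epsilon_schedule)) {
    abort("`epsilon_schedule` must be a function of the episode index.",
          class = "apeo_config_error")
  }
  if (is.null(q)) q <- q_table(env$n_states, env$n_actions)
  returns <- numeric(episodes)
  eps_used <- numeric(episodes)
  with_seed(seed, {
    for (ep in seq_len(episodes)) {
      eps <- epsilon_schedule(ep)
      eps_used[ep] <- eps
      s <- env$reset()
      total <- 0
      for (k in seq_len(steps_per_episode)) {
        a <- if (runif(1) < eps) sample.int(env$n_actions, 1L)
             else greedy_action(q, s)
        out <- env$step(s, a)
        total <- total + out$reward
        q <- q_update(q, s, a, out$reward,
                      if (isTRUE(out$done)) NA else out$state)
        if (isTRUE(out$done)) break
        s <- out$state
      }
      returns[ep] <- total
    }
  })
  structure(list(q = q,
                 returns = tibble(episode = seq_len(episodes),
                                  return = returns, epsilon = eps_used)),
            class = "apeo_policy")
}

#' Evaluate a policy's mean return on an environment
#'
#' @param env environment list (see [train_policy()]).
#' @param q an `apeo_qtable` for greedy play, or `NULL` for the uniform
#'   random policy.
#' @param episodes,steps_per_episode evaluation horizon.
#' @param seed integer seed.
#' @return mean per-episode return.
#' @export
evaluate_policy <- function(env, q = NULL, episodes = 10L,
                            steps_per_episode = 50L, seed = 1L) {
  with_seed(seed, {
    mean(vapply(seq_len(episodes), function(ep) {
      s <- env$reset()
      total <- 0
      for (k in seq_len(steps_per_episode)) {
        a <- if (is.null(q)) sample.int(env$n_actions, 1L)
             else greedy_action(q, s)
        out <- env$step(s, a)
        total <- total + out$reward
        if (isTRUE(out$done)) break
        s <- out$state
      }
      total
    }, numeric(1)))
  })
}

#' Serialize a Q-table to CSV
#'
#' Long format: one row per (state, action) pair.
#'
#' @param q an `apeo_qtable`.
#' @param path CSV path.
#' @return `path` invisibly / the restored table.
#' @export
write_q_table <- function(q, path) {
  df <- tidyr::expand_grid(state_bin = seq_len(nrow(q$values)),
                           action_index = seq_len(ncol(q$values)))
  df$value <- q$values[cbind(df$state_bin, df$action_index)]
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_q_table
#' @param eta_lr,gamma_discount hyper-parameters for the restored table.
#' @export
read_q_table <- function(path, eta_lr = 0.5, gamma_discount = 0.9) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  q <- q_table(max(df$state_bin), max(df$action_index), eta_lr, gamma_discount)
  q$values[cbind(df$state_bin, df$action_index)] <- df$value
  q
}

#' Simulated single-participant environment
#'
#' A compact stateful environment for exercising the personalization agent:
#' states are engagement quantile bins, actions an intensity grid crossed
#' with the modality set; the participant's engagement rises when the chosen
#' modality matches its latent preference and when intensity sits near its
#' preferred load, and decays otherwise. Rewards follow [step_reward()].
#'
#' @param preferred_modality latent preferred modality index.
#' @param preferred_intensity latent preferred intensity in `[0, 1]`.
#' @param n_bins engagement bins (states).
#' @param intensities intensity grid.
#' @param weights a [reward_weights()].
#' @return environment list for [train_policy()].
#' @export
participant_env <- function(preferred_modality = 2L,
                            preferred_intensity = 0.6,
                            n_bins = 5L,
                            intensities = c(0.2, 0.5, 0.8),
                            weights = reward_weights()) {
  n_mod <- length(activity_modalities())
  n_actions <- n_mod * length(intensities)
  state_of <- function(e) min(n_bins, 1L + floor(e * n_bins))
  e_cur <- new.env(parent = emptyenv())
  e_cur$e <- 0.5
  list(
    n_states = n_bins,
    n_actions = n_actions,
    reset = function() {
      e_cur$e <- 0.5
      state_of(e_cur$e)
    },
    step = function(s, a) {
      mod <- ((a - 1L) %% n_mod) + 1L
      int <- intensities[((a - 1L) %/% n_mod) + 1L]
      match_gain <- 0.25 * (mod == preferred_modality) -
        0.4 * abs(int - preferred_intensity)
      e_new <- as.numeric(clamp(0.9 * e_cur$e + match_gain + 0.05, 0, 1))
      effort <- weights$gamma1 * int^2 + weights$gamma2 * 30
      r <- step_reward(e_new, 0.1 * int, effort, weights)
      e_cur$e <- e_new
      list(state = state_of(e_new), reward = r, done = FALSE)
    }
  )
}
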