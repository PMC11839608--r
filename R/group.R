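as_state_matrix <- function(states) {
  if (is.list(states) && !is.data.frame(states) && !is.matrix(states)) {
    states <- lapply(states, function(s) {
      if (inherits(s, "participant_state")) state_as_vector(s) else s
    })
    lens <- vapply(states, length, integer(1))
    if (length(unique(lens)) != 1L) {
      abort("participant states have differing layouts.",
            class = "apeo_shape_error")
    }
    states <- do.call(rbind, states)
  }
  m <- as.matrix(states)
  if (nrow(m) < 1) {
    abort("at least one participant is required.",
          class = "apeo_invalid_argument")
  }
  m
}

#' Group state as the mean of member states
#'
#' Component-wise arithmetic mean over participants.
#'
#' @param states a numeric matrix (one row per participant), a list of
#'   state vectors, or a list of [participant_state()] objects.
#' @return numeric vector, the mean state.
#' @export
group_state <- function(states) {
  colMeans(as_state_matrix(states))
}

#' Group cohesion loss
#'
#' `L_group = sum_i ||S_i - G||^2`; zero iff all member states coincide,
#' and equal to `N` times the population variance in the scalar case.
#'
#' @param states member states (see [group_state()]).
#' @param g optional precomputed group mean; validated against `states`.
#' @return non-negative loss.
#' @export
cohesion_loss <- function(states, g = NULL) {
  m <- as_state_matrix(states)
  gm <- colMeans(m)
  if (!is.null(g)) {
    if (length(g) != ncol(m) || any(abs(g - gm) > 1e-8)) {
      abort("`g` is not the mean of `states`.", class = "apeo_invalid_argument")
    }
  }
  sum(sweep(m, 2, gm)^2)
}

#' Group floor constraints
#'
#' @param e_min engagement floor in `[0, 1]`.
#' @param f_min fitness floor vector (recycled over fitness components).
#' @return a `group_constraints` list.
#' @export
group_constraints <- function(e_min = 0, f_min = -Inf) {
  check_scalar_number(e_min, "e_min", lower = 0, upper = 1)
  structure(list(e_min = e_min, f_min = f_min), class = "group_constraints")
}

#' Check member states against group floors
#'
#' Floors use `>=` semantics: a value exactly at its floor is not flagged.
#'
#' @param states tibble or matrix of member states with named columns; an
#'   `engagement` column is compared against `e_min`, every `fitness*`
#'   column against `f_min`.
#' @param constraints a [group_constraints()].
#' @return tibble of violations (`participant`, `quantity`, `value`,
#'   `floor`); zero rows iff all constraints hold.
#' @export
check_constraints <- function(states, constraints) {
  df <- as_tibble(as.data.frame(states))
  if (!"participant" %in% names(df)) df$participant <- seq_len(nrow(df))
  out <- list()
  if ("engagement" %in% names(df)) {
    bad <- df$engagement < constraints$e_min
    if (any(bad)) {
      out[[length(out) + 1L]] <- tibble(
        participant = df$participant[bad], quantity = "engagement",
        value = df$engagement[bad], floor = constraints$e_min)
    }
  }
  fit_cols <- grep("^fitness", names(df), value = TRUE)
  fmin <- rep(constraints$f_min, length.out = max(1L, length(fit_cols)))
  for (k in seq_along(fit_cols)) {
    bad <- df[[fit_cols[k]]] < fmin[k]
    if (any(bad)) {
      out[[length(out) + 1L]] <- tibble(
        participant = df$participant[bad], quantity = fit_cols[k],
        value = df[[fit_cols[k]]][bad], floor = fmin[k])
    }
  }
  if (length(out) == 0) {
    return(tibble(participant = integer(), quantity = character(),
                  value = numeric(), floor = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Per-step group reward term
#'
#' `-L_group + alpha1 E_group + alpha2 F_group`; the cumulative group
#' reward sums these terms over the horizon.
#'
#' @param l_group cohesion loss at the step.
#' @param e_group,f_group collective (mean) engagement and fitness.
#' @param alpha1,alpha2 non-negative weights.
#' @return scalar reward term.
#' @export
group_reward <- function(l_group, e_group, f_group, alpha1 = 1, alpha2 = 1) {
  stopifnot(alpha1 >= 0, alpha2 >= 0)
  -l_group + alpha1 * e_group + alpha2 * f_group
}

#' Social-influence graph
#'
#' Directed weighted edges; self-loops are rejected and weights must be
#' finite and non-negative.
#'
#' @param edges tibble/data frame with columns `src`, `dst`, `weight`.
#' @return an `apeo_social_graph` tibble.
#' @export
social_graph <- function(edges) {
  edges <- as_tibble(edges)
  stopifnot(all(c("src", "dst", "weight") %in% names(edges)))
  if (any(edges$src == edges$dst)) {
    abort("self-edges are not allowed.", class = "apeo_invalid_argument")
  }
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0)) {
    abort("edge weights must be finite and >= 0.",
          class = "apeo_invalid_argument")
  }
  class(edges) <- c("apeo_social_graph", class(edges))
  edges
}

#' Graph-based cohesion
#'
#' Mean squared state difference over the edges:
#' `C = (1/|E|) sum_(i,j) ||S_i - S_j||^2`. An empty edge set yields `NA`
#' with a warning (undefined, not silently 0).
#'
#' @param graph an [social_graph()].
#' @param states matrix/tibble of states whose row order matches the
#'   participant ids used in the edge list.
#' @return mean pairwise cohesion (smaller = more cohesive).
#' @export
graph_cohesion <- function(graph, states) {
  m <- as_state_matrix(states)
  if (nrow(graph) == 0) {
    warn("empty edge set: graph cohesion is undefined.")
    return(NA_real_)
  }
  if (max(graph$src, graph$dst) > nrow(m)) {
    abort("edge endpoint without a state.", class = "apeo_shape_error")
  }
  d2 <- rowSums((m[graph$src, , drop = FALSE] -
                   m[graph$dst, , drop = FALSE])^2)
  mean(d2)
}

#' Distribute group rewards from collective performance
#'
#' `R = (1/N) sum_i (alpha T_i + beta E_i)`.
#'
#' @param t_scores task completion scores.
#' @param e_levels engagement levels, aligned with `t_scores`.
#' @param alpha,beta non-negative weights.
#' @return scalar group reward.
#' @export
distribute_group_rewards <- function(t_scores, e_levels, alpha = 1, beta = 1) {
  check_same_length(t_scores, e_levels, "t_scores", "e_levels")
  stopifnot(alpha >= 0, beta >= 0)
  mean(alpha * t_scores + beta * e_levels)
}

#' Adaptive influence-weight update
#'
#' `w_ij <- w_ij + eta (E_j - E_i)`, clamped at zero from below (a
#' `clamped` attribute flags when the floor was hit).
#'
#' @param w_ij current weight.
#' @param e_i,e_j engagement of the influenced and influencing participant.
#' @param eta_w adjustment rate (>= 0).
#' @return updated weight.
#' @export
update_influence <- function(w_ij, e_i, e_j, eta_w) {
  stopifnot(eta_w >= 0)
  clamp(w_ij + eta_w * (e_j - e_i), 0, Inf)
}

#' Simulated group environment over an activity grid
#'
#' Deterministic member responses for exercising group-level Q-learning:
#' each member's engagement relaxes toward a peak centred on its preferred
#' intensity, and scalar fitness accrues with intensity. Actions are rows
#' of the activity grid; feasibility masks out actions whose one-step
#' predicted states would break the group floors.
#'
#' @param preferred_intensities numeric vector, one latent preference per
#'   member.
#' @param action_grid tibble with columns `intensity`, `duration`,
#'   `modality` (default: 5-point intensity grid at 30 min crossed with the
#'   aerobic modality kept fixed to keep the grid small).
#' @param constraints a [group_constraints()].
#' @param alpha1,alpha2 weights of the group reward.
#' @param n_bins group-state bins over mean engagement.
#' @param bounds an [activity_bounds()] that every grid row must satisfy.
#' @return a `group_env` list for [optimize_group_activity()].
#' @export
group_env <- function(preferred_intensities,
                      action_grid = NULL,
                      constraints = group_constraints(),
                      alpha1 = 1, alpha2 = 1, n_bins = 5L,
                      bounds = activity_bounds()) {
  if (is.null(action_grid)) {
    action_grid <- tidyr::expand_grid(
      intensity = seq(bounds$i_min + 0.1, bounds$i_max - 0.1, length.out = 5),
      duration = 30,
      modality = "aerobic"
    )
  }
  for (k in seq_len(nrow(action_grid))) {
    activity_params(action_grid$intensity[k], action_grid$duration[k],
                    action_grid$modality[k], bounds)  # validates boxes
  }
  n <- length(preferred_intensities)
  init_e <- rep(0.5, n)
  init_f <- rep(0, n)
  store <- new.env(parent = emptyenv())
  respond <- function(e, f, a) {
    i_k <- action_grid$intensity[a]
    e_new <- as.numeric(clamp(0.7 * e + 0.3 * (1 - 2 * abs(i_k - preferred_intensities)),
                              0, 1))
    f_new <- f + 0.05 * i_k
    list(e = e_new, f = f_new)
  }
  state_bin <- function(e) min(n_bins, 1L + floor(mean(e) * n_bins))
  list(
    n_states = n_bins,
    n_actions = nrow(action_grid),
    action_grid = action_grid,
    bounds = bounds,
    reset = function() {
      store$e <- init_e
      store$f <- init_f
      state_bin(store$e)
    },
    feasible = function() {
      vapply(seq_len(nrow(action_grid)), function(a) {
        nxt <- respond(store$e, store$f, a)
        all(nxt$e >= constraints$e_min) && all(nxt$f >= constraints$f_min)
      }, logical(1))
    },
    step = function(a) {
      nxt <- respond(store$e, store$f, a)
      store$e <- nxt$e
      store$f <- nxt$f
      states <- cbind(fitness = nxt$f, engagement = nxt$e)
      l <- cohesion_loss(states)
      r <- group_reward(l, mean(nxt$e), mean(nxt$f), alpha1, alpha2)
      list(state = state_bin(nxt$e), reward = r, l_group = l)
    },
    members = n
  )
}

#' Group-level activity optimization by Q-learning
#'
#' Reuses the tabular update at the group level: states are bins of the
#' mean group state, actions rows of the activity grid, rewards the
#' per-step group-reward terms. Infeasible actions (predicted to violate
#' the group floors) are masked out of both the behaviour policy and the
#' greedy argmax, so no recommended action ever leaves the feasible box.
#'
#' @param env a [group_env()].
#' @param episodes,steps_per_episode training horizon.
#' @param eta_lr,gamma_discount Q-learning hyper-parameters.
#' @param epsilon_schedule exploration schedule, see [eps_exp_decay()].
#' @param schedule_steps length of the greedy schedule rolled out after
#'   training.
#' @param seed integer seed.
#' @return an `apeo_group_policy`: trained `q`, `returns` trace, and the
#'   greedy `schedule` tibble (`t`, `action`, `intensity`, `duration`,
#'   `modality`, `l_group`, `r_group`).
#' @export
optimize_group_activity <- function(env, episodes = 60L,
                                    steps_per_episode = 20L,
                                    eta_lr = 0.5, gamma_discount = 0.9,
                                    epsilon_schedule = eps_exp_decay(),
                                    schedule_steps = 20L, seed = 1L) {
  q <- q_table(env$n_states, env$n_actions, eta_lr, gamma_discount)
  returns <- numeric(episodes)
  with_seed(seed, {
    for (ep in seq_len(episodes)) {
      eps <- epsilon_schedule(ep)
      s <- env$reset()
      total <- 0
      for (k in seq_len(steps_per_episode)) {
        mask <- env$feasible()
        if (!any(mask)) {
          abort("no feasible action satisfies the group constraints.",
                class = "apeo_infeasible_error")
        }
        a <- if (runif(1) < eps) {
          allowed <- which(mask)
          allowed[sample.int(length(allowed), 1L)]
        } else {
          greedy_action(q, s, mask)
        }
        out <- env$step(a)
        total <- total + out$reward
        q <- q_update(q, s, a, out$reward, out$state)
        s <- out$state
      }
      returns[ep] <- total
    }
  })
  # greedy rollout
  s <- env$reset()
  sched <- vector("list", schedule_steps)
  for (t in seq_len(schedule_steps)) {
    mask <- env$feasible()
    a <- greedy_action(q, s, mask)
    out <- env$step(a)
    sched[[t]] <- tibble(t = t, action = a,
                         intensity = env$action_grid$intensity[a],
                         duration = env$action_grid$duration[a],
                         modality = env$action_grid$modality[a],
                         l_group = out$l_group, r_group = out$reward)
    s <- out$state
  }
  structure(list(q = q,
                 returns = tibble(episode = seq_len(episodes),
                                  return = returns),
                 schedule = dplyr::bind_rows(sched)),
            class = "apeo_group_policy")
}

#' Joint engagement-progress objective
#'
#' `value = sum_i (lambda1 E_i + lambda2 progress_i)`, feasible iff the
#' challenge balance does not exceed its threshold (`<=` semantics).
#'
#' @param e_levels engagement levels.
#' @param progress per-participant progress, aligned with `e_levels`.
#' @param lambda1,lambda2 non-negative trade-off weights.
#' @param c_balance challenge balance, see [challenge_balance()].
#' @param tau_balance feasibility threshold.
#' @return list with `value` and logical `feasible`.
#' @export
joint_objective <- function(e_levels, progress, lambda1, lambda2,
                            c_balance, tau_balance) {
  check_same_length(e_levels, progress, "e_levels", "progress")
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  list(value = sum(lambda1 * e_levels + lambda2 * progress),
       feasible = c_balance <= tau_balance)
}

#' Write / read a social graph edge list as CSV
#'
#' @param graph an [social_graph()]; `path` CSV file.
#' @param path CSV file path.
#' @return `path` invisibly / the restored graph.
#' @export
write_social_graph <- function(graph, path) {
  readr::write_csv(as_tibble(graph), path)
  invisible(path)
}

#' @rdname write_social_graph
#' @export
read_social_graph <- function(path) {
  social_graph(readr::read_csv(path, show_col_types = FALSE))
}
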