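#' Engagement factor decomposition
#'
#' Intrinsic motivation `M = enjoyment / perceived effort`, perceived
#' competency `C = skill gain / skill requirement`, and social influence
#' `S = sum_j w_ij E_j` over peers with normalized influence weights.
#'
#' @param enjoyment task enjoyment (>= 0).
#' @param effort perceived effort (> 0).
#' @param skill_gain observed skill improvement (>= 0).
#' @param skill_req skill requirement of the task (> 0).
#' @param peer_engagements engagement levels of the peers.
#' @param weights influence weights `w_ij`, aligned with
#'   `peer_engagements` and summing to 1 (tolerance 1e-8).
#' @return one-row tibble with `intrinsic_m`, `social_s`, `competency_c`.
#' @export
engagement_components <- function(enjoyment, effort, skill_gain, skill_req,
                                  peer_engagements, weights) {
  if (effort <= 0 || skill_req <= 0) {
    abort("`effort` and `skill_req` must be > 0.", class = "apeo_domain_error")
  }
  check_same_length(peer_engagements, weights, "peer_engagements", "weights")
  if (abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must sum to 1 (within 1e-8).",
          class = "apeo_invalid_argument")
  }
  tibble(
    intrinsic_m = enjoyment / effort,
    social_s = sum(weights * peer_engagements),
    competency_c = skill_gain / skill_req
  )
}

#' Softmax peer-influence weights
#'
#' `w_ij = exp(theta_i . phi_j) / sum_k exp(theta_i . phi_k)` over the
#' peers of participant i, computed with max-subtraction so large dot
#' products cannot overflow. Weights are strictly positive, sum to one, and
#' are invariant to adding a constant to every dot product.
#'
#' @param theta_i embedding of the focal participant.
#' @param phis list (or matrix rows) of peer embeddings.
#' @return numeric weight vector over peers.
#' @export
influence_weights <- function(theta_i, phis) {
  if (is.matrix(phis)) phis <- asplit(phis, 1)
  if (length(phis) < 1) {
    abort("at least one peer is required.", class = "apeo_invalid_argument")
  }
  dots <- vapply(phis, function(p) {
    check_same_length(theta_i, p, "theta_i", "phi_j")
    sum(theta_i * p)
  }, numeric(1))
  z <- exp(dots - max(dots))
  z / sum(z)
}

#' Engagement read-out from its factors
#'
#' The mapping from (M, S, C) to engagement is realized as a logistic-linear
#' read-out `E = sigma(w . [M, S, C] + b) + eps`, clamped to `[0, 1]`; the
#' non-linear form is pluggable via `link`.
#'
#' @param factors one-row tibble from [engagement_components()].
#' @param w length-3 weight vector; `b` intercept.
#' @param b intercept.
#' @param noise_sd standard deviation of the additive noise (>= 0).
#' @param seed optional seed for the noise draw.
#' @param link function mapping the linear predictor to `[0, 1]`.
#' @return engagement scalar in `[0, 1]`.
#' @export
engagement_value <- function(factors, w = c(0.5, 0.5, 0.5), b = 0,
                             noise_sd = 0, seed = NULL, link = sigmoid) {
  x <- c(factors$intrinsic_m, factors$social_s, factors$competency_c)
  if (any(!is.finite(x))) {
    abort("engagement factors must be finite.", class = "apeo_domain_error")
  }
  e <- link(sum(w * x) + b)
  if (noise_sd > 0) {
    eps <- if (is.null(seed)) rnorm(1, 0, noise_sd)
           else with_seed(seed, rnorm(1, 0, noise_sd))
    e <- e + eps
  }
  as.numeric(clamp(e, 0, 1))
}

#' Gamification parameters
#'
#' @param beta1,beta2,gamma_bonus reward weights on task score, engagement
#'   and milestone bonus (>= 0).
#' @param t_threshold task-score threshold above which bonus accrues.
#' @param delta challenge-reward coupling (>= 0).
#' @param eta_target target adaptation rate in (0, 1].
#' @param alpha_decay engagement decay rate in `[0, 1]`.
#' @return a `gamification_params` list.
#' @export
gamification_params <- function(beta1 = 1, beta2 = 1, gamma_bonus = 1,
                                t_threshold = 0.6, delta = 0.5,
                                eta_target = 0.1, alpha_decay = 0.9) {
  for (nm in c("beta1", "beta2", "gamma_bonus", "delta")) {
    check_scalar_number(get(nm), nm, lower = 0)
  }
  if (eta_target <= 0 || eta_target > 1) {
    abort("`eta_target` must lie in (0, 1].", class = "apeo_invalid_argument")
  }
  check_scalar_number(alpha_decay, "alpha_decay", lower = 0, upper = 1)
  structure(list(beta1 = beta1, beta2 = beta2, gamma_bonus = gamma_bonus,
                 t_threshold = t_threshold, delta = delta,
                 eta_target = eta_target, alpha_decay = alpha_decay),
            class = "gamification_params")
}

#' Multi-layer gamified reward
#'
#' Bonus `B = max(0, T - T_threshold)` and reward
#' `R = beta1 T + beta2 E + gamma B`.
#'
#' @param task_score task completion score `T`.
#' @param engagement engagement level `E`.
#' @param params a [gamification_params()].
#' @return one-row tibble with `bonus` and `reward`.
#' @export
compute_reward <- function(task_score, engagement, params = gamification_params()) {
  b <- pmax(0, task_score - params$t_threshold)
  tibble(bonus = b,
         reward = params$beta1 * task_score + params$beta2 * engagement +
           params$gamma_bonus * b)
}

#' Challenge balance
#'
#' `C_balance = ||F_target - F_actual||^2 - delta R`; may be negative when
#' rewards outweigh the performance gap.
#'
#' @param f_target,f_actual aligned performance vectors.
#' @param reward earned reward `R`.
#' @param delta reward coupling (>= 0).
#' @return scalar challenge balance.
#' @export
challenge_balance <- function(f_target, f_actual, reward, delta) {
  check_same_length(f_target, f_actual, "f_target", "f_actual")
  stopifnot(delta >= 0)
  sum((f_target - f_actual)^2) - delta * reward
}

#' Adaptive target update
#'
#' `F_target <- F_target + eta (F_actual - F_target)`; a contraction toward
#' the achieved performance for `eta` in (0, 1].
#'
#' @param f_target,f_actual aligned vectors.
#' @param eta_target adaptation rate in (0, 1].
#' @return updated target vector.
#' @export
update_target <- function(f_target, f_actual, eta_target) {
  if (eta_target <= 0 || eta_target > 1) {
    abort("`eta_target` must lie in (0, 1].", class = "apeo_invalid_argument")
  }
  check_same_length(f_target, f_actual, "f_target", "f_actual")
  f_target + eta_target * (f_actual - f_target)
}

#' Engagement decay toward the reward level
#'
#' `E(t+1) = alpha E(t) + (1 - alpha) R`; for constant `R` the iterates
#' follow the geometric closed form `E(t) = R + alpha^t (E(0) - R)`.
#'
#' @param engagement current engagement `E(t)`.
#' @param reward reward level `R`.
#' @param alpha_decay decay rate in `[0, 1]` (1 means no decay).
#' @return next engagement value.
#' @export
decay_engagement <- function(engagement, reward, alpha_decay) {
  if (alpha_decay < 0 || alpha_decay > 1) {
    abort("`alpha_decay` must lie in [0, 1].", class = "apeo_invalid_argument")
  }
  alpha_decay * engagement + (1 - alpha_decay) * reward
}
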