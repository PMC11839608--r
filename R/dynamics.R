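#' Participant state vector
#'
#' The per-participant state stacks the fitness vector with scalar
#' engagement and adherence, both kept in `[0, 1]` after every update.
#'
#' @param fitness numeric fitness vector.
#' @param engagement,adherence scalars in `[0, 1]`.
#' @param t step index.
#' @return a `participant_state` list.
#' @export
participant_state <- function(fitness, engagement, adherence, t = 0L) {
  stopifnot(is.numeric(fitness), all(is.finite(fitness)))
  check_scalar_number(engagement, "engagement", lower = 0, upper = 1)
  check_scalar_number(adherence, "adherence", lower = 0, upper = 1)
  structure(list(fitness = fitness, engagement = engagement,
                 adherence = adherence, t = as.integer(t)),
            class = "participant_state")
}

#' @export
print.participant_state <- function(x, ...) {
  cat(sprintf("<participant_state t=%d> F=[%s] E=%.3f A=%.3f\n", x$t,
              paste(signif(x$fitness, 4), collapse = ", "),
              x$engagement, x$adherence))
  invisible(x)
}

state_as_vector <- function(s) c(s$fitness, s$engagement, s$adherence)

#' Intervention-response dynamics
#'
#' Linear response matrices: `W_s` maps the intervention vector and `D_s`
#' the disturbance vector into additive state change.
#'
#' @param w_s,d_s numeric matrices with one row per state component.
#' @return a `state_dynamics` list.
#' @export
state_dynamics <- function(w_s, d_s) {
  w_s <- as.matrix(w_s); d_s <- as.matrix(d_s)
  if (nrow(w_s) != nrow(d_s)) {
    abort("`w_s` and `d_s` must have the same number of rows (state dim).",
          class = "apeo_shape_error")
  }
  structure(list(w_s = w_s, d_s = d_s), class = "state_dynamics")
}

#' Evolve a participant state one step
#'
#' `S(t+1) = S(t) + W_s u + D_s d`, after which engagement and adherence are
#' clamped into `[0, 1]` (a `clamped` attribute records whether the clamp
#' was active).
#'
#' @param s a [participant_state()].
#' @param u intervention vector (columns of `W_s`).
#' @param d disturbance vector (columns of `D_s`).
#' @param dyn a [state_dynamics()].
#' @return the updated `participant_state` with `t` advanced by one.
#' @export
evolve_state <- function(s, u, d, dyn) {
  x <- state_as_vector(s)
  if (length(u) != ncol(dyn$w_s) || length(d) != ncol(dyn$d_s) ||
      length(x) != nrow(dyn$w_s)) {
    abort("state/intervention/disturbance dimensions do not conform.",
          class = "apeo_shape_error")
  }
  xn <- x + drop(dyn$w_s %*% u) + drop(dyn$d_s %*% d)
  nf <- length(s$fitness)
  e <- clamp(xn[nf + 1], 0, 1)
  a <- clamp(xn[nf + 2], 0, 1)
  out <- participant_state(xn[seq_len(nf)], as.numeric(e), as.numeric(a),
                           t = s$t + 1L)
  attr(out, "clamped") <- isTRUE(attr(e, "clamped")) || isTRUE(attr(a, "clamped"))
  out
}

#' Tracking error against the fitness target
#'
#' @param f_target,f_actual fitness vectors of equal length.
#' @return `f_target - f_actual`.
#' @export
performance_error <- function(f_target, f_actual) {
  check_same_length(f_target, f_actual, "f_target", "f_actual")
  f_target - f_actual
}

#' Regularized state-tracking cost
#'
#' `L = sum_i ||e_i||^2 + lambda ||u_i||^2` over participants.
#'
#' @param errors list of per-participant error vectors.
#' @param interventions list of per-participant intervention vectors.
#' @param lambda intervention penalty weight (>= 0).
#' @return non-negative scalar cost.
#' @export
state_cost <- function(errors, interventions, lambda = 0) {
  if (lambda < 0) {
    abort("`lambda` must be >= 0.", class = "apeo_invalid_argument")
  }
  if (length(errors) != length(interventions)) {
    abort("`errors` and `interventions` must cover the same participants.",
          class = "apeo_shape_error")
  }
  sum(vapply(errors, function(e) sum(e^2), numeric(1))) +
    lambda * sum(vapply(interventions, function(u) sum(u^2), numeric(1)))
}

#' First-order relaxation toward a target state
#'
#' Closed-form solution of `dS/dt = -(S - S_target)/tau`:
#' `S(t) = S_target + (S0 - S_target) exp(-t/tau)`.
#'
#' @param s0 initial value(s).
#' @param s_target target value(s).
#' @param tau participant-specific time constant (> 0).
#' @param t elapsed time (>= 0), scalar or vector.
#' @return relaxed value(s).
#' @export
relax_towards_target <- function(s0, s_target, tau, t) {
  if (!is.numeric(tau) || any(tau <= 0)) {
    abort("`tau` must be > 0.", class = "apeo_domain_error")
  }
  stopifnot(all(t >= 0))
  s_target + (s0 - s_target) * exp(-t / tau)
}

#' PID gains
#'
#' @param kp,ki,kd proportional, integral and derivative gains (>= 0).
#' @param dt step length (> 0).
#' @param i_max anti-windup bound on the magnitude of the integral term
#'   (default unbounded); interventions are box-constrained downstream, so
#'   an unbounded integral is rarely wanted in closed loop.
#' @return a `pid_gains` list.
#' @export
pid_gains <- function(kp = 1, ki = 0, kd = 0, dt = 1, i_max = Inf) {
  for (nm in c("kp", "ki", "kd")) {
    check_scalar_number(get(nm), nm, lower = 0)
  }
  check_scalar_number(dt, "dt", lower = 0, strict_lower = TRUE)
  structure(list(kp = kp, ki = ki, kd = kd, dt = dt, i_max = i_max),
            class = "pid_gains")
}

#' PID control law
#'
#' `u = Kp e(t) + Ki * (rectangle-rule integral of the error history) +
#' Kd * (backward difference)/dt`, applied component-wise when errors are
#' vectors (rows of a matrix history). The integral term is clamped to
#' `[-i_max, i_max]` for anti-windup.
#'
#' @param error_history numeric vector of scalar errors over time, or a
#'   matrix with one row per step.
#' @param gains a [pid_gains()].
#' @return control vector (length = error dimension).
#' @export
pid_control <- function(error_history, gains) {
  if (is.vector(error_history)) {
    error_history <- matrix(error_history, ncol = 1L)
  }
  n <- nrow(error_history)
  if (n < 1) {
    abort("`error_history` must contain at least one error.",
          class = "apeo_invalid_argument")
  }
  e_now <- error_history[n, ]
  integ <- colSums(error_history) * gains$dt
  integ <- pmin(pmax(integ * gains$ki, -gains$i_max), gains$i_max)
  deriv <- if (n >= 2) (e_now - error_history[n - 1, ]) / gains$dt else 0 * e_now
  drop(gains$kp * e_now + integ + gains$kd * deriv)
}
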