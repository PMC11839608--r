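#' Feedback parameters
#'
#' @param epsilon optimal-band tolerance (>= 0).
#' @param kappa under/over-exertion tolerance (>= `epsilon`; the band
#'   between them is the explicit MARGINAL class).
#' @param gamma1,gamma2 corrective and motivational signal scales (>= 0).
#' @param eta_goal goal adjustment rate in (0, 1].
#' @param alpha_h,beta_v,zeta_r fatigue-risk weights on heart-rate
#'   variability, movement-velocity deviation and cumulative rewards.
#' @param tau_fatigue fatigue-risk threshold gating intensity reduction.
#' @param rho intensity adjustment rate (>= 0).
#' @param i_min,i_max intensity clamp applied after adjustment.
#' @return a `feedback_params` list.
#' @export
feedback_params <- function(epsilon = 0.25, kappa = 1, gamma1 = 0.5,
                            gamma2 = 0.5, eta_goal = 0.2, alpha_h = 1,
                            beta_v = 1, zeta_r = 1, tau_fatigue = 1,
                            rho = 0.2, i_min = 0, i_max = 1) {
  for (nm in c("epsilon", "kappa", "gamma1", "gamma2", "alpha_h", "beta_v",
               "zeta_r", "rho")) {
    check_scalar_number(get(nm), nm, lower = 0)
  }
  if (epsilon > kappa) {
    abort("`epsilon` must not exceed `kappa`.", class = "apeo_invalid_argument")
  }
  if (eta_goal <= 0 || eta_goal > 1) {
    abort("`eta_goal` must lie in (0, 1].", class = "apeo_invalid_argument")
  }
  structure(list(epsilon = epsilon, kappa = kappa, gamma1 = gamma1,
                 gamma2 = gamma2, eta_goal = eta_goal, alpha_h = alpha_h,
                 beta_v = beta_v, zeta_r = zeta_r, tau_fatigue = tau_fatigue,
                 rho = rho, i_min = i_min, i_max = i_max),
            class = "feedback_params")
}

#' Periodic goal update
#'
#' `G <- G + eta (T_optimal - M)`; with constant measurement `M` the
#' iterates grow linearly, `G_t = G_0 + t eta (T_optimal - M)`.
#'
#' @param goal current goal `G`.
#' @param measurement current performance `M`.
#' @param t_optimal optimal target performance.
#' @param eta_goal adjustment rate in (0, 1].
#' @return updated goal.
#' @export
update_goal <- function(goal, measurement, t_optimal, eta_goal) {
  if (eta_goal <= 0 || eta_goal > 1) {
    abort("`eta_goal` must lie in (0, 1].", class = "apeo_invalid_argument")
  }
  goal + eta_goal * (t_optimal - measurement)
}

#' Threshold-based performance classification
#'
#' OPTIMAL when `||M - G|| <= epsilon`; UNDERPERFORMING when
#' `M < G - kappa`; OVEREXERTING when `M > G + kappa`; the band
#' `epsilon < ||M - G|| <= kappa` is labelled MARGINAL explicitly
#' ("monitor, no adjustment") instead of silently falling into a
#' neighbouring class. The four labels partition the line for every
#' `epsilon <= kappa`.
#'
#' @param measurement performance `M`; `goal` target `G`.
#' @param goal target `G`.
#' @param params a [feedback_params()].
#' @return one of `"OPTIMAL"`, `"UNDERPERFORMING"`, `"OVEREXERTING"`,
#'   `"MARGINAL"`.
#' @export
classify_performance <- function(measurement, goal, params = feedback_params()) {
  dev <- measurement - goal
  if (abs(dev) <= params$epsilon) return("OPTIMAL")
  if (dev < -params$kappa) return("UNDERPERFORMING")
  if (dev > params$kappa) return("OVEREXERTING")
  "MARGINAL"
}

#' Corrective and motivational feedback signals
#'
#' Corrective signal `C = gamma1 (G - M)`. The motivational cue is
#' `gamma2 * h(M, P)` where `h` defaults to the least-squares slope of the
#' last `window` history points (pluggable): a positive slope yields
#' reinforcement proportional to the improvement rate, a flat or absent
#' history sets the encouragement flag so correction is paired with
#' encouragement.
#'
#' @param measurement current performance `M`; `goal` target `G`.
#' @param goal target `G`.
#' @param history numeric vector of past performance (oldest first).
#' @param params a [feedback_params()].
#' @param window history points entering the slope.
#' @param h optional replacement for the motivational function
#'   `(measurement, history) -> numeric`.
#' @return tibble with `corrective`, `cue`, `encourage` (logical),
#'   `history_missing` (logical).
#' @export
feedback_signals <- function(measurement, goal, history = numeric(),
                             params = feedback_params(), window = 5L,
                             h = NULL) {
  corrective <- params$gamma1 * (goal - measurement)
  missing_hist <- length(history) == 0
  slope <- if (!is.null(h)) {
    h(measurement, history)
  } else if (missing_hist) {
    0
  } else {
    recent <- utils::tail(c(history, measurement), window)
    if (length(recent) < 2) 0
    else unname(coef(lm(y ~ x, data.frame(x = seq_along(recent), y = recent)))[2])
  }
  cue <- params$gamma2 * slope
  tibble(corrective = corrective, cue = cue,
         encourage = slope <= 0, history_missing = missing_hist)
}

#' Fatigue / disengagement risk
#'
#' `risk = alpha H + beta V - zeta R` over heart-rate variability `H`,
#' movement-velocity deviation `V` and cumulative rewards `R`; strictly
#' decreasing in `R` when `zeta > 0`. `H` and `V` are expected z-scored
#' against the participant's rolling baseline so the weights stay
#' scale-free.
#'
#' @param hrv heart-rate variability `H` (z-scored).
#' @param vel_dev movement-velocity deviation `V` (z-scored).
#' @param rewards cumulative rewards `R`.
#' @param params a [feedback_params()].
#' @return scalar risk score.
#' @export
fatigue_risk <- function(hrv, vel_dev, rewards, params = feedback_params()) {
  params$alpha_h * hrv + params$beta_v * vel_dev - params$zeta_r * rewards
}

#' Risk-gated intensity adjustment
#'
#' When `risk > tau_fatigue` the intensity drops by `rho * deviation` and
#' is clamped into `[i_min, i_max]` (clamp flagged); otherwise it is left
#' unchanged.
#'
#' @param intensity current activity intensity.
#' @param deviation detected performance deviation `D`.
#' @param risk fatigue risk from [fatigue_risk()].
#' @param params a [feedback_params()].
#' @return adjusted intensity (with a `clamped` attribute when the box was
#'   hit).
#' @export
adjust_intensity <- function(intensity, deviation, risk,
                             params = feedback_params()) {
  if (risk <= params$tau_fatigue) return(intensity)
  clamp(intensity - params$rho * deviation, params$i_min, params$i_max)
}
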