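#' Joint trajectory
#'
#' Positions (metres) sampled at `dt`; velocities and accelerations are
#' derived by central differences when not supplied (one-sided differences
#' at the ends).
#'
#' @param positions numeric matrix, one row per step, columns x/y/z (any
#'   dimension >= 1 is accepted).
#' @param dt sampling interval, seconds (> 0).
#' @param mass segment mass, kg (> 0).
#' @param velocities,accelerations optional matrices aligned with
#'   `positions`.
#' @return a `joint_trajectory` list.
#' @export
joint_trajectory <- function(positions, dt, mass,
                             velocities = NULL, accelerations = NULL) {
  positions <- as.matrix(positions)
  check_scalar_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_scalar_number(mass, "mass", lower = 0, strict_lower = TRUE)
  if (is.null(velocities) || is.null(accelerations)) {
    if (nrow(positions) < 3) {
      abort("at least 3 samples are needed to differentiate positions.",
            class = "apeo_insufficient_data")
    }
  }
  if (is.null(velocities)) velocities <- central_diff(positions, dt)
  if (is.null(accelerations)) accelerations <- central_diff(velocities, dt)
  velocities <- as.matrix(velocities); accelerations <- as.matrix(accelerations)
  if (nrow(velocities) != nrow(positions) ||
      nrow(accelerations) != nrow(positions)) {
    abort("positions, velocities and accelerations must be aligned.",
          class = "apeo_shape_error")
  }
  structure(list(positions = positions, velocities = velocities,
                 accelerations = accelerations, dt = dt, mass = mass),
            class = "joint_trajectory")
}

# Central differences along rows; one-sided at both ends.
central_diff <- function(x, dt) {
  n <- nrow(x)
  d <- x
  d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]) / (2 * dt)
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  d
}

#' Joint forces from Newton's second law
#'
#' `F(t) = m a(t)` per step.
#'
#' @param traj a [joint_trajectory()].
#' @return numeric matrix of forces aligned with the trajectory.
#' @export
joint_kinetics <- function(traj) {
  traj$mass * traj$accelerations
}

#' Single-joint inverse dynamics
#'
#' Required torque `tau = I qdd + C(q, qd) + G(q)` for a one
#' degree-of-freedom rigid joint.
#'
#' @param q,qd,qdd joint coordinate, velocity and acceleration (vectors of
#'   equal length).
#' @param model a [rigid_joint_model()].
#' @return torque vector.
#' @export
inverse_dynamics <- function(q, qd, qdd, model) {
  if (any(!is.finite(c(q, qd, qdd)))) {
    abort("inputs must be finite.", class = "apeo_domain_error")
  }
  check_same_length(q, qd, "q", "qd")
  check_same_length(q, qdd, "q", "qdd")
  model$inertia * qdd + model$coriolis_fn(q, qd) + model$gravity_fn(q)
}

#' Rigid one-joint model
#'
#' @param inertia scalar inertia, kg m^2 (> 0).
#' @param coriolis_fn function `(q, qd) -> torque`, default 0.
#' @param gravity_fn function `(q) -> torque`, default 0.
#' @return a `rigid_joint_model` list.
#' @export
rigid_joint_model <- function(inertia,
                              coriolis_fn = function(q, qd) 0 * q,
                              gravity_fn = function(q) 0 * q) {
  check_scalar_number(inertia, "inertia", lower = 0, strict_lower = TRUE)
  structure(list(inertia = inertia, coriolis_fn = coriolis_fn,
                 gravity_fn = gravity_fn),
            class = "rigid_joint_model")
}

#' Pendulum joint model
#'
#' Point mass `m` at length `l`, angle measured from the vertical; gravity
#' torque `m g l sin(q)`, inertia `m l^2`. Used as the canonical
#' inverse-dynamics check: the gravity term equals the potential-energy
#' gradient `dV/dq` with `V = -m g l cos(q)`.
#'
#' @param m mass, kg; `l` length, m; `g` gravity, m/s^2.
#' @param l,g see above.
#' @return a [rigid_joint_model()].
#' @export
pendulum_model <- function(m = 1, l = 1, g = 9.81) {
  rigid_joint_model(inertia = m * l^2,
                    gravity_fn = function(q) m * g * l * sin(q))
}

#' Mechanical energy along a trajectory
#'
#' `E(t) = 1/2 m ||v(t)||^2 +` trapezoidal accumulation of the power
#' `F(t) . v(t)`; the kinetic term is always non-negative.
#'
#' @param traj a [joint_trajectory()].
#' @param forces force matrix aligned with the trajectory.
#' @return numeric vector `E(t)` in joules.
#' @export
mechanical_energy <- function(traj, forces) {
  forces <- as.matrix(forces)
  if (nrow(forces) != nrow(traj$velocities)) {
    abort("`forces` must be aligned with the trajectory.",
          class = "apeo_shape_error")
  }
  ke <- 0.5 * traj$mass * rowSums(traj$velocities^2)
  pow <- rowSums(forces * traj$velocities)
  n <- length(pow)
  work <- numeric(n)
  if (n > 1) {
    inc <- (pow[-1] + pow[-n]) / 2 * traj$dt
    work[-1] <- cumsum(inc)
  }
  ke + work
}

#' Energy budget for force optimization
#'
#' @param e_max permissible total mechanical energy, joules (> 0).
#' @return an `energy_budget` list.
#' @export
energy_budget <- function(e_max) {
  check_scalar_number(e_max, "e_max", lower = 0, strict_lower = TRUE)
  structure(list(e_max = e_max), class = "energy_budget")
}

#' Gradient-descent force optimization
#'
#' Minimizes the inefficiency loss `L = sum ||F - F_optimal||^2` by
#' iterating `F <- F - eta * 2 (F - F_optimal)`, which contracts the gap to
#' the optimal profile geometrically with ratio `|1 - 2 eta|`. When an
#' energy budget and a trajectory are supplied, each step is projected: if
#' the candidate iterate's terminal mechanical energy exceeds `e_max`, the
#' step is scaled back by halving until the constraint holds (the incoming
#' iterate is assumed feasible).
#'
#' @param f_actual,f_optimal aligned force series (vectors or matrices).
#' @param eta step size in (0, 1); `eta >= 1` warns of divergence risk.
#' @param budget optional [energy_budget()].
#' @param traj trajectory used to evaluate the energy constraint (required
#'   with `budget`).
#' @param max_iter iteration cap.
#' @param tol stop when the loss falls below this.
#' @return list with `forces` (optimized series), `loss_trace` tibble
#'   (`iter`, `loss`), and `converged`; class `apeo_forceopt`.
#' @export
optimize_forces <- function(f_actual, f_optimal, eta, budget = NULL,
                            traj = NULL, max_iter = 100L, tol = 1e-12) {
  if (eta <= 0) {
    abort("`eta` must be > 0.", class = "apeo_invalid_argument")
  }
  if (eta >= 1) {
    warn("`eta` >= 1 risks divergence of the force updates.")
  }
  f <- as.matrix(f_actual)
  fo <- as.matrix(f_optimal)
  if (!all(dim(f) == dim(fo))) {
    abort("`f_actual` and `f_optimal` must be aligned.",
          class = "apeo_shape_error")
  }
  loss <- function(x) sum((x - fo)^2)
  trace <- numeric(max_iter + 1L)
  trace[1] <- loss(f)
  it <- 0L
  while (it < max_iter && trace[it + 1L] >= tol) {
    step <- -eta * 2 * (f - fo)
    if (!is.null(budget)) {
      if (is.null(traj)) {
        abort("`traj` is required to evaluate the energy budget.",
              class = "apeo_invalid_argument")
      }
      scale <- 1
      repeat {
        cand <- f + scale * step
        e_tot <- sum(utils::tail(mechanical_energy(traj, cand), 1L))
        if (e_tot <= budget$e_max) break
        if (scale < 1e-8) { scale <- 0; break }  # no feasible step remains
        scale <- scale / 2
      }
      step <- scale * step
      if (scale == 0) break
    }
    f <- f + step
    it <- it + 1L
    trace[it + 1L] <- loss(f)
  }
  structure(
    list(forces = f,
         loss_trace = tibble(iter = 0:it, loss = trace[seq_len(it + 1L)]),
         converged = trace[it + 1L] < tol),
    class = "apeo_forceopt"
  )
}

#' Reference optimal-force profile scaled by body mass
#'
#' The source of participant-specific optimal forces is left open by the
#' surrounding framework (norms, body parameters, energy minimization); this
#' helper is an explicit stand-in that scales a unit reference profile by
#' body mass.
#'
#' @param reference unit-mass force profile (vector or matrix).
#' @param body_mass participant mass, kg.
#' @return scaled profile.
#' @export
scale_reference_forces <- function(reference, body_mass) {
  check_scalar_number(body_mass, "body_mass", lower = 0, strict_lower = TRUE)
  reference * body_mass
}

#' Synthetic per-modality joint trajectory templates
#'
#' Canned single-joint position templates (synthetic; no motion capture):
#' sinusoidal flexion whose amplitude and frequency scale with the activity
#' intensity, differentiated numerically into a [joint_trajectory()].
#'
#' @param modality one of the activity modalities (see
#'   [activity_modalities()]).
#' @param intensity activity intensity in `[0, 1]`.
#' @param duration seconds; `fs` template sampling rate, Hz.
#' @param fs samples per second.
#' @param mass segment mass, kg.
#' @return a [joint_trajectory()].
#' @export
modality_trajectory <- function(modality, intensity, duration = 4, fs = 50,
                                mass = 3) {
  freq <- switch(modality,
    aerobic = 1.5, team = 1.2, skill = 0.8, relaxation = 0.3,
    high_energy = 2.2,
    abort(sprintf("unknown modality `%s`.", modality),
          class = "apeo_invalid_argument"))
  amp <- 0.1 + 0.4 * intensity
  tt <- seq(0, duration, by = 1 / fs)
  pos <- cbind(amp * sin(2 * pi * freq * tt), 0, 0)
  joint_trajectory(pos, dt = 1 / fs, mass = mass)
}
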