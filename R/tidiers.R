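#' Tidy methods for fitted objects
#'
#' `tidy()` returns the per-iteration trace as a tibble; `glance()` a
#' one-row model summary.
#'
#' @param x a fitted object (`apeo_rnn_fit`, `apeo_policy`,
#'   `apeo_group_policy`, `apeo_forceopt` or `apeo_run`).
#' @param ... unused.
#' @return a tibble.
#' @name apeo_tidiers
NULL

#' @rdname apeo_tidiers
#' @export
tidy.apeo_rnn_fit <- function(x, ...) x$loss_trace

#' @rdname apeo_tidiers
#' @export
glance.apeo_rnn_fit <- function(x, ...) {
  tibble(epochs = nrow(x$loss_trace),
         initial_loss = x$loss_trace$loss[1],
         final_loss = utils::tail(x$loss_trace$loss, 1),
         hidden_dim = nrow(x$params$w_h),
         n_seq = x$n_seq)
}

#' @rdname apeo_tidiers
#' @export
tidy.apeo_policy <- function(x, ...) x$returns

#' @rdname apeo_tidiers
#' @export
glance.apeo_policy <- function(x, ...) {
  tibble(episodes = nrow(x$returns),
         mean_return = mean(x$returns$return),
         final_return = utils::tail(x$returns$return, 1),
         n_states = nrow(x$q$values),
         n_actions = ncol(x$q$values))
}

#' @rdname apeo_tidiers
#' @export
tidy.apeo_group_policy <- function(x, ...) x$schedule

#' @rdname apeo_tidiers
#' @export
glance.apeo_group_policy <- function(x, ...) {
  tibble(episodes = nrow(x$returns),
         mean_return = mean(x$returns$return),
         schedule_mean_cohesion = mean(x$schedule$l_group),
         schedule_steps = nrow(x$schedule))
}

#' @rdname apeo_tidiers
#' @export
tidy.apeo_forceopt <- function(x, ...) x$loss_trace

#' @rdname apeo_tidiers
#' @export
glance.apeo_forceopt <- function(x, ...) {
  tibble(iterations = nrow(x$loss_trace) - 1L,
         initial_loss = x$loss_trace$loss[1],
         final_loss = utils::tail(x$loss_trace$loss, 1),
         converged = x$converged)
}

#' @rdname apeo_tidiers
#' @export
tidy.apeo_run <- function(x, ...) x$timeseries

#' @rdname apeo_tidiers
#' @export
glance.apeo_run <- function(x, ...) {
  as_tibble(x$summary[c("mean_engagement", "mean_cohesion",
                        "constraint_violations", "cumulative_reward",
                        "mental_health_index", "risk_steps", "horizon",
                        "n", "policy", "seed")])
}
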