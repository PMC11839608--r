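#' Plot methods
#'
#' `autoplot()` gives a standard ggplot view of each result type: loss or
#' return traces for fitted objects, per-participant engagement
#' trajectories for simulation runs, and the power spectrum for EEG traces.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return a ggplot.
#' @name apeo_autoplot
NULL

#' @rdname apeo_autoplot
#' @export
autoplot.apeo_rnn_fit <- function(object, ...) {
  ggplot(object$loss_trace, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    labs(x = "epoch", y = "training loss",
         title = "Engagement predictor training")
}

#' @rdname apeo_autoplot
#' @export
autoplot.apeo_policy <- function(object, ...) {
  ggplot(object$returns, aes(x = .data$episode, y = .data$return)) +
    geom_line() +
    labs(x = "episode", y = "return", title = "Q-learning returns")
}

#' @rdname apeo_autoplot
#' @export
autoplot.apeo_group_policy <- function(object, ...) {
  ggplot(object$schedule, aes(x = .data$t, y = .data$l_group)) +
    geom_line() +
    geom_point(aes(colour = factor(.data$intensity))) +
    labs(x = "step", y = "group cohesion loss", colour = "intensity",
         title = "Greedy group schedule")
}

#' @rdname apeo_autoplot
#' @export
autoplot.apeo_forceopt <- function(object, ...) {
  ggplot(object$loss_trace, aes(x = .data$iter, y = .data$loss)) +
    geom_line() +
    labs(x = "iteration", y = "inefficiency loss",
         title = "Force optimization")
}

#' @rdname apeo_autoplot
#' @export
autoplot.apeo_run <- function(object, ...) {
  ggplot(object$timeseries,
         aes(x = .data$t, y = .data$engagement,
             group = .data$participant_id)) +
    geom_line(alpha = 0.6) +
    labs(x = "step", y = "engagement",
         title = sprintf("Engagement trajectories (%s policy)",
                         object$config$policy))
}

#' @rdname apeo_autoplot
#' @export
autoplot.eeg_trace <- function(object, ...) {
  sp <- psd_welch(object$samples[, 1], object$fs)
  df <- tibble(freq = sp$freq, psd = sp$psd)
  ggplot(dplyr::filter(df, .data$freq <= 50),
         aes(x = .data$freq, y = .data$psd)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz)),
         title = "EEG power spectral density (channel 1)")
}
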