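#' Cohort configuration
#'
#' Builds the settings object consumed by [generate_profiles()]. Each trait is
#' either a single number (held fixed across the cohort) or a distribution
#' spec `list(dist = , ...)` with `dist` one of `"normal"`, `"lognormal"`,
#' `"uniform"` or `"beta"` plus the usual parameters; optional `min`/`max`
#' entries truncate by clipping. Defaults describe a school-age cohort:
#' body mass ~ Normal(55, 8) kg, baseline VO2 ~ Normal(40, 5) mL/kg/min,
#' adaptation time constant tau ~ Uniform(2, 8) steps, enjoyment ~ Beta(2, 2),
#' perceived effort ~ Uniform(0.2, 1) and skill requirement ~ Uniform(0.3, 1).
#'
#' @param fitness_dim length of the standardized fitness vector (default 3:
#'   endurance, strength, composite).
#' @param embedding_dim dimension of the social-influence embeddings.
#' @param body_mass,vo2_baseline,tau,enjoyment,perceived_effort,skill_requirement
#'   trait specs as described above.
#' @param eeg_signature per-state band-power multiplier matrix; see
#'   [default_eeg_signature()].
#' @return a named list of class `apeo_cohort_config`.
#' @export
cohort_config <- function(fitness_dim = 3L,
                          embedding_dim = 2L,
                          body_mass = list(dist = "normal", mean = 55, sd = 8, min = 30),
                          vo2_baseline = list(dist = "normal", mean = 40, sd = 5, min = 20),
                          tau = list(dist = "uniform", min = 2, max = 8),
                          enjoyment = list(dist = "beta", shape1 = 2, shape2 = 2),
                          perceived_effort = list(dist = "uniform", min = 0.2, max = 1),
                          skill_requirement = list(dist = "uniform", min = 0.3, max = 1),
                          eeg_signature = default_eeg_signature()) {
  check_scalar_number(fitness_dim, "fitness_dim", lower = 1)
  check_scalar_number(embedding_dim, "embedding_dim", lower = 1)
  cfg <- list(
    fitness_dim = as.integer(fitness_dim),
    embedding_dim = as.integer(embedding_dim),
    body_mass = body_mass, vo2_baseline = vo2_baseline, tau = tau,
    enjoyment = enjoyment, perceived_effort = perceived_effort,
    skill_requirement = skill_requirement,
    eeg_signature = eeg_signature
  )
  for (key in c("body_mass", "vo2_baseline", "tau", "enjoyment",
                "perceived_effort", "skill_requirement")) {
    validate_trait_spec(cfg[[key]], key)
  }
  structure(cfg, class = "apeo_cohort_config")
}

validate_trait_spec <- function(spec, key) {
  if (is.numeric(spec) && length(spec) == 1L && is.finite(spec)) {
    return(invisible(TRUE))
  }
  if (!is.list(spec) || is.null(spec$dist)) {
    abort(sprintf("config key `%s` must be a number or a list with a `dist` entry.", key),
          class = "apeo_config_error")
  }
  if (!spec$dist %in% c("normal", "lognormal", "uniform", "beta")) {
    abort(sprintf("config key `%s` has unknown dist `%s`.", key, spec$dist),
          class = "apeo_config_error")
  }
  invisible(TRUE)
}

draw_trait <- function(spec, n) {
  if (is.numeric(spec)) {
    return(rep(spec, n))
  }
  x <- switch(spec$dist,
    normal = rnorm(n, spec$mean, spec$sd),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    uniform = runif(n, spec$min, spec$max),
    beta = stats::rbeta(n, spec$shape1, spec$shape2)
  )
  if (!is.null(spec$min) && spec$dist != "uniform") x <- pmax(x, spec$min)
  if (!is.null(spec$max) && spec$dist != "uniform") x <- pmin(x, spec$max)
  x
}

#' Read a cohort configuration from YAML
#'
#' Expects a top-level `cohort` block with optional keys `n`, `seed`,
#' `fitness_dim`, `embedding_dim` and per-trait distribution blocks. Unknown
#' keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return list with elements `n`, `seed` and `config` (an
#'   `apeo_cohort_config`).
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$cohort)) {
    abort("config file must contain a top-level `cohort` block.",
          class = "apeo_config_error")
  }
  blk <- normalize_yaml_names(raw$cohort)
  known <- c("n", "seed", "fitness_dim", "embedding_dim", "body_mass",
             "vo2_baseline", "tau", "enjoyment", "perceived_effort",
             "skill_requirement")
  bad <- setdiff(names(blk), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown cohort config key(s): %s", paste(bad, collapse = ", ")),
          class = "apeo_config_error")
  }
  args <- blk[setdiff(names(blk), c("n", "seed"))]
  cfg <- do.call(cohort_config, args)
  list(n = blk$n %||% 10L, seed = blk$seed %||% 1L, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML 1.1 parses a bare `n:` key as the boolean FALSE; map it back, and
# accept the unambiguous spelling `n_participants` as well.
normalize_yaml_names <- function(x) {
  nm <- names(x)
  nm[nm %in% c("FALSE", "n_participants")] <- "n"
  names(x) <- nm
  x
}

#' Generate a synthetic participant cohort
#'
#' Draws `n` participant profiles with latent traits (body mass, baseline
#' VO2, adaptation time constant, enjoyment, perceived effort, skill
#' requirement), a social embedding vector, and the per-state EEG band-power
#' signature used by the synthetic EEG generator. Each participant carries a
#' private RNG seed derived arithmetically from the master seed, so enlarging
#' the cohort never perturbs the streams of existing participants.
#'
#' @param n cohort size (>= 1).
#' @param config an [cohort_config()] object.
#' @param seed master integer seed.
#' @return a tibble with one row per participant; `embedding` and
#'   `eeg_signature` are list-columns.
#' @export
generate_profiles <- function(n, config = cohort_config(), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a single integer >= 1.", class = "apeo_invalid_argument")
  }
  if (!inherits(config, "apeo_cohort_config")) {
    abort("`config` must come from cohort_config().", class = "apeo_config_error")
  }
  n <- as.integer(n)
  rows <- lapply(seq_len(n), function(i) {
    si <- derive_seed(seed, i)
    with_seed(si, {
      tibble(
        id = i,
        body_mass = draw_trait(config$body_mass, 1L),
        vo2_baseline = draw_trait(config$vo2_baseline, 1L),
        tau = draw_trait(config$tau, 1L),
        enjoyment = draw_trait(config$enjoyment, 1L),
        perceived_effort = draw_trait(config$perceived_effort, 1L),
        skill_requirement = draw_trait(config$skill_requirement, 1L),
        embedding = list(rnorm(config$embedding_dim)),
        eeg_signature = list(config$eeg_signature),
        rng_seed = si
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  stopifnot(all(out$perceived_effort > 0), all(out$skill_requirement > 0),
            all(out$tau > 0), all(out$body_mass > 0))
  attr(out, "fitness_dim") <- config$fitness_dim
  class(out) <- c("apeo_cohort", class(out))
  out
}

#' Endurance and strength fitness attributes
#'
#' Standardized fitness scores: relative VO2max gain
#' `(vo2max - vo2_baseline) / vo2_baseline` and strength-to-weight ratio
#' `w_max / w_body`.
#'
#' @param vo2max,vo2_baseline maximal and baseline oxygen uptake
#'   (mL/kg/min), `vo2_baseline > 0`.
#' @param w_max maximal force output; `w_body` body weight (> 0).
#' @return tibble with columns `f_endurance`, `f_strength`.
#' @export
fitness_attributes <- function(vo2max, vo2_baseline, w_max, w_body) {
  if (any(vo2_baseline <= 0)) {
    abort("`vo2_baseline` must be > 0.", class = "apeo_domain_error")
  }
  if (any(w_body <= 0)) {
    abort("`w_body` must be > 0.", class = "apeo_domain_error")
  }
  tibble(
    f_endurance = (vo2max - vo2_baseline) / vo2_baseline,
    f_strength = w_max / w_body
  )
}

#' Physical-literacy latent score (forward model)
#'
#' Forward generator for the latent literacy construct: `L = W x + eps` with
#' Gaussian noise. With `noise_sd = 0` the map is deterministic. Estimation
#' of the loadings is out of scope; ordinary least squares on simulated data
#' recovers them, which the test-suite uses as the identification check.
#'
#' @param x observable vector, or a matrix with one row per subject.
#' @param loadings numeric loading vector `W`, matched to `ncol(x)`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed optional seed for the noise draw.
#' @return numeric vector of latent scores.
#' @export
literacy_score <- function(x, loadings, noise_sd = 0, seed = NULL) {
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(loadings)) {
    abort(sprintf("`x` has %d columns but `loadings` has length %d.",
                  ncol(x), length(loadings)),
          class = "apeo_shape_error")
  }
  mu <- drop(x %*% loadings)
  if (noise_sd == 0) return(mu)
  eps <- if (is.null(seed)) rnorm(length(mu), 0, noise_sd)
         else with_seed(seed, rnorm(length(mu), 0, noise_sd))
  mu + eps
}

#' Participation probability
#'
#' Sigmoid participation model `P = sigma(E'wE + C'wC)` over engagement
#' factors `E` and physical-condition factors `C`.
#'
#' @param e,c factor vectors (or matrices with one row per subject).
#' @param w_e,w_c weight vectors matched to `e` and `c`.
#' @return probability vector, strictly inside (0, 1) for finite input.
#' @export
participation_probability <- function(e, c, w_e, w_c) {
  if (is.vector(e)) e <- matrix(e, nrow = 1L)
  if (is.vector(c)) c <- matrix(c, nrow = 1L)
  if (ncol(e) != length(w_e)) {
    abort("`e` and `w_e` dimensions do not match.", class = "apeo_shape_error")
  }
  if (ncol(c) != length(w_c)) {
    abort("`c` and `w_c` dimensions do not match.", class = "apeo_shape_error")
  }
  sigmoid(drop(e %*% w_e) + drop(c %*% w_c))
}

#' Generate an external-disturbance series
#'
#' Zero-mean disturbance stream feeding the state dynamics (fatigue,
#' environment). Default is i.i.d. Gaussian; `ar` in (0, 1) switches to a
#' stationary AR(1) process with the same marginal scale, for serially
#' correlated sources such as accumulating fatigue.
#'
#' @param n_steps series length (>= 1).
#' @param scale marginal standard deviation (>= 0); 0 gives an all-zero series.
#' @param seed integer seed.
#' @param dim number of disturbance channels.
#' @param ar AR(1) coefficient in `[0, 1)`.
#' @return numeric matrix `n_steps x dim`.
#' @export
generate_disturbances <- function(n_steps, scale, seed = 1L, dim = 1L, ar = 0) {
  check_scalar_number(n_steps, "n_steps", lower = 1)
  if (!is.numeric(scale) || length(scale) != 1L || scale < 0) {
    abort("`scale` must be a single number >= 0.", class = "apeo_invalid_argument")
  }
  check_scalar_number(ar, "ar", lower = 0, upper = 1 - 1e-12)
  n_steps <- as.integer(n_steps)
  if (scale == 0) return(matrix(0, n_steps, dim))
  with_seed(seed, {
    eps <- matrix(rnorm(n_steps * dim, 0, scale), n_steps, dim)
    if (ar == 0) return(eps)
    d <- matrix(0, n_steps, dim)
    innov_sd <- sqrt(1 - ar^2)
    d[1, ] <- eps[1, ]
    for (t in 2:n_steps) d[t, ] <- ar * d[t - 1, ] + innov_sd * eps[t, ]
    d
  })
}

#' Write / read a cohort as CSV
#'
#' List-columns (embedding) are flattened to `embedding_1..embedding_k`; the
#' shared EEG signature travels separately via [default_eeg_signature()].
#'
#' @param cohort a cohort tibble from [generate_profiles()].
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the tibble.
#' @export
write_cohort <- function(cohort, path) {
  emb <- do.call(rbind, cohort$embedding)
  colnames(emb) <- paste0("embedding_", seq_len(ncol(emb)))
  flat <- dplyr::bind_cols(
    dplyr::select(as_tibble(cohort), -"embedding", -"eeg_signature"),
    as_tibble(emb)
  )
  readr::write_csv(flat, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE)
  emb_cols <- grep("^embedding_", names(flat), value = TRUE)
  emb <- as.matrix(flat[, emb_cols])
  out <- dplyr::select(flat, -dplyr::all_of(emb_cols))
  out$embedding <- lapply(seq_len(nrow(emb)), function(i) unname(emb[i, ]))
  out$eeg_signature <- rep(list(default_eeg_signature()), nrow(out))
  class(out) <- c("apeo_cohort", class(out))
  out
}
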