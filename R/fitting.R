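#' Tumor-volume observation series
#'
#' A measured (or synthetic) total tumor volume time series together with the
#' fractionation schedule under which it was observed; the input of
#' [fit_parameters()]. Volumes are percent of the initial (day 0) volume, so
#' a day-0 observation, if present, must equal 100.
#'
#' @param days Observation days (non-negative, strictly increasing).
#' @param v_t Total tumor volumes, percent of initial (> 0).
#' @param schedule The `radfrac_schedule` delivered while the series was
#'   observed.
#' @return An object of class `radfrac_series`: list with `observations`
#'   (data frame `day`, `v_t`) and `schedule`.
#' @export
volume_series <- function(days, v_t, schedule) {
  stopifnot(inherits(schedule, "radfrac_schedule"))
  if (length(days) != length(v_t) || length(days) == 0)
    stop("need aligned, non-empty day and volume vectors", call. = FALSE)
  if (any(days < 0) || any(diff(days) <= 0))
    stop("observation days must be non-negative and strictly increasing",
         call. = FALSE)
  if (any(v_t <= 0)) stop("volumes must be positive", call. = FALSE)
  if (days[1] == 0 && abs(v_t[1] - 100) > 1e-8)
    stop("the day-0 volume must be 100 (volumes are percent of initial)",
         call. = FALSE)
  structure(list(observations = data.frame(day = as.integer(days), v_t = v_t),
                 schedule = schedule),
            class = "radfrac_series")
}

# Vectorized re-simulation across parameter draws: same dynamics as
# simulate_course()/tumor_step(), but carried as vectors over draws so that a
# Monte Carlo search over tens of thousands of parameter sets stays cheap.
# `theta` is an n x 4 matrix with columns rho, t_half, k_hat, gamma_v.
# Returns the n x length(obs_days) matrix of total volumes at the requested
# days (start-of-day states, day 0 = 100). Agreement with simulate_course()
# is asserted in the test suite.
simulate_vt_batch <- function(theta, schedule, obs_days,
                              constants = model_constants()) {
  rho <- theta[, 1]; t_half <- theta[, 2]
  k <- theta[, 3]; gamma_v <- theta[, 4]
  n <- nrow(theta)
  horizon <- max(max(obs_days), max(schedule$fractions$day) + 1L)
  dose_by_day <- numeric(horizon + 1L)
  dose_by_day[schedule$fractions$day + 1L] <- schedule$fractions$dose_Gy

  v_a <- rep(100, n)
  v_n <- numeric(n)
  dec <- 2^(-1 / t_half)
  out <- matrix(NA_real_, n, length(obs_days))
  grab <- match(0:horizon, obs_days)
  for (t in 0:horizon) {
    j <- grab[t + 1L]
    if (!is.na(j)) out[, j] <- v_a + v_n
    if (t == horizon) break
    po2 <- pmin(pmax(100 * (k - v_a) / k, 0), 100)
    alpha <- constants$alpha_min +
      po2 / 100 * (constants$alpha_max - constants$alpha_min)
    d <- dose_by_day[t + 1L]
    if (d > 0) {
      sf_t <- exp(-alpha * d * (1 + d / constants$ab_tumor))
      sf_v <- exp(-alpha * gamma_v * d * (1 + d / constants$ab_vasc))
      new_necrosis <- v_a * (1 - sf_t)
    } else {
      sf_t <- 1; sf_v <- 1; new_necrosis <- 0
    }
    grown <- v_a * pmax(1 + rho * log(k / v_a), 0)
    v_a <- grown * sf_t
    k <- k * sf_v
    v_n <- (v_n + new_necrosis) * dec
  }
  out
}

#' Monte Carlo fit of the four free patient parameters
#'
#' Plain uniform random search: draws `n_samples` parameter vectors
#' (`rho`, `t_half`, `k_hat`, `gamma_v`) uniformly within `bounds`, simulates
#' each under the series' schedule, and scores the root-mean-square error
#' between simulated and observed total volume at the observation days. The
#' draws are a deterministic function of `seed`, and are generated so that
#' the first `m` draws of any larger budget coincide with the draws of a
#' budget-`m` run: the best loss is non-increasing in `n_samples`.
#'
#' Because distinct `(t_half, gamma_v)` pairs can produce near-identical
#' total-volume fits, the top `top_k` parameter vectors are returned along
#' with the winner so that identifiability problems are visible rather than
#' hidden.
#'
#' @param series A [volume_series()].
#' @param bounds A [parameter_bounds()] object.
#' @param n_samples Number of random draws (>= 1).
#' @param seed Integer seed making the search reproducible.
#' @param top_k Number of best parameter vectors to report.
#' @param constants A [model_constants()] object.
#' @return A list with `best` (a [patient_parameters()] object, id `"fit"`),
#'   `loss` (RMSE of the winner), `top` (data frame of the `top_k` best
#'   draws: parameters + `loss`), `n_samples` and `seed`.
#' @examples
#' b <- patient_parameters("B", 0.07, 28, 150, 0.7)
#' sched <- constant_schedule(1.8)
#' obs <- generate_series(b, sched, obs_days = seq(0, 28, by = 7))
#' fit <- fit_parameters(obs, n_samples = 200, seed = 1)
#' @export
fit_parameters <- function(series, bounds = parameter_bounds(),
                           n_samples, seed, top_k = 10,
                           constants = model_constants()) {
  stopifnot(inherits(series, "radfrac_series"),
            inherits(bounds, "radfrac_bounds"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 1) stop("n_samples must be at least 1", call. = FALSE)
  if (nrow(series$observations) < 2)
    stop("need at least 2 observations to fit", call. = FALSE)

  theta <- with_preserved_rng(seed, {
    # draw row-wise so a budget-m run shares its draws with any larger budget
    u <- matrix(stats::runif(4L * n_samples), ncol = 4L, byrow = TRUE)
    lower <- vapply(bounds, `[`, 0, 1)[c("rho", "t_half", "k_hat", "gamma_v")]
    upper <- vapply(bounds, `[`, 0, 2)[c("rho", "t_half", "k_hat", "gamma_v")]
    sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  })

  sim <- simulate_vt_batch(theta, series$schedule, series$observations$day,
                           constants)
  resid <- sweep(sim, 2, series$observations$v_t, "-")
  loss <- sqrt(rowMeans(resid^2))
  bad <- !is.finite(loss)
  if (any(bad)) {
    warning(sum(bad), " draw(s) could not be simulated and were skipped",
            call. = FALSE)
    loss[bad] <- Inf
  }
  ord <- order(loss)
  top_idx <- ord[seq_len(min(top_k, n_samples))]
  top <- data.frame(rho = theta[top_idx, 1], t_half = theta[top_idx, 2],
                    k_hat = theta[top_idx, 3], gamma_v = theta[top_idx, 4],
                    loss = loss[top_idx])
  best <- patient_parameters("fit", top$rho[1], top$t_half[1],
                             top$k_hat[1], top$gamma_v[1], relaxed = TRUE)
  list(best = best, loss = top$loss[1], top = top,
       n_samples = n_samples, seed = seed)
}

#' Generate a synthetic tumor-volume series
#'
#' Simulates a course and samples the total volume at the requested days,
#' optionally perturbed by multiplicative Gaussian noise (volumes span orders
#' of magnitude over a regression, so noise proportional to the signal is the
#' realistic choice). The day-0 observation, if requested, is left at exactly
#' 100 since volumes are normalized to baseline by construction. Stands in
#' for clinical volume measurements in parameter-recovery studies.
#'
#' @param params A [patient_parameters()] object (the ground truth).
#' @param schedule A `radfrac_schedule`.
#' @param obs_days Observation days (within the simulated horizon).
#' @param noise_sd Multiplicative noise standard deviation, percent of the
#'   noiseless value (0 = exact model output).
#' @param seed Optional integer seed for the noise.
#' @param constants A [model_constants()] object.
#' @return A [volume_series()].
#' @export
generate_series <- function(params, schedule, obs_days, noise_sd = 0,
                            seed = NULL, constants = model_constants()) {
  if (any(obs_days < 0)) stop("observation days must be non-negative",
                              call. = FALSE)
  horizon <- max(max(obs_days), max(schedule$fractions$day) + 1L)
  sim <- simulate_course(params, schedule, constants, horizon = horizon)
  v_t <- sim$trajectory$V_t[match(obs_days, sim$trajectory$day)]
  if (noise_sd > 0) {
    factor <- with_preserved_rng(seed,
      1 + stats::rnorm(length(v_t), sd = noise_sd / 100))
    factor[obs_days == 0] <- 1
    v_t <- pmax(v_t * factor, 1e-6)
  }
  volume_series(obs_days, v_t, schedule)
}

#' Correlate model oxygenation with a vascularization index series
#'
#' Doppler-derived indices (vascularization index, flow index, ...) relate to
#' tumor oxygen availability without measuring it directly; the Pearson
#' correlation between such an index and the model's oxygenation surrogate is
#' used to judge whether the simulated vasculature/oxygenation dynamics track
#' the observed ones.
#'
#' @param po2_series Model oxygenation surrogate values (e.g. the `PO2`
#'   column of a simulated trajectory, subset to the index's days).
#' @param index_series User-supplied index values, aligned with `po2_series`.
#' @return Pearson correlation coefficient.
#' @export
correlate_oxygenation <- function(po2_series, index_series) {
  if (length(po2_series) != length(index_series) || length(po2_series) < 3)
    stop("need at least 3 aligned points", call. = FALSE)
  if (stats::sd(po2_series) == 0 || stats::sd(index_series) == 0)
    stop("correlation undefined for constant series", call. = FALSE)
  stats::cor(po2_series, index_series)
}

# Run `expr` under a local RNG stream seeded with `seed` (if non-NULL),
# restoring the caller's RNG state afterwards.
with_preserved_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
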