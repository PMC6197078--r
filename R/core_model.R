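#' Tumor oxygenation surrogate
#'
#' Average oxygen partial-pressure surrogate on a 0-100 scale. Oxygen supply
#' is set by the vasculature (carrying capacity `k`) while consumption is set
#' by the active tumor cells, so the surrogate is the relative headroom of
#' the capacity over the active volume, `100 * (k - v_a) / k`, clamped to
#' `[0, 100]` (the capacity can be driven below the active volume by heavy
#' vascular damage, in which case oxygenation is floored at 0).
#'
#' @param k Carrying capacity, percent of initial tumor volume (> 0).
#' @param v_a Active tumor volume, percent of initial (>= 0).
#' @return Oxygenation surrogate in `[0, 100]`.
#' @examples
#' oxygen_pressure(220, 100)  # 54.5: well-oxygenated tumor below capacity
#' oxygen_pressure(150, 150)  # 0: tumor at capacity
#' @export
oxygen_pressure <- function(k, v_a) {
  if (!is.finite(k) || k <= 0)
    stop("carrying capacity must be positive", call. = FALSE)
  if (!is.finite(v_a) || v_a < 0)
    stop("active volume must be non-negative", call. = FALSE)
  min(max(100 * (k - v_a) / k, 0), 100)
}

#' Oxygenation-dependent radiosensitivity
#'
#' Linear map from the oxygenation surrogate to the linear-quadratic alpha
#' coefficient: fully hypoxic tumor tissue is nearly radioresistant
#' (`alpha_min`), fully oxygenated tissue is maximally sensitive
#' (`alpha_max`).
#'
#' @param po2 Oxygenation surrogate in `[0, 100]` (see [oxygen_pressure()]).
#' @param constants A [model_constants()] object.
#' @return Radiosensitivity alpha in 1/Gy, within
#'   `[alpha_min, alpha_max]`.
#' @examples
#' radiosensitivity(0)    # 0.001
#' radiosensitivity(100)  # 0.3
#' @export
radiosensitivity <- function(po2, constants = model_constants()) {
  if (!is.finite(po2) || po2 < 0 || po2 > 100)
    stop("oxygenation surrogate must lie in [0, 100]", call. = FALSE)
  constants$alpha_min + po2 / 100 * (constants$alpha_max - constants$alpha_min)
}

#' Linear-quadratic surviving fraction
#'
#' Fraction of a cell population (tumor, `gamma = 1`) or of the vascular
#' capacity (`gamma < 1`) surviving a single fraction of dose `d`:
#' `exp(-alpha * gamma * d * (1 + d / ab))`.
#'
#' @param alpha Radiosensitivity, 1/Gy (> 0).
#' @param gamma Kill coefficient (>= 0); 1 for tumor, below 1 for the less
#'   radiosensitive vasculature.
#' @param d Fraction dose, Gy (>= 0).
#' @param ab Alpha/beta ratio, Gy (> 0).
#' @return Surviving fraction in `(0, 1]`; strictly decreasing in each of
#'   `alpha`, `gamma` and `d`, and exactly 1 at `d = 0`.
#' @examples
#' surviving_fraction(0.3, 1, 1.8, 10)    # ~0.529, the worst case at 1.8 Gy
#' surviving_fraction(0.001, 1, 1.8, 10)  # ~0.998, fully hypoxic tumor
#' @export
surviving_fraction <- function(alpha, gamma, d, ab) {
  if (!is.finite(d) || d < 0) stop("dose must be non-negative", call. = FALSE)
  if (alpha <= 0 || gamma < 0 || ab <= 0)
    stop("need alpha > 0, gamma >= 0, ab > 0", call. = FALSE)
  exp(-alpha * gamma * d * (1 + d / ab))
}

#' Initial tumor state
#'
#' The model state at day 0 (first irradiation): fully active tumor at 100%
#' of its initial volume, no necrosis, carrying capacity at the patient's
#' initial value.
#'
#' @param params A [patient_parameters()] object.
#' @return An object of class `radfrac_state`: list with day index `t`,
#'   active volume `v_a`, carrying capacity `k`, and the necrotic cohort
#'   ledger `cohorts` (data frame with creation day `t_i` and created volume
#'   `v0`).
#' @export
initial_state <- function(params) {
  stopifnot(inherits(params, "radfrac_patient"))
  structure(list(t = 0L, v_a = 100, k = params$k_hat,
                 cohorts = data.frame(t_i = integer(0), v0 = numeric(0))),
            class = "radfrac_state")
}

#' Necrotic volume of a state
#'
#' Each irradiation day creates a necrotic cohort that is reabsorbed
#' exponentially from its creation day with the patient's clearance
#' half-time: the total necrotic volume at day `t` is
#' `sum_i v0_i * 2^(-(t - t_i) / t_half)`.
#'
#' @param state A `radfrac_state` (see [initial_state()], [tumor_step()]).
#' @param t_half Clearance half-time, days.
#' @return Necrotic volume, percent of initial tumor volume.
#' @export
necrotic_volume <- function(state, t_half) {
  stopifnot(inherits(state, "radfrac_state"))
  if (nrow(state$cohorts) == 0) return(0)
  sum(state$cohorts$v0 * 2^(-(state$t - state$cohorts$t_i) / t_half))
}

#' One daily update of the tumor system
#'
#' Advances the state from day `t` to day `t + 1`. Within the day:
#' oxygenation and radiosensitivity are evaluated on the start-of-day state;
#' the active tumor takes its Gompertz growth increment
#' `v_a + rho * log(k / v_a) * v_a` and is then culled by the tumor surviving
#' fraction; on irradiation days the killed cells are booked as a new
#' necrotic cohort and the carrying capacity is damaged by the vascular
#' surviving fraction. Non-treatment days (`dose = 0` or `NULL`) have both
#' surviving fractions equal to 1: the tumor grows and necrosis clears, but
#' nothing is killed.
#'
#' @param state A `radfrac_state`.
#' @param dose Fraction dose in Gy, or `NULL`/0 for a rest day.
#' @param params A [patient_parameters()] object.
#' @param constants A [model_constants()] object.
#' @param mass_conserving If `TRUE`, the necrotic cohort created on an
#'   irradiation day is the killed part of the *grown* volume,
#'   `G * (1 - SF_t)`, so that active + new necrotic exactly equals the grown
#'   volume. The default (`FALSE`) books `v_a(t) * (1 - SF_t)`, the killed
#'   part of the start-of-day volume, matching the model's published update
#'   rule.
#' @return The `radfrac_state` at day `t + 1`, with attributes `po2`,
#'   `alpha`, `sf_t`, `sf_v` recording the quantities applied during the day.
#' @examples
#' a <- patient_parameters("A", 0.17, 14, 220, 0.9)
#' s1 <- tumor_step(initial_state(a), 1.8, a)
#' s1$v_a  # ~80: one standard fraction kills ~30% of the grown volume
#' @export
tumor_step <- function(state, dose, params, constants = model_constants(),
                       mass_conserving = FALSE) {
  stopifnot(inherits(state, "radfrac_state"),
            inherits(params, "radfrac_patient"))
  d <- if (is.null(dose)) 0 else dose
  if (!is.finite(d) || d < 0) stop("dose must be non-negative", call. = FALSE)

  po2 <- oxygen_pressure(state$k, state$v_a)
  alpha <- radiosensitivity(po2, constants)
  sf_t <- surviving_fraction(alpha, constants$gamma_tumor, d, constants$ab_tumor)
  sf_v <- surviving_fraction(alpha, params$gamma_v, d, constants$ab_vasc)

  # Gompertz daily increment, floored so a pathological k << v_a cannot
  # flip the grown volume negative in one step.
  growth_factor <- max(1 + params$rho * log(state$k / state$v_a), 0)
  grown <- state$v_a * growth_factor

  cohorts <- state$cohorts
  if (d > 0) {
    source_volume <- if (mass_conserving) grown else state$v_a
    cohorts <- rbind(cohorts,
                     data.frame(t_i = state$t, v0 = source_volume * (1 - sf_t)))
  }

  v_a_new <- grown * sf_t
  k_new <- state$k * sf_v
  if (!is.finite(v_a_new) || v_a_new <= 0 || !is.finite(k_new) || k_new <= 0)
    stop(sprintf("state driven non-positive at day %d (v_a = %g, k = %g)",
                 state$t + 1L, v_a_new, k_new), call. = FALSE)

  out <- structure(list(t = state$t + 1L, v_a = v_a_new, k = k_new,
                        cohorts = cohorts), class = "radfrac_state")
  attr(out, "po2") <- po2
  attr(out, "alpha") <- alpha
  attr(out, "sf_t") <- sf_t
  attr(out, "sf_v") <- sf_v
  out
}

#' Simulate a full radiotherapy course
#'
#' Runs the daily update from day 0 (first irradiation; fully active tumor at
#' 100%) through the endpoint day, applying the schedule's fractions on their
#' calendar days and plain growth/clearance days elsewhere (weekends are
#' ordinary rest days).
#'
#' @param params A [patient_parameters()] object.
#' @param schedule A `radfrac_schedule` (see [constant_schedule()],
#'   [ramp_schedule()]).
#' @param constants A [model_constants()] object.
#' @param horizon Endpoint day. The default, one day after the last fraction,
#'   is the state immediately after the full course has acted; larger values
#'   extend the follow-up with rest days.
#' @param mass_conserving Passed to [tumor_step()].
#' @return An object of class `radfrac_sim`: list with
#'   \describe{
#'     \item{trajectory}{data frame with one row per day from 0 to the
#'       endpoint, columns `day, dose_Gy, V_a, V_n, V_t, PO2, alpha, SF_t,
#'       SF_v, k`. Volumes and `k` are the start-of-day state in percent of
#'       the initial volume; `PO2`, `alpha` and the surviving fractions are
#'       the values applied during that day (1 on rest days and, by
#'       convention, on the endpoint day itself).}
#'     \item{t_e}{endpoint day,}
#'     \item{v_a_final, v_n_final, v_t_final}{endpoint volumes,}
#'     \item{params, schedule}{the inputs.}
#'   }
#' @examples
#' b <- patient_parameters("B", 0.07, 28, 150, 0.7)
#' sim <- simulate_course(b, constant_schedule(1.8))
#' sim$v_a_final  # ~7.3% of initial
#' @export
simulate_course <- function(params, schedule, constants = model_constants(),
                            horizon = NULL, mass_conserving = FALSE) {
  stopifnot(inherits(params, "radfrac_patient"),
            inherits(schedule, "radfrac_schedule"))
  if (schedule$n == 0) stop("schedule has no fractions", call. = FALSE)
  t_e <- if (is.null(horizon)) max(schedule$fractions$day) + 1L
         else as.integer(horizon)
  if (t_e < max(schedule$fractions$day) + 1L)
    stop("horizon must reach past the last fraction", call. = FALSE)

  dose_by_day <- numeric(t_e + 1L)
  dose_by_day[schedule$fractions$day + 1L] <- schedule$fractions$dose_Gy

  n_rows <- t_e + 1L
  traj <- data.frame(day = 0:t_e, dose_Gy = dose_by_day,
                     V_a = numeric(n_rows), V_n = numeric(n_rows),
                     V_t = numeric(n_rows), PO2 = numeric(n_rows),
                     alpha = numeric(n_rows), SF_t = numeric(n_rows),
                     SF_v = numeric(n_rows), k = numeric(n_rows))
  state <- initial_state(params)
  for (t in 0:t_e) {
    i <- t + 1L
    traj$V_a[i] <- state$v_a
    traj$V_n[i] <- necrotic_volume(state, params$t_half)
    traj$k[i] <- state$k
    if (t < t_e) {
      state <- tumor_step(state, dose_by_day[i], params, constants,
                          mass_conserving)
      traj$PO2[i] <- attr(state, "po2")
      traj$alpha[i] <- attr(state, "alpha")
      traj$SF_t[i] <- attr(state, "sf_t")
      traj$SF_v[i] <- attr(state, "sf_v")
    } else {
      # endpoint row: state is recorded, no further update is applied
      traj$PO2[i] <- oxygen_pressure(state$k, state$v_a)
      traj$alpha[i] <- radiosensitivity(traj$PO2[i], constants)
      traj$SF_t[i] <- 1
      traj$SF_v[i] <- 1
    }
  }
  traj$V_t <- traj$V_a + traj$V_n

  structure(list(trajectory = traj, t_e = t_e,
                 v_a_final = traj$V_a[n_rows],
                 v_n_final = traj$V_n[n_rows],
                 v_t_final = traj$V_t[n_rows],
                 params = params, schedule = schedule),
            class = "radfrac_sim")
}

#' @export
print.radfrac_sim <- function(x, ...) {
  cat(sprintf(
    "simulated course for patient %s under '%s'\n  endpoint day %d: V_a = %.2f%%, V_n = %.2f%%, V_t = %.2f%% of initial\n",
    x$params$id, x$schedule$label, x$t_e,
    x$v_a_final, x$v_n_final, x$v_t_final))
  invisible(x)
}
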