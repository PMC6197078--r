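#' Constant-dose regimen grid over a cohort
#'
#' Simulates every patient of a cohort under each constant dose-per-fraction
#' arm (each arm built by [constant_schedule()] at the common target BED) and
#' collects the endpoint volumes.
#'
#' @param cohort A `radfrac_cohort` or list of [patient_parameters()].
#' @param doses Dose-per-fraction arms, Gy.
#' @param target_bed,constants,mass_conserving Passed to the schedule builder
#'   and simulator.
#' @return A data frame of class `radfrac_grid` with one row per patient x
#'   dose: `patient`, `dose`, `n_fractions`, `bed`, `v_a_final`, `v_t_final`.
#' @examples
#' grid <- run_dose_grid(reference_cohort()["A"])
#' @export
run_dose_grid <- function(cohort, doses = c(1, 1.5, 1.8, 2, 2.5, 3),
                          target_bed = 60, constants = model_constants(),
                          mass_conserving = FALSE) {
  schedules <- lapply(doses, constant_schedule, target_bed = target_bed,
                      ab = constants$ab_tumor)
  rows <- lapply(cohort, function(p) {
    finals <- lapply(schedules, function(s)
      simulate_course(p, s, constants, mass_conserving = mass_conserving))
    data.frame(patient = p$id, dose = doses,
               n_fractions = vapply(schedules, `[[`, 0, "n"),
               bed = vapply(schedules, `[[`, 0, "bed"),
               v_a_final = vapply(finals, `[[`, 0, "v_a_final"),
               v_t_final = vapply(finals, `[[`, 0, "v_t_final"))
  })
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            class = c("radfrac_grid", "data.frame"))
}

#' Pearson correlation between dose per fraction and final volume
#'
#' The sign of this correlation summarizes a patient's dose response across
#' the constant-dose arms: negative means larger fractions help
#' (hypofractionation candidate), positive means smaller fractions spread
#' over a longer course help (hyperfractionation candidate).
#'
#' @param doses Dose-per-fraction values, Gy.
#' @param finals Final volumes under each dose, percent of initial.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
dose_response_correlation <- function(doses, finals) {
  if (length(doses) != length(finals) || length(doses) < 3)
    stop("need at least 3 aligned (dose, final volume) points", call. = FALSE)
  if (stats::sd(doses) == 0 || stats::sd(finals) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  stats::cor(doses, finals)
}

#' Classify a best dose as hypo-, standard or hyperfractionation
#'
#' Standard clinical fractionation is 1.8-2 Gy per fraction; regimens with
#' larger best fractions are hypofractionated (fewer, larger fractions),
#' smaller ones hyperfractionated.
#'
#' @param best_dose Best dose per fraction, Gy.
#' @return `"hypo"`, `"strd"` or `"hyper"`.
#' @examples
#' classify_regimen(3)   # "hypo"
#' classify_regimen(2)   # "strd"
#' classify_regimen(1)   # "hyper"
#' @export
classify_regimen <- function(best_dose) {
  if (best_dose > 2) "hypo" else if (best_dose < 1.8) "hyper" else "strd"
}

#' Per-patient regimen ranking from a dose grid
#'
#' Selects, for each patient, the constant-dose arm giving the largest final
#' regression of the chosen endpoint (ties go to the lower dose), classifies
#' it, and computes the dose-response correlation.
#'
#' @param grid A `radfrac_grid` from [run_dose_grid()].
#' @param endpoint `"active"` (default) to rank by final active volume,
#'   `"total"` to rank by final overall (active + necrotic) volume.
#' @return A data frame with one row per patient: `patient`, `best_dose`,
#'   `best_final`, `category`, `correlation`.
#' @examples
#' rank_regimens(run_dose_grid(reference_cohort()["A"]))
#' @export
rank_regimens <- function(grid, endpoint = c("active", "total")) {
  endpoint <- match.arg(endpoint)
  col <- if (endpoint == "active") "v_a_final" else "v_t_final"
  out <- lapply(split(grid, grid$patient), function(g) {
    g <- g[order(g$dose), ]
    best <- which.min(g[[col]])  # first minimum -> lower dose on ties
    data.frame(patient = g$patient[1],
               best_dose = g$dose[best],
               best_final = g[[col]][best],
               category = classify_regimen(g$dose[best]),
               correlation = dose_response_correlation(g$dose, g[[col]]))
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$patient), ]
}

#' Minimum BED to reach a prescribed regression
#'
#' Simulates a course day by day and finds the first day on which the active
#' volume has dropped below `threshold` percent of the initial volume. The
#' reported cumulative BED is that of the fractions actually delivered by the
#' time the crossing state is observed (i.e. including the fraction whose
#' daily update produced the crossing). If the course never achieves the
#' regression, the crossing day and BED are `NA`: an early stop is simply not
#' available for that regimen.
#'
#' @param params A [patient_parameters()] object.
#' @param schedule A `radfrac_schedule`.
#' @param threshold Active-volume threshold, percent of initial (default 20,
#'   i.e. an 80% regression).
#' @param constants,mass_conserving Passed to [simulate_course()].
#' @return A list with `patient`, `label`, `crossing_day` (integer or `NA`),
#'   `bed` (Gy or `NA`), and `n_fractions` delivered at the crossing.
#' @examples
#' b <- patient_parameters("B", 0.07, 28, 150, 0.7)
#' min_bed_to_threshold(b, constant_schedule(1))  # ~58 Gy
#' @export
min_bed_to_threshold <- function(params, schedule, threshold = 20,
                                 constants = model_constants(),
                                 mass_conserving = FALSE) {
  if (threshold <= 0 || threshold > 100)
    stop("threshold must lie in (0, 100]", call. = FALSE)
  sim <- simulate_course(params, schedule, constants,
                         mass_conserving = mass_conserving)
  traj <- sim$trajectory
  cross <- which(traj$V_a < threshold)[1]
  if (is.na(cross))
    return(list(patient = params$id, label = schedule$label,
                crossing_day = NA_integer_, bed = NA_real_,
                n_fractions = NA_integer_))
  day <- traj$day[cross]
  delivered <- schedule$fractions$day < day  # fractions applied before the
                                             # crossing state is recorded
  list(patient = params$id, label = schedule$label,
       crossing_day = day,
       bed = bed(schedule$fractions$dose_Gy[delivered], schedule$ab),
       n_fractions = sum(delivered))
}

#' Partial-BED table over a cohort and dose arms
#'
#' Applies [min_bed_to_threshold()] to every patient x constant-dose arm.
#'
#' @inheritParams run_dose_grid
#' @param threshold Active-volume threshold, percent of initial.
#' @return Data frame with columns `patient`, `dose`, `crossing_day`, `bed`,
#'   `n_fractions`; `NA` rows mean the regression is never reached.
#' @export
partial_bed_table <- function(cohort, doses = c(1, 1.5, 1.8, 2, 2.5, 3),
                              threshold = 20, target_bed = 60,
                              constants = model_constants()) {
  rows <- lapply(cohort, function(p) {
    per_dose <- lapply(doses, function(d)
      min_bed_to_threshold(p, constant_schedule(d, target_bed,
                                                ab = constants$ab_tumor),
                           threshold, constants))
    data.frame(patient = p$id, dose = doses,
               crossing_day = vapply(per_dose, `[[`, 0L, "crossing_day"),
               bed = vapply(per_dose, `[[`, 0, "bed"),
               n_fractions = vapply(per_dose, `[[`, 0L, "n_fractions"))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Effect of dose ordering in ramped schedules
#'
#' Simulates each patient under the increasing and the decreasing ramp (same
#' dose multiset, hence identical BED) and summarizes how much the final
#' active volume depends on the order of administration: the per-patient
#' absolute difference (in percentage points of the initial volume) and the
#' relative difference normalized by the mean of the two finals.
#'
#' @param cohort A `radfrac_cohort` or list of [patient_parameters()].
#' @param d_min,d_max,delta,per_week Ramp geometry, see [ramp_schedule()].
#' @param constants A [model_constants()] object.
#' @return A list with `per_patient` (data frame: `patient`, `v_a_up`,
#'   `v_a_down`, `abs_diff`, `rel_diff`), `mean_abs_diff` (percentage points
#'   of initial volume) and `mean_rel_diff_pct` (percent of the mean final
#'   volume).
#' @examples
#' ramp_comparison(reference_cohort()["A"])
#' @export
ramp_comparison <- function(cohort, d_min = 0.5, d_max = 4.5, delta = 0.25,
                            per_week = 5, constants = model_constants()) {
  up <- ramp_schedule(d_min, d_max, delta, "increasing", per_week)
  down <- ramp_schedule(d_min, d_max, delta, "decreasing", per_week)
  per <- lapply(cohort, function(p) {
    fu <- simulate_course(p, up, constants)$v_a_final
    fd <- simulate_course(p, down, constants)$v_a_final
    data.frame(patient = p$id, v_a_up = fu, v_a_down = fd,
               abs_diff = abs(fu - fd),
               rel_diff = abs(fu - fd) / ((fu + fd) / 2))
  })
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  list(per_patient = per,
       mean_abs_diff = mean(per$abs_diff),
       mean_rel_diff_pct = 100 * mean(per$rel_diff))
}
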