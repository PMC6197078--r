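#' Biologically effective dose of a fraction sequence
#'
#' Standard BED of a (possibly non-constant) sequence of fraction doses:
#' `sum(d_i * (1 + d_i / ab))`. BED is the isoeffect currency used to compare
#' fractionation schemes: all schedules built by this package are constrained
#' to a common target BED so that regimens differ in calendar and dose
#' profile, not in total biological effect.
#'
#' @param doses Numeric vector of fraction doses, Gy (may be empty).
#' @param ab Alpha/beta ratio, Gy (default 10, the tumor value).
#' @return BED in Gy. Additive over concatenation and invariant to the order
#'   of fractions.
#' @examples
#' bed(rep(1.8, 28))   # 59.472, the standard-course anchor for "BED ~ 60 Gy"
#' bed(2)              # 2.4
#' @export
bed <- function(doses, ab = 10) {
  if (length(doses) == 0) return(0)
  if (any(!is.finite(doses)) || any(doses < 0))
    stop("fraction doses must be non-negative", call. = FALSE)
  if (ab <= 0) stop("alpha/beta ratio must be positive", call. = FALSE)
  sum(doses * (1 + doses / ab))
}

# Calendar of the i-th fraction (0-based): `per_week` weekdays on, rest off.
# Day 0 is a Monday, so the default 5/week pattern is Mon-Fri with weekend
# gaps during which growth and necrotic clearance continue.
fraction_days <- function(n, per_week = 5) {
  if (per_week < 1 || per_week > 7)
    stop("per_week must be between 1 and 7", call. = FALSE)
  i <- seq_len(n) - 1
  7 * (i %/% per_week) + (i %% per_week)
}

new_schedule <- function(days, doses, label, ab = 10) {
  stopifnot(length(days) == length(doses))
  if (any(diff(days) <= 0)) stop("fraction days must be strictly increasing",
                                 call. = FALSE)
  if (any(doses <= 0)) stop("fraction doses must be positive", call. = FALSE)
  structure(list(
    fractions = data.frame(day = as.integer(days), dose_Gy = doses),
    label = label,
    n = length(doses),
    total_dose = sum(doses),
    bed = bed(doses, ab),
    ab = ab
  ), class = "radfrac_schedule")
}

#' @export
print.radfrac_schedule <- function(x, ...) {
  cat(sprintf("fractionation schedule '%s': %d fractions, %.4g Gy total, BED %.4g Gy (a/b = %g)\n",
              x$label, x$n, x$total_dose, x$bed, x$ab))
  cat(sprintf("  days %d..%d, doses %s Gy\n",
              min(x$fractions$day), max(x$fractions$day),
              if (length(unique(x$fractions$dose_Gy)) == 1)
                format(x$fractions$dose_Gy[1])
              else paste0(format(min(x$fractions$dose_Gy)), "..",
                          format(max(x$fractions$dose_Gy)))))
  invisible(x)
}

#' Constant-dose schedule at a target BED
#'
#' Builds a constant dose-per-fraction calendar whose fraction count `N`
#' minimizes the distance of the realized BED from `target_bed` (ties go to
#' the smaller count). With the defaults this reproduces the canonical
#' 1.8 Gy x 28-fraction standard course (BED 59.47 Gy).
#'
#' @param d Dose per fraction, Gy. Strict mode requires `0.5 <= d <= 3`, the
#'   range over which the model's radiobiological parameters are considered
#'   trustworthy; `relaxed = TRUE` accepts any positive dose with a warning.
#' @param target_bed Target biologically effective dose, Gy.
#' @param ab Alpha/beta ratio used for the BED accounting, Gy.
#' @param per_week Fractions per calendar week (default 5, Mon-Fri).
#' @param relaxed Accept out-of-range doses with a warning.
#' @return A `radfrac_schedule`.
#' @examples
#' constant_schedule(1.8)  # 28 fractions
#' constant_schedule(3)    # 15 fractions
#' @export
constant_schedule <- function(d, target_bed = 60, ab = 10, per_week = 5,
                              relaxed = FALSE) {
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0)
    stop("dose per fraction must be a positive number", call. = FALSE)
  if (d < 0.5 || d > 3) {
    msg <- sprintf("dose %g Gy outside the constant-dose range [0.5, 3] Gy", d)
    if (relaxed) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  per_fraction <- bed(d, ab)
  n_lo <- max(1L, as.integer(floor(target_bed / per_fraction)))
  cand <- c(n_lo, n_lo + 1L)
  err <- abs(cand * per_fraction - target_bed)
  n <- cand[which.min(err)]  # which.min takes the first, i.e. fewer fractions
  new_schedule(fraction_days(n, per_week), rep(d, n),
               label = sprintf("const %g Gy x %d", d, n), ab = ab)
}

#' Ramped (increasing or decreasing dose) schedule
#'
#' Builds a non-constant schedule whose doses walk a regular grid from
#' `d_min` to `d_max` in steps of `delta` (17 fractions, mean 2.5 Gy, for the
#' defaults). The decreasing direction delivers the same multiset of doses in
#' reverse order, hence at identical BED: any difference in outcome between
#' the two directions isolates the effect of dose ordering.
#'
#' @param d_min,d_max Smallest and largest dose per fraction, Gy.
#' @param delta Dose increment between consecutive fractions, Gy.
#' @param direction `"increasing"` or `"decreasing"`.
#' @param per_week Fractions per calendar week.
#' @return A `radfrac_schedule`.
#' @examples
#' ramp_schedule()                          # 0.5, 0.75, ..., 4.5 Gy
#' ramp_schedule(direction = "decreasing")  # same doses, reversed
#' @export
ramp_schedule <- function(d_min = 0.5, d_max = 4.5, delta = 0.25,
                          direction = c("increasing", "decreasing"),
                          per_week = 5) {
  direction <- match.arg(direction)
  if (d_min <= 0 || d_max <= d_min || delta <= 0)
    stop("need 0 < d_min < d_max and delta > 0", call. = FALSE)
  steps <- (d_max - d_min) / delta
  if (abs(steps - round(steps)) > 1e-8)
    stop("(d_max - d_min) must be an integer multiple of delta", call. = FALSE)
  doses <- seq(d_min, d_max, by = delta)
  if (direction == "decreasing") doses <- rev(doses)
  new_schedule(fraction_days(length(doses), per_week), doses,
               label = sprintf("ramp %s %g..%g Gy (step %g)",
                               direction, d_min, d_max, delta))
}

#' Schedule from an explicit (day, dose) table
#'
#' @param days Integer fraction days (day 0 = first irradiation, a Monday).
#' @param doses Fraction doses, Gy.
#' @param label Schedule label.
#' @param ab Alpha/beta ratio for the BED accounting, Gy.
#' @return A `radfrac_schedule`.
#' @export
schedule_from_fractions <- function(days, doses, label = "custom", ab = 10) {
  new_schedule(days, doses, label, ab)
}

#' Read / write a schedule as a two-column CSV
#'
#' The on-disk format is `day,dose_Gy`, one row per fraction.
#'
#' @param schedule A `radfrac_schedule`.
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `radfrac_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "radfrac_schedule"))
  utils::write.csv(schedule$fractions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @param label Label for the schedule read back.
#' @param ab Alpha/beta ratio for the BED accounting, Gy.
#' @export
read_schedule <- function(path, label = basename(path), ab = 10) {
  df <- utils::read.csv(path)
  if (!all(c("day", "dose_Gy") %in% names(df)))
    stop("schedule file must have columns day,dose_Gy: ", path, call. = FALSE)
  new_schedule(df$day, df$dose_Gy, label, ab)
}
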