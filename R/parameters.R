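#' Fixed radiobiological constants
#'
#' Bundles the quantities of the model that are not fitted per patient: the
#' radiosensitivity range spanned by the oxygenation map, the alpha/beta
#' ratios of the linear-quadratic survival model for tumor and vasculature,
#' and the tumor kill coefficient (fixed at 1; only the vasculature gets a
#' per-patient coefficient below 1).
#'
#' @param alpha_min Radiosensitivity floor at zero oxygenation, in 1/Gy.
#' @param alpha_max Radiosensitivity ceiling at full oxygenation, in 1/Gy.
#'   The defaults bound the per-fraction tumor surviving fraction in (0.5, 1)
#'   for a standard 1.8 Gy fraction at alpha/beta = 10 Gy.
#' @param ab_tumor Alpha/beta ratio of the tumor, in Gy.
#' @param ab_vasc Alpha/beta ratio of the vasculature, in Gy.
#'
#' @return An object of class `radfrac_constants`: a named list with fields
#'   `alpha_min`, `alpha_max`, `ab_tumor`, `ab_vasc`, `gamma_tumor`.
#' @examples
#' model_constants()
#' @export
model_constants <- function(alpha_min = 0.001, alpha_max = 0.3,
                            ab_tumor = 10, ab_vasc = 3) {
  if (!is.numeric(alpha_min) || !is.numeric(alpha_max) ||
      alpha_min <= 0 || alpha_max <= alpha_min)
    stop("invalid radiosensitivity range: need 0 < alpha_min < alpha_max",
         call. = FALSE)
  if (ab_tumor <= 0 || ab_vasc <= 0)
    stop("alpha/beta ratios must be positive", call. = FALSE)
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max,
                 ab_tumor = ab_tumor, ab_vasc = ab_vasc, gamma_tumor = 1),
            class = "radfrac_constants")
}

#' Training bounds of the free patient parameters
#'
#' The four free parameters of the model are searched (and, in strict mode,
#' validated) within these boxes: growth rate `rho` in per day, necrotic
#' clearance half-time `t_half` in days, initial carrying capacity `k_hat`
#' as percent of the initial tumor volume, and vasculature kill coefficient
#' `gamma_v` (dimensionless).
#'
#' @param rho,t_half,k_hat,gamma_v Length-2 numeric `c(lower, upper)` bounds.
#' @return An object of class `radfrac_bounds` (named list of length-2 ranges).
#' @examples
#' parameter_bounds()
#' @export
parameter_bounds <- function(rho = c(0.01, 0.2), t_half = c(2, 30),
                             k_hat = c(100, 300), gamma_v = c(0, 1)) {
  b <- list(rho = rho, t_half = t_half, k_hat = k_hat, gamma_v = gamma_v)
  for (nm in names(b)) {
    v <- b[[nm]]
    if (length(v) != 2 || !is.numeric(v) || v[1] > v[2])
      stop("bound for '", nm, "' must be c(lower, upper) with lower <= upper",
           call. = FALSE)
  }
  structure(b, class = "radfrac_bounds")
}

#' Construct a virtual-patient parameter set
#'
#' A virtual patient is the four-parameter signature of the model fitted to a
#' real patient's tumor-volume regression: Gompertz growth rate, dead-cell
#' clearance half-time, initial carrying capacity, and vasculature kill
#' coefficient.
#'
#' @param id Patient label.
#' @param rho Gompertz growth rate, per day.
#' @param t_half Half-time of necrotic (dead cell) volume clearance, days.
#' @param k_hat Initial carrying capacity, percent of the initial tumor volume
#'   (100 means the tumor starts at capacity).
#' @param gamma_v Vasculature kill coefficient in `[0, 1]`, scaling the
#'   linear-quadratic exponent for vascular damage; lower values mean a more
#'   radioresistant vasculature.
#' @param relaxed If `TRUE`, parameters outside the training bounds
#'   ([parameter_bounds()]) raise a warning instead of an error (any positive
#'   values are then accepted).
#'
#' @return An object of class `radfrac_patient`.
#' @examples
#' patient_parameters("A", rho = 0.17, t_half = 14, k_hat = 220, gamma_v = 0.9)
#' @export
patient_parameters <- function(id, rho, t_half, k_hat, gamma_v,
                               relaxed = FALSE) {
  vals <- c(rho = rho, t_half = t_half, k_hat = k_hat, gamma_v = gamma_v)
  if (any(!is.finite(vals)))
    stop("patient parameters must be finite numbers", call. = FALSE)
  if (rho < 0 || t_half <= 0 || k_hat <= 0 || gamma_v < 0)
    stop("patient parameters must be positive (gamma_v, rho may be 0)",
         call. = FALSE)
  b <- parameter_bounds()
  off <- vapply(names(b), function(nm)
    vals[[nm]] < b[[nm]][1] || vals[[nm]] > b[[nm]][2], logical(1))
  if (any(off)) {
    msg <- paste0("parameter(s) outside training bounds for patient ", id,
                  ": ", paste(names(b)[off], collapse = ", "))
    if (relaxed) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  structure(list(id = as.character(id), rho = rho, t_half = t_half,
                 k_hat = k_hat, gamma_v = gamma_v),
            class = "radfrac_patient")
}

#' @export
print.radfrac_patient <- function(x, ...) {
  cat(sprintf(
    "virtual patient %s: rho = %g /day, T1/2 = %g d, k_hat = %g%%, gamma_v = %g\n",
    x$id, x$rho, x$t_half, x$k_hat, x$gamma_v))
  invisible(x)
}

#' Reference virtual-patient cohort
#'
#' The seven cervical-cancer virtual patients (labels A to G) whose parameter
#' signatures were estimated from clinical tumor-volume regressions under the
#' standard 1.8 Gy x 28-fraction course. They are the study conditions of the
#' in silico fractionation experiments in this package.
#'
#' @return A list of seven [patient_parameters()] objects, named A..G, with
#'   class `radfrac_cohort`.
#' @examples
#' reference_cohort()[["A"]]
#' @export
reference_cohort <- function() {
  tab <- data.frame(
    id      = c("A", "B", "C", "D", "E", "F", "G"),
    rho     = c(0.17, 0.07, 0.08, 0.02, 0.02, 0.10, 0.10),
    t_half  = c(14, 28, 4, 22, 30, 30, 30),
    k_hat   = c(220, 150, 125, 300, 140, 120, 120),
    gamma_v = c(0.9, 0.7, 0.7, 0.9, 0.8, 0.6, 0.7)
  )
  cohort <- lapply(seq_len(nrow(tab)), function(i)
    patient_parameters(tab$id[i], tab$rho[i], tab$t_half[i],
                       tab$k_hat[i], tab$gamma_v[i]))
  names(cohort) <- tab$id
  structure(cohort, class = "radfrac_cohort")
}

#' @export
print.radfrac_cohort <- function(x, ...) {
  cat("virtual patient cohort (", length(x), " patients)\n", sep = "")
  for (p in x) print(p)
  invisible(x)
}

#' Proliferation saturation index
#'
#' Ratio of the (initial) tumor volume to the carrying capacity. A value near
#' 1 means the tumor is close to the maximum the vasculature can sustain, so
#' little proliferation (and, by the oxygenation map of this model, low
#' radiosensitivity) is expected; small values indicate a well-supported,
#' actively proliferating tumor.
#'
#' @param params A [patient_parameters()] object.
#' @param v0 Tumor volume to compare against capacity, percent of initial
#'   (default 100, the start-of-treatment volume).
#' @return A single number, `v0 / k_hat`.
#' @examples
#' psi(patient_parameters("A", 0.17, 14, 220, 0.9)) # 0.4545
#' @export
psi <- function(params, v0 = 100) {
  stopifnot(inherits(params, "radfrac_patient"))
  if (params$k_hat <= 0) stop("carrying capacity must be positive", call. = FALSE)
  v0 / params$k_hat
}
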