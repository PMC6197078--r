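# Independent, naively-coded day-by-day recomputation of the model, kept
# deliberately separate from the package internals: explicit cohort list,
# scalar arithmetic, no shared helpers. Used as the oracle that
# simulate_course() must match to machine precision.
oracle_trajectory <- function(patient, fraction_days, fraction_doses,
                              t_end = max(fraction_days) + 1,
                              alpha_min = 0.001, alpha_max = 0.3,
                              ab_tumor = 10, ab_vasc = 3) {
  v_a <- 100
  k <- patient$k_hat
  cohorts <- list()
  rows <- list()
  for (day in 0:t_end) {
    v_n <- 0
    for (co in cohorts)
      v_n <- v_n + co$v0 * 2^(-(day - co$created) / patient$t_half)
    rows[[day + 1]] <- c(day = day, V_a = v_a, V_n = v_n, k = k)
    if (day == t_end) break
    dose <- 0
    hit <- which(fraction_days == day)
    if (length(hit) == 1) dose <- fraction_doses[hit]
    po2 <- 100 * (k - v_a) / k
    if (po2 < 0) po2 <- 0
    if (po2 > 100) po2 <- 100
    alpha <- alpha_min + po2 / 100 * (alpha_max - alpha_min)
    sf_t <- exp(-alpha * dose * (1 + dose / ab_tumor))
    sf_v <- exp(-alpha * patient$gamma_v * dose * (1 + dose / ab_vasc))
    grown <- v_a * (1 + patient$rho * log(k / v_a))
    if (grown < 0) grown <- 0
    if (dose > 0)
      cohorts[[length(cohorts) + 1]] <- list(created = day,
                                             v0 = v_a * (1 - sf_t))
    v_a <- grown * sf_t
    k <- k * sf_v
  }
  as.data.frame(do.call(rbind, rows))
}

# Hand-coded Pearson correlation, independent of stats::cor.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Bare state constructor for unit-testing necrotic bookkeeping.
make_state <- function(t, v_a, k, t_i = integer(0), v0 = numeric(0)) {
  structure(list(t = as.integer(t), v_a = v_a, k = k,
                 cohorts = data.frame(t_i = t_i, v0 = v0)),
            class = "radfrac_state")
}
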