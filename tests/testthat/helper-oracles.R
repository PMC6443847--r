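# Independent oracles and fixture builders, written deliberately in plain
# base R (loops, no package internals) so they cannot share a bug with the
# implementation they check.

# Invert the delta -> atom% conversion by bisection on delta.
oracle_delta_by_bisection <- function(atom_percent, standard, lo = -999.9,
                                      hi = 1e6, tol = 1e-12) {
  f <- function(d) delta_to_atom_percent(d, standard) - atom_percent
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Brute-force recomputation of a plant's budget from raw organ rows.
oracle_budget <- function(organs, q_wps_ref, baseline) {
  n <- nrow(organs)
  q <- numeric(n)
  n_content <- numeric(n)
  for (i in 1:n) {
    n_content[i] <- organs$dry_mass[i] * organs$n_concentration[i]
    q[i] <- (organs$atom_percent_15N[i] - baseline) / 100 * n_content[i]
    if (q[i] < 0) q[i] <- 0
  }
  q_wpm_excess <- 0
  q_wpm_n <- 0
  for (i in 1:n) {
    q_wpm_excess <- q_wpm_excess + q[i]
    q_wpm_n <- q_wpm_n + n_content[i]
  }
  gi <- which(organs$organ == "grain")
  out <- list(q_wpm_excess = q_wpm_excess, q_wpm_n = q_wpm_n,
              q_grain_n = n_content[gi], post_uptake = q_wpm_n - q_wps_ref)
  if (organs$label_phase[1] == "vegetative") {
    out$rem_pct <- 100 * q[gi] / q_wpm_excess
    out$q_rem_grain <- q_wps_ref * out$rem_pct / 100
    out$grain_rem_pct <- 100 * out$q_rem_grain / n_content[gi]
  } else if (organs$label_phase[1] == "reproductive") {
    pct <- 100 * q / q_wpm_excess
    names(pct) <- organs$organ
    out$post_pct <- pct
    out$q_post_grain <- (q_wpm_n - q_wps_ref) * pct[[ "grain" ]] / 100
    out$grain_rem_pct <- 100 * (1 - out$q_post_grain / n_content[gi])
  }
  out
}

# Hand-built maturity plant with chosen organ N contents and enrichments.
# Dry masses are set so that n_concentration stays within bounds.
make_plant <- function(n_content, enrichment, label_phase = "vegetative",
                       plant_id = "P1", veg = "Nveg", rep = "NW") {
  organs <- names(n_content)
  tibble::tibble(
    plant_id = plant_id, block = 1, greenhouse = 1,
    veg_treatment = veg, rep_treatment = rep, label_phase = label_phase,
    stage = "maturity", organ = organs,
    dry_mass = unname(n_content) / 0.02,
    n_concentration = 0.02,
    atom_percent_15N = unname(enrichment[organs]))
}

ALL_ORGANS <- c("green_leaves", "senesced_leaves", "stalk", "roots",
                "grain", "repro_nongrain")
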