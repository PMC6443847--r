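# Synthetic dual-phase 15N labelling experiment.
#
# Emulates a nested factorial greenhouse design: two vegetative N levels
# crossed with four post-silking N x water treatments, each maturity plant
# labelled in exactly one phase (vegetative or reproductive) or not at all,
# plus a silking-harvest cohort used to estimate treatment-mean pre-silking
# uptake. Every generated plant carries a mechanistically consistent ground
# truth (true remobilization, post-silking uptake and partitioning), so the
# mass-balance pipeline can be validated by parameter recovery.
#
# The label model is the minimal one consistent with the mass-balance
# assumptions: each uptake phase draws on a single well-mixed fertilizer
# pool, so a fraction phi of that phase's N is fertilizer-derived and the
# phase pool's enrichment is baseline + phi * (label - baseline). Organ-
# specific mixing exists only behind perturb_assumptions().

#' Configuration of the synthetic labelling experiment
#'
#' Defaults encode the study conditions of the emulated experiment: mean
#' pre-silking uptake 2.76 / 1.61 g N per plant (high / low vegetative N),
#' a stalk-heavy silking N partition under high N, per-cell remobilization
#' fractions back-solved from the published remobilized-N and pre-silking
#' uptake means, per-cell post-silking uptake and six-organ partition
#' vectors, label doses of 40 mg 15N (vegetative phase) and 90 mg 15N
#' (reproductive phase) at 10 atom%, and measurement noise typical of IRMS
#' and tissue sampling (additive SD 0.002 atom-points on enrichment,
#' multiplicative 5% CV on N content). Between-plant SDs are reconstructed
#' from published standard errors (SE x sqrt(n)).
#'
#' @param n_plants plants per treatment cell at maturity, by label phase
#'   (named list: vegetative, reproductive, unlabelled).
#' @param n_silking_per_veg silking-harvest plants per vegetative treatment
#'   used for the Q_wps reference.
#' @param q_wps_mean,q_wps_sd mean and SD of pre-silking whole-plant N (g),
#'   named by vegetative treatment.
#' @param silking_partition matrix (veg x silking organ) of silking N
#'   partition fractions; rows sum to 1.
#' @param rem_frac matrix (veg x rep) of true fractions of pre-silking N
#'   remobilized to the grain.
#' @param post_uptake_mean,post_uptake_sd matrices (veg x rep) of
#'   post-silking N uptake (g).
#' @param post_partition array (veg x rep x maturity organ) of post-silking
#'   N partition fractions; each vector sums to 1.
#' @param mobilization_weights relative propensity of each silking organ to
#'   give up N to the grain (stalk most mobilizable).
#' @param senesced_frac matrix (veg x rep): fraction of the leaf pool
#'   senesced by maturity (more under stress).
#' @param label_atom_percent atom% 15N of the tracer salt.
#' @param veg_dose,rep_dose [tracer_dose()] objects for the two phases.
#' @param label_uptake_frac fraction of applied fertilizer N absorbed by the
#'   plant within its labelling phase.
#' @param leach_efficiency efficiency of the silking leach-out; 1 removes
#'   all residual vegetative label (the idealized design assumption), lower
#'   values let residual label enter post-silking uptake.
#' @param n_loss_frac fraction of pre-silking N lost from the plant during
#'   grain fill (0 under the mass-balance assumptions; set via
#'   [perturb_assumptions()]).
#' @param label_mix_bias optional named multipliers (silking organs) on
#'   pre-silking pool enrichment, for non-uniform-labelling bias studies.
#' @param atom_noise_sd additive measurement noise on atom% 15N.
#' @param n_content_cv multiplicative lognormal CV on organ N content.
#' @param dry_mass_cv multiplicative lognormal CV on organ dry mass around
#'   its N-anchored expectation (organ dry masses scale with the plant's N
#'   pools through per-cell reference concentrations, so biomass and N
#'   covary as in real plants while cell means match the configured
#'   biomass and grain-yield statistics).
#' @param biomass_silking_mean,biomass_silking_sd silking biomass (g), by veg.
#' @param silking_mass_fraction dry-mass partition at silking.
#' @param grain_yield_mean,grain_yield_sd grain dry mass (g), veg x rep.
#' @param biomass_maturity_mean,biomass_maturity_sd total maturity biomass
#'   (g), veg x rep.
#' @param veg_mass_fraction dry-mass split of non-grain maturity biomass.
#' @param spikelet_mean,spikelet_sd spikelets per plant at silking, by veg.
#' @param kernel_mean,kernel_sd kernels per plant at maturity, veg x rep.
#' @param iso an [iso_config()].
#' @param noiseless if TRUE, zero every SD and noise term (biological and
#'   measurement), so the pipeline must recover the truth exactly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_plants = list(vegetative = 4, reproductive = 4, unlabelled = 2),
    n_silking_per_veg = 12,
    q_wps_mean = c(Nveg = 2.76, nveg = 1.61),
    q_wps_sd = c(Nveg = 0.30, nveg = 0.19) * sqrt(12),
    silking_partition = rbind(
      Nveg = c(leaves = 0.45, stalk = 0.36, roots = 0.12, reproductive = 0.07),
      nveg = c(leaves = 0.50, stalk = 0.31, roots = 0.12, reproductive = 0.07)),
    rem_frac = rbind(
      Nveg = c(NW = 1.59, nW = 1.67, Nw = 1.63, nw = 1.42) / 2.76,
      nveg = c(NW = 0.91, nW = 0.82, Nw = 0.77, nw = 0.59) / 1.61),
    post_uptake_mean = rbind(
      Nveg = c(NW = 1.35, nW = 0.58, Nw = 0.61, nw = 0.67),
      nveg = c(NW = 1.75, nW = 0.50, Nw = 0.69, nw = 0.58)),
    post_uptake_sd = rbind(
      Nveg = c(NW = 0.23, nW = 0.15, Nw = 0.26, nw = 0.12),
      nveg = c(NW = 0.31, nW = 0.15, Nw = 0.14, nw = 0.07)) * 2,
    post_partition = NULL,
    mobilization_weights = c(leaves = 1, stalk = 1.5, roots = 0.7,
                             reproductive = 0.3),
    senesced_frac = rbind(
      Nveg = c(NW = 0.30, nW = 0.40, Nw = 0.45, nw = 0.50),
      nveg = c(NW = 0.35, nW = 0.55, Nw = 0.50, nw = 0.65)),
    label_atom_percent = 10,
    veg_dose = tracer_dose(n15_mass_mg = 40, atom_percent_label = 10),
    rep_dose = tracer_dose(n15_mass_mg = 90, atom_percent_label = 10),
    label_uptake_frac = 0.7,
    leach_efficiency = 1.0,
    n_loss_frac = 0,
    label_mix_bias = NULL,
    atom_noise_sd = 0.002,
    n_content_cv = 0.05,
    dry_mass_cv = 0.08,
    biomass_silking_mean = c(Nveg = 176.8, nveg = 156.4),
    biomass_silking_sd = c(Nveg = 12.1, nveg = 8.4) * sqrt(12),
    silking_mass_fraction = c(leaves = 0.25, stalk = 0.50, roots = 0.18,
                              reproductive = 0.07),
    grain_yield_mean = rbind(
      Nveg = c(NW = 133.0, nW = 139.2, Nw = 107.5, nw = 91.3),
      nveg = c(NW = 129.7, nW = 107.4, Nw = 78.1, nw = 66.6)),
    grain_yield_sd = rbind(
      Nveg = c(NW = 8.9, nW = 5.5, Nw = 6.3, nw = 6.4),
      nveg = c(NW = 12.9, nW = 8.9, Nw = 9.2, nw = 4.9)) * sqrt(10),
    biomass_maturity_mean = rbind(
      Nveg = c(NW = 277.2, nW = 281.8, Nw = 229.5, nw = 222.8),
      nveg = c(NW = 291.6, nW = 224.6, Nw = 213.1, nw = 169.9)),
    biomass_maturity_sd = rbind(
      Nveg = c(NW = 15.7, nW = 12.3, Nw = 15.3, nw = 9.9),
      nveg = c(NW = 14.2, nW = 18.8, Nw = 12.4, nw = 11.7)) * sqrt(10),
    veg_mass_fraction = c(stalk = 0.47, roots = 0.27, leaves = 0.18,
                          repro_nongrain = 0.08),
    spikelet_mean = c(Nveg = 805, nveg = 656),
    spikelet_sd = c(Nveg = 25, nveg = 21) * sqrt(12),
    kernel_mean = rbind(
      Nveg = c(NW = 575, nW = 615, Nw = 548, nw = 500),
      nveg = c(NW = 532, nW = 512, Nw = 401, nw = 371)),
    kernel_sd = rbind(
      Nveg = c(NW = 30, nW = 17, Nw = 18, nw = 43),
      nveg = c(NW = 54, nW = 49, Nw = 51, nw = 30)) * sqrt(10),
    iso = iso_config(),
    noiseless = FALSE) {

  if (is.null(post_partition)) {
    raw <- array(NA_real_, dim = c(2, 4, 6),
                 dimnames = list(c("Nveg", "nveg"),
                                 c("NW", "nW", "Nw", "nw"),
                                 c("grain", "repro_nongrain", "stalk",
                                   "roots", "green_leaves", "senesced_leaves")))
    raw["Nveg", "NW", ] <- c(64.6, 1.7, 20.3, 11.5, 0.3, 2.1)
    raw["Nveg", "nW", ] <- c(69.0, 1.8, 19.1, 7.1, 1.5, 1.5)
    raw["Nveg", "Nw", ] <- c(25.6, 1.7, 35.7, 33.9, 1.9, 1.2)
    raw["Nveg", "nw", ] <- c(17.0, 2.4, 20.3, 58.9, 0.7, 0.7)
    raw["nveg", "NW", ] <- c(32.7, 14.3, 30.9, 14.7, 5.1, 2.2)
    raw["nveg", "nW", ] <- c(86.4, 3.0, 4.6, 4.0, 0.6, 1.5)
    raw["nveg", "Nw", ] <- c(30.4, 9.3, 19.8, 37.3, 2.5, 0.6)
    raw["nveg", "nw", ] <- c(72.4, 2.6, 5.6, 16.1, 2.7, 0.9)
    post_partition <- raw / rep(apply(raw, c(1, 2), sum), times = 6)
  }

  cfg <- list(
    veg_levels = rownames(rem_frac), rep_levels = colnames(rem_frac),
    n_plants = n_plants, n_silking_per_veg = n_silking_per_veg,
    q_wps_mean = q_wps_mean, q_wps_sd = q_wps_sd,
    silking_partition = silking_partition, rem_frac = rem_frac,
    post_uptake_mean = post_uptake_mean, post_uptake_sd = post_uptake_sd,
    post_partition = post_partition,
    mobilization_weights = mobilization_weights,
    senesced_frac = senesced_frac,
    label_atom_percent = label_atom_percent,
    veg_dose = veg_dose, rep_dose = rep_dose,
    label_uptake_frac = label_uptake_frac,
    leach_efficiency = leach_efficiency,
    n_loss_frac = n_loss_frac, label_mix_bias = label_mix_bias,
    atom_noise_sd = atom_noise_sd, n_content_cv = n_content_cv,
    dry_mass_cv = dry_mass_cv,
    biomass_silking_mean = biomass_silking_mean,
    biomass_silking_sd = biomass_silking_sd,
    silking_mass_fraction = silking_mass_fraction,
    grain_yield_mean = grain_yield_mean, grain_yield_sd = grain_yield_sd,
    biomass_maturity_mean = biomass_maturity_mean,
    biomass_maturity_sd = biomass_maturity_sd,
    veg_mass_fraction = veg_mass_fraction,
    spikelet_mean = spikelet_mean, spikelet_sd = spikelet_sd,
    kernel_mean = kernel_mean, kernel_sd = kernel_sd,
    iso = iso)

  if (noiseless) {
    for (nm in c("q_wps_sd", "post_uptake_sd", "biomass_silking_sd",
                 "grain_yield_sd", "biomass_maturity_sd", "spikelet_sd",
                 "kernel_sd"))
      cfg[[nm]] <- cfg[[nm]] * 0
    cfg$atom_noise_sd <- 0
    cfg$n_content_cv <- 0
    cfg$dry_mass_cv <- 0
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks partition vectors sum to 1, fractions lie in [0, 1], SDs are
#' non-negative, and (crucially) that the remobilization demand is feasible:
#' with mobilization weights `w` and silking partition `p`, the fraction of
#' organ `x` withdrawn is `rem * w_x / sum(w * p)`, which must not exceed 1
#' for any organ in any treatment cell.
#'
#' @param cfg a `sim_config` list.
#' @return `cfg`, invisibly on success; errors otherwise.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk01 <- function(x, nm) {
    if (any(x < 0 | x > 1))
      stop(nm, " must lie in [0, 1]", call. = FALSE)
  }
  chk01(cfg$rem_frac, "rem_frac")
  chk01(cfg$senesced_frac, "senesced_frac")
  chk01(cfg$label_uptake_frac, "label_uptake_frac")
  chk01(cfg$leach_efficiency, "leach_efficiency")
  chk01(cfg$n_loss_frac, "n_loss_frac")
  if (any(abs(rowSums(cfg$silking_partition) - 1) > 1e-8))
    stop("silking_partition rows must sum to 1", call. = FALSE)
  ps <- apply(cfg$post_partition, c(1, 2), sum)
  if (any(abs(ps - 1) > 1e-8))
    stop("post_partition vectors must sum to 1", call. = FALSE)
  for (nm in c("q_wps_sd", "post_uptake_sd", "atom_noise_sd", "n_content_cv",
               "dry_mass_cv", "biomass_silking_sd", "grain_yield_sd",
               "biomass_maturity_sd", "spikelet_sd", "kernel_sd"))
    if (any(cfg[[nm]] < 0)) stop(nm, " must be >= 0", call. = FALSE)
  # remobilization feasibility (organ cannot give up more N than it holds)
  for (v in cfg$veg_levels) {
    p <- cfg$silking_partition[v, ]
    w <- cfg$mobilization_weights[names(p)]
    denom <- sum(w * p)
    for (r in cfg$rep_levels) {
      frac_out <- cfg$rem_frac[v, r] * w / denom
      if (any(frac_out > 1))
        stop("infeasible config: remobilization in cell ", v, " x ", r,
             " would withdraw more N than organ '",
             names(which.max(frac_out)), "' holds", call. = FALSE)
    }
  }
  invisible(cfg)
}

# positive-truncated normal draw (rejection); lower bound as a floor keeps
# pathological tails from producing zero or negative pools
.rnorm_pos <- function(n, mean, sd, lower = NULL) {
  if (is.null(lower)) lower <- pmax(0.02 * mean, 1e-6)
  if (all(sd == 0)) return(rep_len(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
    tries <- tries + 1
  }
  x[x <= lower] <- lower
  x
}

# multiplicative lognormal measurement noise, mean 1
.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Leach-out of residual labelled fertilizer at silking
#'
#' Applies the silking irrigation flush to the growing-medium pool state:
#' the residual unabsorbed labelled fertilizer is reduced to
#' `(1 - efficiency)` of its amount. At the default efficiency of 0.99 the
#' flush removes 99% of residual fertilizer N, preventing (almost all)
#' vegetative-phase label from entering post-silking uptake — the basis for
#' using no residual-uptake correction factor in the mass balance.
#'
#' @param state list with element `residual_label_n` (residual labelled
#'   fertilizer N in the medium; any mass unit).
#' @param efficiency fraction of the residual removed, in [0, 1].
#' @return The state with `residual_label_n` reduced.
#' @examples
#' leach_event(list(residual_label_n = 100), efficiency = 0.99)
#' @export
leach_event <- function(state, efficiency = 0.99) {
  if (!is.list(state) || is.null(state$residual_label_n))
    stop("state must be a list with element residual_label_n", call. = FALSE)
  if (efficiency < 0 || efficiency > 1)
    stop("efficiency must lie in [0, 1]", call. = FALSE)
  state$residual_label_n <- (1 - efficiency) * state$residual_label_n
  state
}

#' Relax one mass-balance assumption in a simulation config
#'
#' Returns a config that deliberately violates one of the stated assumptions
#' of the tracer mass balance, for bias studies:
#' \describe{
#'   \item{n_loss}{a fraction `amount` of pre-silking N is lost from the
#'     plant during grain fill (e.g. volatilization); estimated post-silking
#'     uptake is then biased low by about the lost mass.}
#'   \item{nonuniform_label}{pre-silking pool enrichment differs between
#'     organs: leaves and stalk (the remobilization sources) are
#'     over-enriched by factor `1 + amount`, roots under-enriched by
#'     `1 - amount`, so the remobilized fraction is over-estimated.}
#' }
#'
#' @param config a [sim_config()].
#' @param which "n_loss" or "nonuniform_label".
#' @param amount perturbation size (fraction); 0 returns the config
#'   unchanged in effect.
#' @return A modified, revalidated `sim_config`.
#' @export
perturb_assumptions <- function(config, which = c("n_loss", "nonuniform_label"),
                                amount = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  which <- match.arg(which)
  if (amount < 0 || amount > 1)
    stop("amount must lie in [0, 1]", call. = FALSE)
  if (which == "n_loss") {
    config$n_loss_frac <- amount
  } else {
    config$label_mix_bias <- c(leaves = 1 + amount, stalk = 1 + amount,
                               roots = 1 - amount, reproductive = 1)
  }
  validate_sim_config(config)
  config
}

# Internal: deterministic mass mechanics of one maturity plant — silking
# pools, remobilization withdrawals, optional loss, post-silking allocation.
# Shared between plant simulation and the per-cell expected values that
# anchor organ dry masses.
.n_mech <- function(q_wps, u, veg, rep, cfg) {
  pools <- cfg$silking_partition[veg, ] * q_wps
  rem <- cfg$rem_frac[veg, rep]
  r_total <- rem * q_wps
  w <- cfg$mobilization_weights[names(pools)]
  withdrawal <- r_total * w * pools / sum(w * pools)
  if (any(withdrawal > pools + 1e-12))
    stop("infeasible remobilization in cell ", veg, " x ", rep, call. = FALSE)
  pools_left <- pools - withdrawal

  loss <- cfg$n_loss_frac * q_wps
  if (loss > 0) {
    frac_left <- loss / sum(pools_left)
    if (frac_left >= 1)
      stop("n_loss_frac removes more N than vegetative organs hold",
           call. = FALSE)
    pools_left <- pools_left * (1 - frac_left)
  }

  part <- cfg$post_partition[veg, rep, ]
  post_n <- part * u
  s <- cfg$senesced_frac[veg, rep]
  pre_n <- c(green_leaves = unname(pools_left["leaves"]) * (1 - s),
             senesced_leaves = unname(pools_left["leaves"]) * s,
             stalk = unname(pools_left["stalk"]),
             roots = unname(pools_left["roots"]),
             grain = r_total,
             repro_nongrain = unname(pools_left["reproductive"]))
  list(pools = pools, withdrawal = withdrawal, pools_left = pools_left,
       r_total = r_total, rem = rem, loss = loss, part = part, s = s,
       pre_n = pre_n[MATURITY_ORGANS],
       post_n = post_n[MATURITY_ORGANS],
       n_true = pre_n[MATURITY_ORGANS] + post_n[MATURITY_ORGANS])
}

# Internal: per-cell reference N concentrations (g N per g dry mass) that
# anchor organ dry masses to the plant's N pools. Organ dry mass is the
# plant's organ N divided by its cell's reference concentration (times
# sampling noise), so bigger N pools mean bigger organs — the within-cell
# biomass-N correlation of real plants — while cell-mean biomass and grain
# yield reproduce the configured phenotype means.
.conc_ref <- function(veg, rep, cfg) {
  mech <- .n_mech(cfg$q_wps_mean[[veg]], cfg$post_uptake_mean[veg, rep],
                  veg, rep, cfg)
  gy_mean <- cfg$grain_yield_mean[veg, rep]
  vm_mean <- cfg$biomass_maturity_mean[veg, rep] - gy_mean
  mf <- cfg$veg_mass_fraction
  s <- mech$s
  mass_mean <- c(green_leaves = unname(mf["leaves"]) * vm_mean * (1 - s),
                 senesced_leaves = unname(mf["leaves"]) * vm_mean * s,
                 stalk = unname(mf["stalk"]) * vm_mean,
                 roots = unname(mf["roots"]) * vm_mean,
                 grain = gy_mean,
                 repro_nongrain = unname(mf["repro_nongrain"]) * vm_mean)
  mech$n_true / mass_mean[MATURITY_ORGANS]
}

# Internal: simulate one maturity plant. Returns list(organs, truth, pheno).
.sim_maturity_plant <- function(pid, block, gh, veg, rep, phase, cfg) {
  iso <- cfg$iso
  a0 <- iso$baseline_atom_percent
  lab <- cfg$label_atom_percent

  q_wps <- .rnorm_pos(1, cfg$q_wps_mean[[veg]], cfg$q_wps_sd[[veg]])
  u <- .rnorm_pos(1, cfg$post_uptake_mean[veg, rep],
                  cfg$post_uptake_sd[veg, rep])
  mech <- .n_mech(q_wps, u, veg, rep, cfg)

  # pre-silking pool enrichment (single well-mixed fertilizer pool)
  applied_veg <- cfg$veg_dose$n_mass_mg / 1000   # g N
  if (phase == "vegetative") {
    absorbed_veg <- min(cfg$label_uptake_frac * applied_veg, q_wps)
    phi_veg <- absorbed_veg / q_wps
  } else {
    absorbed_veg <- 0
    phi_veg <- 0
  }
  silk_organs <- colnames(cfg$silking_partition)
  bias <- if (is.null(cfg$label_mix_bias)) {
    stats::setNames(rep(1, length(silk_organs)), silk_organs)
  } else cfg$label_mix_bias[silk_organs]
  e_pre <- pmin(a0 + bias * phi_veg * (lab - a0), lab)   # atom% per organ
  c_pre <- (e_pre - a0) / 100                            # g excess per g N
  grain_pre_excess <- sum(mech$withdrawal * c_pre[names(mech$withdrawal)])

  # post-silking fertilizer fraction (or leach-survived carryover)
  applied_rep <- cfg$rep_dose$n_mass_mg / 1000
  if (phase == "reproductive") {
    phi_post <- min(cfg$label_uptake_frac * applied_rep, u) / u
  } else if (phase == "vegetative") {
    residual <- leach_event(list(residual_label_n = applied_veg - absorbed_veg),
                            efficiency = cfg$leach_efficiency)$residual_label_n
    phi_post <- min(residual, u) / u
  } else {
    phi_post <- 0
  }
  c_post <- phi_post * (lab - a0) / 100

  s <- mech$s
  # pools_left already reflects any configured N loss, so the lost N takes
  # its label with it proportionally
  pools_left <- mech$pools_left
  pre_ex <- c(green_leaves = unname(pools_left["leaves"] * c_pre["leaves"]) * (1 - s),
              senesced_leaves = unname(pools_left["leaves"] * c_pre["leaves"]) * s,
              stalk = unname(pools_left["stalk"] * c_pre["stalk"]),
              roots = unname(pools_left["roots"] * c_pre["roots"]),
              grain = grain_pre_excess,
              repro_nongrain = unname(pools_left["reproductive"] *
                                        c_pre["reproductive"]))
  organs <- MATURITY_ORGANS
  n_true <- mech$n_true
  ex_true <- pre_ex[organs] + mech$post_n[organs] * c_post
  atom_true <- a0 + 100 * ex_true / n_true

  # organ dry masses anchored to N pools via per-cell reference
  # concentrations, with sampling noise on mass
  conc_ref <- .conc_ref(veg, rep, cfg)
  dry <- n_true / conc_ref * .lognoise(length(organs), cfg$dry_mass_cv)
  grain_mass <- unname(dry["grain"])

  # recorded values = truth + measurement noise
  n_meas <- n_true * .lognoise(length(organs), cfg$n_content_cv)
  atom_meas <- if (phase == "unlabelled") {
    a0 + stats::rnorm(length(organs), 0, cfg$atom_noise_sd)
  } else {
    atom_true + stats::rnorm(length(organs), 0, cfg$atom_noise_sd)
  }
  conc <- n_meas / dry
  if (any(conc > 0.1))
    stop("simulated N concentration exceeds 10% of dry mass; check config",
         call. = FALSE)

  organs_tbl <- tibble::tibble(
    plant_id = pid, block = block, greenhouse = gh,
    veg_treatment = veg, rep_treatment = rep, label_phase = phase,
    stage = "maturity", organ = organs,
    dry_mass = unname(dry), n_concentration = unname(conc),
    atom_percent_15N = unname(atom_meas))

  spik <- round(.rnorm_pos(1, cfg$spikelet_mean[[veg]], cfg$spikelet_sd[[veg]]))
  kern <- round(.rnorm_pos(1, cfg$kernel_mean[veg, rep], cfg$kernel_sd[veg, rep]))
  pheno <- tibble::tibble(
    plant_id = pid, block = block, greenhouse = gh,
    veg_treatment = veg, rep_treatment = rep, label_phase = phase,
    spikelet_count = spik, kernel_number = kern, grain_mass = grain_mass)

  truth <- tibble::tibble(
    plant_id = pid, veg_treatment = veg, rep_treatment = rep,
    label_phase = phase,
    q_wps = q_wps, rem_pct = 100 * mech$rem, q_rem_grain = mech$r_total,
    post_uptake = u, q_grain_n = unname(n_true["grain"]),
    grain_rem_pct = 100 * mech$r_total / unname(n_true["grain"]),
    q_wpm_n = sum(n_true), n_loss = mech$loss)
  for (org in organs)
    truth[[paste0("post_pct_", org)]] <- 100 * mech$part[[org]]

  list(organs = organs_tbl, truth = truth, pheno = pheno)
}

# Internal: one silking-harvest plant (unlabelled; used for Q_wps reference)
.sim_silking_plant <- function(pid, block, gh, veg, cfg) {
  a0 <- cfg$iso$baseline_atom_percent
  q_wps <- .rnorm_pos(1, cfg$q_wps_mean[[veg]], cfg$q_wps_sd[[veg]])
  pools <- cfg$silking_partition[veg, ] * q_wps
  # dry mass anchored to the plant's N pools via the cell-mean reference
  # concentration (see .conc_ref); cell-mean biomass matches the config
  conc_ref <- (cfg$silking_partition[veg, ] * cfg$q_wps_mean[[veg]]) /
    (cfg$silking_mass_fraction[names(pools)] *
       cfg$biomass_silking_mean[[veg]])
  dry <- pools / conc_ref * .lognoise(length(pools), cfg$dry_mass_cv)
  n_meas <- pools * .lognoise(length(pools), cfg$n_content_cv)
  atom <- a0 + stats::rnorm(length(pools), 0, cfg$atom_noise_sd)
  tibble::tibble(
    plant_id = pid, block = block, greenhouse = gh,
    veg_treatment = veg, rep_treatment = "none", label_phase = "unlabelled",
    stage = "silking", organ = names(pools),
    dry_mass = unname(dry), n_concentration = unname(n_meas / dry),
    atom_percent_15N = unname(atom))
}

#' Generate a synthetic dual-phase labelling experiment
#'
#' Simulates, deterministically for a given seed, a silking-harvest cohort
#' (per vegetative treatment, for the Q_wps reference) and a maturity cohort
#' in which every treatment cell contains vegetative-labelled,
#' reproductive-labelled and unlabelled plants, together with the per-plant
#' ground truth. Within each plant, whole-plant N at maturity equals
#' pre-silking uptake plus post-silking uptake minus any configured loss,
#' exactly; measurement noise perturbs only the recorded values, never the
#' truth.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed; the same seed reproduces the output
#'   exactly.
#' @return A list with elements `plants` (long organ table, silking +
#'   maturity), `phenotypes` (one row per maturity plant) and `truth`
#'   (one row per maturity plant).
#' @examples
#' sim <- generate_experiment(sim_config(noiseless = TRUE), seed = 1)
#' head(sim$truth)
#' @export
generate_experiment <- function(config = sim_config(), seed = 1) {
  validate_sim_config(config)
  set.seed(seed)
  blocks_lab <- c(1, 2, 4, 5)      # greenhouse 1: blocks 1-3, greenhouse 2: 4-6
  blocks_unl <- c(3, 6)
  gh_of <- function(b) ifelse(b <= 3, 1L, 2L)

  plants <- list(); truths <- list(); phenos <- list()
  k <- 0L
  for (veg in config$veg_levels) {
    for (i in seq_len(config$n_silking_per_veg)) {
      b <- blocks_lab[(i - 1) %% length(blocks_lab) + 1]
      k <- k + 1L
      plants[[k]] <- .sim_silking_plant(sprintf("S_%s_%02d", veg, i),
                                        b, gh_of(b), veg, config)
    }
  }
  j <- 0L
  for (veg in config$veg_levels) {
    for (rep in config$rep_levels) {
      for (phase in c("vegetative", "reproductive", "unlabelled")) {
        n <- config$n_plants[[phase]]
        if (is.null(n) || n == 0) next
        bset <- if (phase == "unlabelled") blocks_unl else blocks_lab
        for (i in seq_len(n)) {
          b <- bset[(i - 1) %% length(bset) + 1]
          j <- j + 1L
          pid <- sprintf("M_%s_%s_%s_%02d", veg, rep, substr(phase, 1, 3), i)
          res <- .sim_maturity_plant(pid, b, gh_of(b), veg, rep, phase, config)
          k <- k + 1L
          plants[[k]] <- res$organs
          truths[[j]] <- res$truth
          phenos[[j]] <- res$pheno
        }
      }
    }
  }
  list(plants = dplyr::bind_rows(plants),
       phenotypes = dplyr::bind_rows(phenos),
       truth = dplyr::bind_rows(truths))
}
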