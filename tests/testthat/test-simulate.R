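test_that("generation is deterministic and mass-consistent", {
  cfg <- sim_config(n_plants = list(vegetative = 2, reproductive = 2,
                                    unlabelled = 1), n_silking_per_veg = 4)
  a <- generate_experiment(cfg, seed = 42)
  b <- generate_experiment(cfg, seed = 42)
  expect_identical(a, b)
  c <- generate_experiment(cfg, seed = 43)
  expect_false(identical(a$plants, c$plants))
  # truth is internally mass-consistent in every plant
  tr <- a$truth
  expect_equal(tr$q_wpm_n, tr$q_wps + tr$post_uptake - tr$n_loss,
               tolerance = 1e-12)
  # grain N = remobilized + post-silking grain N
  post_grain <- tr$post_uptake * tr$post_pct_grain / 100
  expect_equal(tr$q_grain_n, tr$q_rem_grain + post_grain, tolerance = 1e-12)
})

test_that("noiseless measured values equal the generator's truth", {
  sim <- generate_experiment(sim_config(noiseless = TRUE), seed = 9)
  plants <- sim$plants[sim$plants$stage == "maturity", ]
  wpn <- whole_plant_n(plants)
  tr <- sim$truth
  expect_equal(unname(wpn[tr$plant_id]), tr$q_wpm_n, tolerance = 1e-9)
  # enrichment bounds: labelled organs lie between baseline and the label
  lab <- plants[plants$label_phase != "unlabelled", ]
  expect_true(all(lab$atom_percent_15N >= iso_config()$baseline_atom_percent -
                    1e-12))
  expect_true(all(lab$atom_percent_15N <= 10 + 1e-12))
})

test_that("infeasible remobilization demand is a config error", {
  expect_error(
    sim_config(rem_frac = rbind(Nveg = c(NW = 0.95, nW = 0.95, Nw = 0.95,
                                         nw = 0.95),
                                nveg = c(NW = 0.95, nW = 0.95, Nw = 0.95,
                                         nw = 0.95))),
    "infeasible")
  expect_error(sim_config(label_uptake_frac = 1.5), "\\[0, 1\\]")
})

test_that("leach_event removes residual fertilizer from the medium", {
  st <- leach_event(list(residual_label_n = 100), efficiency = 0.99)
  expect_equal(st$residual_label_n, 1)
  expect_equal(leach_event(list(residual_label_n = 5),
                           efficiency = 1)$residual_label_n, 0)
  expect_error(leach_event(list(), 0.5), "residual_label_n")
  expect_error(leach_event(list(residual_label_n = 1), 2), "\\[0, 1\\]")
})

test_that("skipping the leach biases remobilization upward (well-watered, high N)", {
  # with no leach, residual vegetative label rides along with post-silking
  # uptake; where the grain's post-silking share exceeds the remobilized
  # fraction this inflates the grain's share of excess 15N
  cfg <- sim_config(noiseless = TRUE, leach_efficiency = 0,
                    n_plants = list(vegetative = 2, reproductive = 0,
                                    unlabelled = 0))
  sim <- generate_experiment(cfg, seed = 21)
  budgets <- nitrogen_budget(sim$plants)
  j <- merge(budgets, sim$truth, by = "plant_id", suffixes = c("", "_true"))
  nw <- j[j$rep_treatment == "NW" & j$veg_treatment == "Nveg", ]
  expect_true(all(nw$rem_pct > nw$rem_pct_true))
  # full-efficiency leach restores exact recovery
  cfg2 <- sim_config(noiseless = TRUE, leach_efficiency = 1,
                     n_plants = list(vegetative = 2, reproductive = 0,
                                     unlabelled = 0))
  sim2 <- generate_experiment(cfg2, seed = 21)
  b2 <- nitrogen_budget(sim2$plants)
  j2 <- merge(b2, sim2$truth, by = "plant_id", suffixes = c("", "_true"))
  expect_equal(j2$rem_pct, j2$rem_pct_true, tolerance = 1e-9)
})

test_that("perturbing the no-loss assumption biases post-silking uptake low", {
  base <- sim_config(noiseless = TRUE,
                     n_plants = list(vegetative = 1, reproductive = 1,
                                     unlabelled = 0))
  expect_identical(perturb_assumptions(base, "n_loss", 0)$n_loss_frac, 0)
  cfg <- perturb_assumptions(base, "n_loss", 0.05)
  sim <- generate_experiment(cfg, seed = 13)
  budgets <- suppressWarnings(nitrogen_budget(sim$plants))
  j <- merge(budgets, sim$truth, by = "plant_id", suffixes = c("", "_true"))
  # estimated uptake is low by exactly the lost mass under zero noise
  expect_equal(j$post_uptake - j$post_uptake_true, -j$n_loss,
               tolerance = 1e-9)
  expect_error(perturb_assumptions(base, "evaporation"), "arg")
})

test_that("non-uniform labelling of mobilizable organs inflates rem%", {
  base <- sim_config(noiseless = TRUE,
                     n_plants = list(vegetative = 1, reproductive = 0,
                                     unlabelled = 0))
  cfg <- perturb_assumptions(base, "nonuniform_label", 0.3)
  sim <- generate_experiment(cfg, seed = 17)
  budgets <- nitrogen_budget(sim$plants)
  j <- merge(budgets, sim$truth, by = "plant_id", suffixes = c("", "_true"))
  # leaves and stalk (the remobilization sources) are over-enriched, so the
  # grain's excess share overstates the true remobilized fraction
  expect_true(all(j$rem_pct > j$rem_pct_true))
})

test_that("phenotypes carry the design's treatment structure", {
  sim <- generate_experiment(sim_config(), seed = 31)
  ph <- sim$phenotypes
  expect_equal(nrow(ph), 2 * 4 * (4 + 4 + 2))
  expect_true(all(ph$spikelet_count > 0 & ph$kernel_number > 0))
  expect_true(all(ph$grain_mass > 0))
  # high vegetative N produces more spikelets on average (large margin)
  m <- tapply(ph$spikelet_count, ph$veg_treatment, mean)
  expect_gt(m[["Nveg"]], m[["nveg"]])
})
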