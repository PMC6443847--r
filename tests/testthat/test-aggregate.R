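test_that("treatment summary reports mean and sample SE per cell", {
  df <- data.frame(veg_treatment = "Nveg", rep_treatment = "NW",
                   y = c(2, 2, 2))
  s <- treatment_summary(df, "y")
  expect_equal(s$mean, 2)
  expect_equal(s$se, 0)                       # constant vector: SE exactly 0
  df2 <- data.frame(veg_treatment = "Nveg", rep_treatment = "NW",
                    y = c(1, 2, 3))
  s2 <- treatment_summary(df2, "y")
  expect_equal(s2$se, 0.57735, tolerance = 1e-5)   # sd/sqrt(3), frozen
  one <- data.frame(veg_treatment = "nveg", rep_treatment = "nw", y = 5)
  s3 <- treatment_summary(one, "y")
  expect_equal(s3$mean, 5)
  expect_true(is.na(s3$se))                   # n = 1 reported as missing
})

test_that("treatment summary orders cells canonically and drops empties", {
  df <- expand.grid(veg_treatment = c("nveg", "Nveg"),
                    rep_treatment = c("nw", "Nw", "nW", "NW"),
                    stringsAsFactors = FALSE)
  df <- df[rep(seq_len(nrow(df)), each = 3), ]
  df$y <- seq_len(nrow(df))
  s <- treatment_summary(df, "y")
  expect_equal(unique(s$rep_treatment), c("NW", "nW", "Nw", "nw"))
  expect_equal(s$veg_treatment[1:2], c("Nveg", "nveg"))
  df$y[df$rep_treatment == "nw"] <- NA
  expect_warning(s2 <- treatment_summary(df, "y"), "omitted")
  expect_false("nw" %in% s2$rep_treatment)
})

test_that("stress_average is the unweighted mean of named cell means", {
  cells <- c(NW = 45.4, nW = 64.0, Nw = 72.1, nw = 61.2)
  expect_equal(stress_average(cells, "Nw"), 72.1)     # single cell: identity
  expect_equal(round(stress_average(cells, c("nW", "Nw", "nw")), 1), 65.8)
  df <- data.frame(rep_treatment = names(cells), mean = unname(cells))
  expect_equal(stress_average(df, c("nW", "Nw", "nw")),
               stress_average(cells, c("nW", "Nw", "nw")))
  expect_error(stress_average(cells, "XX"), "unknown cell")
})

test_that("report rounding is half-away-from-zero and report-only", {
  expect_equal(n15budget:::round_half_away(c(0.5, 1.5, -0.5, 2.25), 0),
               c(1, 2, -1, 2))
  expect_equal(n15budget:::round_half_away(0.125, 2), 0.13)
})

test_that("render_tables writes the fixed table set, byte-identically", {
  sim <- generate_experiment(sim_config(), seed = 77)
  budgets <- suppressWarnings(nitrogen_budget(sim$plants))
  d1 <- file.path(tempdir(), "rep1")
  d2 <- file.path(tempdir(), "rep2")
  silk <- sim$plants[sim$plants$stage == "silking", ]
  p1 <- render_tables(budgets, sim$phenotypes, silking = silk, out_dir = d1)
  p2 <- render_tables(budgets, sim$phenotypes, silking = silk, out_dir = d2)
  expect_equal(basename(p1),
               c("table_silking_parameters.csv", "table_grain_n_sources.csv",
                 "table_postsilking_partitioning.csv",
                 "table_yield_components.csv"))
  for (i in seq_along(p1))
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  g <- utils::read.csv(p1[2])
  expect_true(all(c("veg_treatment", "rep_treatment", "grain_rem_pct_mean",
                    "grain_rem_pct_se", "q_rem_grain_mean") %in% names(g)))
  expect_equal(nrow(g), 8)
  expect_error(render_tables(budgets[0, ], sim$phenotypes, out_dir = d1),
               "empty")
})

test_that("plant CSV round-trips and accepts delta-notation enrichment", {
  cfg <- iso_config()
  sim <- generate_experiment(sim_config(n_plants = list(vegetative = 1,
                                                        reproductive = 1,
                                                        unlabelled = 1),
                                        n_silking_per_veg = 2), seed = 19)
  path <- tempfile(fileext = ".csv")
  write_plants_csv(sim$plants, path)
  back <- read_plants_csv(path, cfg)
  expect_equal(back$atom_percent_15N, sim$plants$atom_percent_15N,
               tolerance = 1e-12)
  # delta-notation input converts through the configured standard
  d <- sim$plants
  d$delta15N_permil <- atom_percent_to_delta(d$atom_percent_15N,
                                             cfg$standard_atom_percent)
  d$atom_percent_15N <- NULL
  write.csv(d, path, row.names = FALSE)
  back2 <- read_plants_csv(path, cfg)
  expect_equal(back2$atom_percent_15N, sim$plants$atom_percent_15N,
               tolerance = 1e-9)
  # a row carrying both encodings is rejected
  d2 <- d
  d2$atom_percent_15N <- 0.4
  write.csv(d2, path, row.names = FALSE)
  expect_error(read_plants_csv(path, cfg), "exactly one")
})

test_that("YAML isotope config reads both reference constants", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("isotope:", "  standard_atom_percent: 0.3663",
               "  baseline_atom_percent: 0.3700"), path)
  cfg <- read_iso_config(path)
  expect_equal(cfg$standard_atom_percent, 0.3663)
  expect_equal(cfg$baseline_atom_percent, 0.37)
  writeLines("isotope: {}", path)
  cfg2 <- read_iso_config(path)
  expect_equal(cfg2$baseline_atom_percent, 0.3733)
})
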