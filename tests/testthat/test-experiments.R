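tiny_config <- function(...) {
  experiment_config(
    archetypes = "prospective",
    cohort = cohort_spec(per_cell = 1, master_seed = 5,
                         shape = small_shape),
    localiser_angles = character(0),
    directions = character(0),
    vertical_offsets_mm = numeric(0),
    lateral_offsets_mm = numeric(0),
    pairings = "single",
    n_photons = 1e4,
    master_seed = 5,
    ...)
}

test_that("the setup grid always contains the reference setup first", {
  st <- setup_table(experiment_config())
  expect_equal(st$setup[1], "reference")
  expect_equal(st$direction[1], "caudocranial")
  expect_equal(st$dx[1] + st$dy[1], 0)
  expect_true(all(table(st$setup) == 1))
  # offsets are applied identically to localiser and scan by construction:
  # one offset column pair drives both
  expect_true(all(c("dx", "dy", "localiser", "direction") %in% names(st)))
})

test_that("run_reference applies the BMI-to-kVp protocol rule", {
  cfg <- tiny_config()
  models <- list(
    u = generate_phantom("male", "underweight", 1, shape = small_shape),
    n = generate_phantom("male", "normal", 2, shape = small_shape),
    o = generate_phantom("female", "overweight", 3, shape = small_shape),
    b = generate_phantom("female", "obese", 4, shape = small_shape))
  ref <- run_reference(cfg, "prospective", models = models)
  od <- ref$organ_doses
  kvp <- tapply(od$kvp, od$model, unique)
  expect_equal(as.numeric(kvp[c("u", "n", "o", "b")]),
               c(100, 120, 120, 140))
  expect_true(all(od$dose_mgy >= 0))
  # breasts present only for the female models
  expect_setequal(unique(od$model[od$organ == "breasts"]), c("o", "b"))
})

test_that("run_reference is deterministic under the master seed", {
  cfg <- tiny_config()
  models <- list(m1 = generate_phantom("male", "normal", 2,
                                       shape = small_shape))
  r1 <- run_reference(cfg, "prospective", models = models)
  r2 <- run_reference(cfg, "prospective", models = models)
  expect_identical(r1$organ_doses, r2$organ_doses)
})

test_that("the reference self-comparison is exactly zero", {
  od <- data.frame(dose = c(1.2, 0.4))
  expect_equal(relative_difference(od$dose, od$dose), c(0, 0))
})

test_that("grid runs are deterministic down to the written bytes", {
  cfg <- experiment_config(
    archetypes = "prospective",
    cohort = cohort_spec(per_cell = 1, master_seed = 5,
                         shape = small_shape),
    localiser_angles = character(0),
    directions = "craniocaudal",
    vertical_offsets_mm = -40,
    lateral_offsets_mm = numeric(0),
    pairings = "single",
    n_photons = 1e4,
    master_seed = 31)
  d1 <- file.path(tempdir(), "grid_a")
  d2 <- file.path(tempdir(), "grid_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_result_bundle(run_grid(cfg), d1)
  write_result_bundle(run_grid(cfg), d2)
  for (f in c("organ_doses.csv", "relative_differences.csv",
              "summary.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # the bundle carries stats for the direction family
  b <- run_grid(cfg)
  expect_true(any(b$stats$test == "paired_t"))
})

test_that("summaries aggregate with exact mean and SD", {
  rd <- data.frame(model = c("a", "b"), archetype = "x", setup = "s",
                   family = "f", pairing = "single", organ = "lungs",
                   dose_mgy = c(1, 1), dose_ref = c(1, 1),
                   rel_diff_pct = c(40, -40))
  bundle <- structure(list(rel_diff = rd), class = "result_bundle")
  sm <- summarize_grid(bundle)
  expect_equal(sm$mean_rel_diff_pct, 0)
  expect_equal(sm$sd_rel_diff_pct, 56.5685, tolerance = 1e-4)
  # two-pass variance oracle
  v <- sum((rd$rel_diff_pct - mean(rd$rel_diff_pct))^2) /
    (nrow(rd) - 1)
  expect_equal(sm$sd_rel_diff_pct, sqrt(v), tolerance = 1e-12)
})

test_that("YAML configurations map onto experiment_config", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "archetypes: [prospective, online]",
    "vertical_offsets_mm: [-40, 40]",
    "lateral_offsets_mm: []",
    "n_photons: 50000",
    "master_seed: 12",
    "cohort:",
    "  per_cell: 2",
    "  master_seed: 9"), f)
  cfg <- experiment_config_from_yaml(f)
  expect_equal(cfg$archetypes, c("prospective", "online"))
  expect_equal(cfg$vertical_offsets_mm, c(-40, 40))
  expect_equal(cfg$n_photons, 50000)
  expect_equal(cfg$cohort$per_cell, 2)
  writeLines("phantom_count: 3", f)
  expect_error(experiment_config_from_yaml(f), "unknown configuration")
})
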