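test_that("material table satisfies its physical invariants", {
  mt <- material_table()
  expect_true(all(diff(mt$energy_kev) > 0))
  expect_lte(min(mt$energy_kev), 10)
  expect_gte(max(mt$energy_kev), 150)
  expect_true(all(mt$mu_pe > 0))
  expect_true(all(mt$mu_incoherent > 0))
  expect_true(all(mt$mu_total >= mt$mu_pe))
  expect_true(all(mt$mu_total >= mt$mu_incoherent))
  expect_true(all(mt$mu_en <= mt$mu_total))
  # bone attenuates more than soft tissue per gram at low energy
  expect_gt(mass_atten(mt, "bone", 30), mass_atten(mt, "soft", 30))
})

test_that("spectrum has bounded support and normalised fluence", {
  s <- build_spectrum(120, 0)
  expect_equal(sum(s$fluence), 1, tolerance = 1e-9)
  expect_true(all(s$energy_kev <= 120))
  expect_true(all(s$fluence >= 0))
  expect_error(build_spectrum(40), "invalid parameter")
  expect_error(build_spectrum(200), "invalid parameter")
})

test_that("filtration hardens the beam monotonically", {
  for (kvp in c(80, 100, 120, 140)) {
    e0 <- spectrum_mean_energy(build_spectrum(kvp, 0))
    e5 <- spectrum_mean_energy(build_spectrum(kvp, 5))
    expect_gt(e5, e0)
  }
})

test_that("spectrum bins match an independent evaluation of the closed form", {
  # independent re-implementation: Kramers shape attenuated by 3 mm Al,
  # using the table coefficients directly
  mt <- material_table()
  kvp <- 100; filt <- 3
  e <- 10:100
  mu_al <- exp(stats::approx(log(mt$energy_kev),
                             log(mt$mu_total[, "aluminium"]),
                             xout = log(e))$y) * 2.699 / 10
  expected <- (kvp - e) / e * exp(-mu_al * filt)
  expected <- expected / sum(expected)
  s <- build_spectrum(kvp, filt)
  for (spot in c(20, 40, 60, 80, 99)) {
    expect_equal(s$fluence[match(spot, s$energy_kev)],
                 expected[match(spot, e)], tolerance = 1e-12)
  }
})

test_that("HVL of a monoenergetic beam equals ln2 / mu", {
  mt <- material_table()
  s <- mono_spectrum(60)
  mu <- linear_atten_mm(mt, "aluminium", 60)
  expect_equal(compute_hvl(s, mt), log(2) / mu, tolerance = 1e-4)
})

test_that("HVL matches a brute-force transmission scan", {
  mt <- material_table()
  s <- build_spectrum(100, 3)
  e <- s$energy_kev
  w <- s$fluence * e * mass_atten(mt, "air", e, "en")
  mu <- linear_atten_mm(mt, "aluminium", e)
  xs <- seq(0, 10, by = 0.001)
  trans <- vapply(xs, function(x) sum(w * exp(-mu * x)) / sum(w), numeric(1))
  brute <- xs[which.min(abs(trans - 0.5))]
  expect_equal(compute_hvl(s, mt), brute, tolerance = 2e-3)
})

test_that("HVL grows with filtration and with extra hardening", {
  mt <- material_table()
  set.seed(4)
  for (i in 1:10) {
    kvp <- sample(80:140, 1)
    f <- stats::runif(1, 0, 8)
    h1 <- compute_hvl(build_spectrum(kvp, f), mt)
    h2 <- compute_hvl(build_spectrum(kvp, f + stats::runif(1, 0.5, 5)), mt)
    expect_gt(h2, h1)
  }
})

test_that("filtration tuning recovers a known HVL", {
  mt <- material_table()
  target <- compute_hvl(build_spectrum(120, 4), mt)
  s <- tune_filtration_to_hvl(120, target, mt)
  expect_equal(s$filtration_mm_al, 4, tolerance = 0.02)
  s2 <- tune_filtration_to_hvl(100, 5, mt)
  expect_gte(compute_hvl(s2, mt), 4.99)
  expect_lte(compute_hvl(s2, mt), 5.01)
  # below the zero-filtration HVL the target is unreachable
  h0 <- compute_hvl(build_spectrum(120, 0), mt)
  expect_error(tune_filtration_to_hvl(120, h0 / 2, mt),
               "unachievable target")
})

test_that("bowtie transmission follows the thickness profile", {
  mt <- material_table()
  bw0 <- bowtie_filter(0.4, 0)
  expect_equal(bowtie_transmission(bw0, 0, 60, mt), 1.0)
  expect_equal(bowtie_transmission(bw0, 0.2, 100, mt), 1.0)
  bw <- bowtie_filter(0.4, 10)
  g <- seq(-0.4, 0.4, by = 0.05)
  tr <- vapply(g, function(x) bowtie_transmission(bw, x, 60, mt), numeric(1))
  expect_equal(tr, rev(tr))                       # symmetry
  expect_true(all(diff(tr[g >= 0]) <= 0))          # non-increasing in |gamma|
  # hand evaluation at gamma = gamma_max / 2: t = t_max / 4
  mu_al <- linear_atten_mm(mt, "aluminium", 60)
  expect_equal(bowtie_transmission(bw, 0.2, 60, mt),
               exp(-mu_al * 10 / 4), tolerance = 1e-12)
  expect_error(bowtie_transmission(bw, 0.5, 60, mt), "out of fan")
})

test_that("scanner model validates its geometry", {
  expect_error(scanner_model(pitch = 2.5), "pitch")
  expect_warning(scanner_model(pitch = 0.8), "pitch")
  expect_s3_class(scanner_archetype("online"), "scanner_model")
  expect_equal(kvp_for_bmi(c("underweight", "normal", "overweight", "obese")),
               c(100, 120, 120, 140))
})
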