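test_that("the modulation rule is the exponential of the WED deviation", {
  m <- atcm_model(ref_wed_mm = 250, ref_ma = 60, strength = 0.5,
                  mu_eff_mm = 0.02)
  expect_equal(atcm_ma(m, 250), 60)                   # identity at reference
  expect_equal(atcm_ma(m, rep(250, 5)), rep(60, 5))
  # s=0.5, mu=0.02/mm, dWED=+50mm -> factor e^0.5
  expect_equal(atcm_ma(m, 300, clamp = FALSE) / 60, exp(0.5),
               tolerance = 1e-12)
  # monotone: larger WED never gives smaller current
  set.seed(2)
  for (i in 1:10) {
    w1 <- runif(20, 150, 350)
    w2 <- w1 + runif(20, 0, 60)
    expect_true(all(atcm_ma(m, w2, clamp = FALSE) >=
                      atcm_ma(m, w1, clamp = FALSE)))
  }
})

test_that("dual-localiser combination halves the log magnification error", {
  m <- atcm_model(aspect_prior = 1)  # circular body; prior plays no role
  w <- rep(250, 10)
  pa <- synthetic_localiser(w, angle = "PA")
  lat <- synthetic_localiser(w, angle = "LAT_left")
  base <- predict_profile(m, pa, lat)
  M <- 1.1111
  pa_mag <- synthetic_localiser(w * M, angle = "PA",
                                offset = c(x = 0, y = -60))
  dual <- predict_profile(m, pa_mag, lat)
  single <- predict_profile(m, pa_mag)
  single_base <- predict_profile(m, pa)
  # dual effective WED scales with sqrt(M) exactly
  expect_equal(dual$ma / base$ma,
               rep(exp(0.5 * 0.02 * 250 * (sqrt(M) - 1)), 10),
               tolerance = 1e-9)
  # single-PA effective WED scales with M exactly
  expect_equal(single$ma / single_base$ma,
               rep(exp(0.5 * 0.02 * 250 * (M - 1)), 10),
               tolerance = 1e-9)
  # hence the log-error of dual is exactly half that of single
  expect_equal(log(dual$ma / base$ma) / log(single$ma / single_base$ma),
               rep((sqrt(M) - 1) / (M - 1), 10), tolerance = 1e-6)
})

test_that("parallel localiser pairs are rejected", {
  m <- atcm_model()
  pa <- synthetic_localiser(rep(250, 4), angle = "PA")
  ap <- synthetic_localiser(rep(250, 4), angle = "AP")
  expect_error(predict_profile(m, pa, ap), "invalid combination")
})

test_that("the lateral-failure variant stops modulating under lateral off-centring", {
  m <- atcm_model("size_compensated", lateral_failure = TRUE)
  w <- c(220, 240, 260, 280, 260, 240)
  img <- synthetic_localiser(w, angle = "PA", offset = c(x = -20, y = 0))
  prof <- predict_profile(m, img)
  # constant at the thickest-slice current: no z-modulation left, and
  # never below what working modulation would have used
  expect_equal(length(unique(prof$ma)), 1)
  img0 <- synthetic_localiser(w, angle = "PA", offset = c(x = -10, y = 0))
  working <- predict_profile(m, img0)
  expect_true(all(prof$ma >= working$ma))
  expect_gt(length(unique(working$ma)), 1)  # below 2 cm it still modulates
})

test_that("NRMSE translation is the identity for identical profiles", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    ref <- tube_current_profile((1:n) * 5, runif(n, 50, 200))
    pat <- tube_current_profile((1:12) * 7, runif(12, 80, 300))
    out <- nrmse_translate(ref, ref, pat)
    expect_equal(out$ma, pat$ma, tolerance = 1e-12)
    expect_equal(out$provenance, "translated")
  }
})

test_that("NRMSE translation transfers uniform scalings exactly", {
  set.seed(6)
  for (c_fac in c(0.5, 0.9, 1.3, 2.0)) {
    n <- 25
    ref <- tube_current_profile((1:n) * 4, runif(n, 60, 180))
    dev <- tube_current_profile(ref$z_mm, ref$ma * c_fac)
    pat <- tube_current_profile((1:15) * 9, runif(15, 80, 250))
    out <- nrmse_translate(ref, dev, pat)
    expect_equal(out$ma, pat$ma * c_fac, tolerance = 1e-9)
  }
})

test_that("NRMSE translation recovers the hand-worked two-run example", {
  ref <- tube_current_profile((0:3) * 5, rep(100, 4))
  dev <- tube_current_profile((0:3) * 5, c(110, 110, 90, 90))
  pat <- tube_current_profile((0:3) * 5, rep(100, 4))
  out <- nrmse_translate(ref, dev, pat)
  expect_equal(out$ma, c(110, 110, 90, 90), tolerance = 1e-12)
})

test_that("NRMSE translation recovers prescribed run factors", {
  pair <- make_profile_pair(list(c(2, 1.1), c(2, 0.9)))
  pat <- tube_current_profile((0:3) * 5, rep(100, 4))
  out <- nrmse_translate(pair$ref, pair$dev, pat)
  expect_equal(out$ma, 100 * pair$factors, tolerance = 1e-12)
  # single-run identity
  pair1 <- make_profile_pair(list(c(4, 1.0)))
  out1 <- nrmse_translate(pair1$ref, pair1$dev, pat)
  expect_equal(out1$ma, pat$ma)
})

test_that("NRMSE run factors stay positive even for extreme deviations", {
  # with RMS normalisation a downward run has RMSE < RMS(ref) whenever
  # 0 < dev < ref pointwise, so factors remain positive for any valid
  # profile pair -- the translated currents can never cross zero
  set.seed(8)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    ref <- tube_current_profile((1:n) * 5, stats::runif(n, 1, 500))
    dev <- tube_current_profile(ref$z_mm,
                                ref$ma * stats::runif(n, 1e-4, 3))
    pat <- tube_current_profile((1:9) * 7, stats::runif(9, 10, 400))
    out <- nrmse_translate(ref, dev, pat)
    expect_true(all(out$ma > 0))
  }
})

test_that("DICOM extraction reads, sorts and validates a series", {
  dir <- file.path(tempdir(), "dcm1")
  unlink(dir, recursive = TRUE)
  make_dicom_series(dir, ma_values = c(5, 10, 15), z_mm = c(0, 5, 10))
  prof <- extract_profile_dicom(dir)
  expect_equal(prof$ma, c(5, 10, 15))
  expect_equal(prof$z_mm, c(0, 5, 10))
  expect_equal(prof$provenance, "dicom")
  # shuffled file naming does not change the z-sorted profile
  dir2 <- file.path(tempdir(), "dcm2")
  unlink(dir2, recursive = TRUE)
  make_dicom_series(dir2, ma_values = c(5, 10, 15), z_mm = c(0, 5, 10),
                    shuffle_order = c(3, 1, 2))
  expect_equal(extract_profile_dicom(dir2)$ma, c(5, 10, 15))
  # single slice
  dir3 <- file.path(tempdir(), "dcm3")
  unlink(dir3, recursive = TRUE)
  make_dicom_series(dir3, ma_values = 42)
  expect_equal(extract_profile_dicom(dir3)$ma, 42)
  # empty directory errors
  dir4 <- file.path(tempdir(), "dcm_empty")
  dir.create(dir4, showWarnings = FALSE)
  expect_error(extract_profile_dicom(dir4), "no files")
})

test_that("DICOM fixtures are readable by an independent parser", {
  dir <- file.path(tempdir(), "dcm_oracle")
  unlink(dir, recursive = TRUE)
  make_dicom_series(dir, ma_values = c(7, 21, 14), z_mm = c(0, 5, 10))
  script <- paste(
    "import sys, glob, pydicom",
    "rows = []",
    "for f in sorted(glob.glob(sys.argv[1] + '/*.dcm')):",
    "    d = pydicom.dcmread(f)",
    "    rows.append((float(d.SliceLocation), int(d.XRayTubeCurrent)))",
    "rows.sort()",
    "print(';'.join('%g,%d' % r for r in rows))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(dir)),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(tail(out, 1), "0,7;5,21;10,14")
  expect_equal(extract_profile_dicom(dir)$ma, c(7, 21, 14))
})

test_that("profile CSV round trip preserves the profile and validates input", {
  prof <- tube_current_profile(c(0, 5, 10), c(55.5, 60.25, 44))
  f <- tempfile(fileext = ".csv")
  write_profile_csv(prof, f)
  back <- read_profile_csv(f)
  expect_equal(back$z_mm, prof$z_mm)
  expect_equal(back$ma, prof$ma)
  writeLines(c("z_mm,mA", "0,-5"), f)
  expect_error(read_profile_csv(f), "validation error")
  writeLines("z_mm,mA", f)
  expect_error(read_profile_csv(f), "empty-profile")
})

test_that("online modulation requires the online archetype", {
  m <- atcm_model("prospective_magnification")
  prof <- flat_profile()
  expect_error(online_modulate(m, prof, fx_cylinder(),
                               scan_protocol(120, 40, 1.4, 0.5,
                                             "caudocranial", c(50, 250),
                                             profile = prof),
                               fx_scanner()),
               "invalid archetype")
})

test_that("online modulation reproduces the prediction on a centred cylinder", {
  sc <- scanner_archetype("online")
  m <- atcm_model_for_scanner(sc)
  cyl <- fx_cylinder()
  img <- project_localiser(cyl, projection_geometry("PA", sc$sid_mm))
  pred <- predict_profile(m, img)
  keep <- pred$z_mm >= 40 & pred$z_mm <= 260
  pred <- tube_current_profile(pred$z_mm[keep], pred$ma[keep])
  prot <- scan_protocol(120, sc$collimation_mm, sc$pitch, 0.6,
                        "caudocranial", c(40, 260), profile = pred)
  onl <- online_modulate(m, pred, cyl, prot, sc, frontal = img)
  # feedback sees the attenuation the prediction anticipated; the residual
  # is chord-model voxelisation
  expect_lt(max(abs(onl$ma / pred$ma - 1)), 0.03)
})

test_that("online feedback responds with half a rotation of lag", {
  # cylinder with a dense (bone) band in its upper half: scanning towards
  # the band, the current rises only after the band has been seen by the
  # detector, i.e. the response at a given z appears once the source is
  # half a rotation past it
  sc <- scanner_archetype("online")
  m <- atcm_model_for_scanner(sc)
  cyl <- water_cylinder_phantom(300)
  # the localiser (and hence the anticipated attenuation) sees the plain
  # cylinder; the dense band is added afterwards so it is a surprise that
  # only the real-time feedback can react to
  img <- project_localiser(cyl, projection_geometry("PA", sc$sid_mm))
  zs <- slice_z_mm(cyl)
  band <- zs >= 200 & zs <= 240
  bone <- cyl$material_codes[["bone"]]
  soft <- cyl$material_codes[["soft"]]
  for (iz in which(band)) {
    sl <- cyl$material[iz, , ]
    sl[sl == soft] <- bone
    cyl$material[iz, , ] <- sl
  }
  dens <- default_materials()$density
  cyl$density <- array(dens[names(cyl$material_codes)][cyl$material + 1L],
                       dim = cyl$shape)
  pred <- predict_profile(m, img)
  keep <- pred$z_mm >= 40 & pred$z_mm <= 260
  pred_flat <- tube_current_profile(pred$z_mm[keep],
                                    rep(mean(pred$ma[keep]),
                                        sum(keep)))  # uniform prediction
  prot <- scan_protocol(120, sc$collimation_mm, sc$pitch, 0.6,
                        "caudocranial", c(40, 260), profile = pred_flat)
  onl <- online_modulate(m, pred_flat, cyl, prot, sc, frontal = img)
  rr <- onl$rotation_resolved
  feed <- sc$collimation_mm * sc$pitch
  # the detector first sees the band at z = 200; the current response must
  # lag behind that position, not anticipate it
  ramp_start <- min(rr$z_mm[rr$ma > 1.1 * pred_flat$ma[1]])
  expect_gt(ramp_start, 200)
  expect_lt(ramp_start, 240 + feed)   # but it does respond within a feed
  # scan positions well before the band are unaffected
  early <- rr$z_mm < 200 - 1.5 * feed
  expect_true(all(abs(rr$ma[early] / pred_flat$ma[1] - 1) < 0.05))
})
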