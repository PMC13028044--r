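# Automatic tube current modulation (ATCM).
#
# Vendor ATCM rules are proprietary; this module implements behavioural
# archetypes around the constant-noise relation mA ~ exp(mu * WED): a
# purely prospective system that trusts the (possibly magnified) localiser
# width, a size-compensated system that corrects the geometric width with
# the magnification-invariant attenuation estimate, and an online system
# that adds real-time feedback with half-a-rotation lag. Profiles can also
# be read from DICOM series or CSV, and translated between a reference
# phantom and a patient model through per-run NRMSE factors.

#' Tube current profile
#'
#' @param z_mm slice positions in mm (strictly increasing after sorting)
#' @param ma tube current in mA per slice (> 0)
#' @param provenance one of `"computed"`, `"dicom"`, `"translated"`, `"file"`
#' @param rotation_resolved optional data frame (`z_mm`, `theta_rad`, `ma`)
#'   carrying angular-resolved modulation
#' @return object of class `tube_current_profile`
#' @export
tube_current_profile <- function(z_mm, ma, provenance = "computed",
                                 rotation_resolved = NULL) {
  if (length(z_mm) != length(ma) || length(ma) == 0) {
    stop("empty profile or length mismatch")
  }
  ord <- order(z_mm)
  z_mm <- z_mm[ord]; ma <- ma[ord]
  if (any(duplicated(z_mm))) stop("duplicate z positions in profile")
  if (any(!is.finite(ma)) || any(ma <= 0)) {
    stop("validation error: tube current must be positive and finite")
  }
  structure(list(z_mm = z_mm, ma = ma, provenance = provenance,
                 rotation_resolved = rotation_resolved),
            class = "tube_current_profile")
}

#' @export
print.tube_current_profile <- function(x, ...) {
  cat(sprintf("tube_current_profile (%s): %d slices, z [%.0f, %.0f] mm, mA [%.1f, %.1f]\n",
              x$provenance, length(x$z_mm), min(x$z_mm), max(x$z_mm),
              min(x$ma), max(x$ma)))
  invisible(x)
}

#' Resample a profile onto a new z grid
#' @param profile a `tube_current_profile`
#' @param z_mm target positions
#' @return resampled profile (linear interpolation, flat extrapolation)
#' @export
resample_profile <- function(profile, z_mm) {
  ma <- stats::approx(profile$z_mm, profile$ma, xout = z_mm, rule = 2)$y
  tube_current_profile(z_mm, ma, provenance = profile$provenance)
}

#' ATCM model
#'
#' @param archetype `"prospective_magnification"`, `"online_lag"` or
#'   `"size_compensated"`
#' @param ref_wed_mm reference water-equivalent diameter at which the
#'   reference current applies
#' @param ref_ma reference tube current in mA
#' @param strength modulation strength s in (0, 1]: fraction of the full
#'   constant-noise exponent applied (vendors attenuate the theoretical
#'   mA ~ exp(mu * WED) response)
#' @param mu_eff_mm effective water attenuation coefficient (1/mm) at the
#'   localiser effective energy
#' @param ma_limits clamp bounds (min, max) in mA
#' @param lateral_failure logical; variant whose modulation shuts down
#'   once lateral off-centring reaches 2 cm, holding the conservative
#'   constant current of its thickest predicted slice
#' @param aspect_prior typical anteroposterior-to-lateral body aspect
#'   ratio assumed when only a single localiser is available: a frontal
#'   width `w` is converted to `WED = w * sqrt(aspect_prior)` (a lateral
#'   width to `w / sqrt(aspect_prior)`), the geometric-mean ellipse rule
#'   with the unseen axis filled in by the prior. This keeps single- and
#'   dual-localiser WED estimates consistent for a typical torso while
#'   preserving the full magnification sensitivity of the measured axis.
#' @return object of class `atcm_model`
#' @export
atcm_model <- function(archetype = c("prospective_magnification",
                                     "online_lag", "size_compensated"),
                       ref_wed_mm = 250, ref_ma = 60, strength = 0.5,
                       mu_eff_mm = 0.02, ma_limits = c(10, 700),
                       lateral_failure = FALSE, aspect_prior = 0.735) {
  archetype <- match.arg(archetype)
  stopifnot(ref_wed_mm > 0, ref_ma > 0, mu_eff_mm > 0,
            strength > 0, strength <= 1, aspect_prior > 0,
            length(ma_limits) == 2, ma_limits[1] > 0,
            ma_limits[2] > ma_limits[1])
  structure(list(archetype = archetype, ref_wed_mm = ref_wed_mm,
                 ref_ma = ref_ma, strength = strength,
                 mu_eff_mm = mu_eff_mm, ma_limits = ma_limits,
                 lateral_failure = lateral_failure,
                 aspect_prior = aspect_prior),
            class = "atcm_model")
}

#' Tube current from an effective water-equivalent diameter
#'
#' The core modulation rule shared by all archetypes:
#' `mA = clamp(ref_ma * exp(s * mu_eff * (WED - ref_wed)))`; a WED series
#' equal to the reference diameter returns the reference current.
#'
#' @param model an [atcm_model()]
#' @param wed_mm effective water-equivalent diameter(s), mm
#' @param clamp apply the mA limits (default TRUE)
#' @return tube current(s) in mA
#' @export
atcm_ma <- function(model, wed_mm, clamp = TRUE) {
  ma <- model$ref_ma * exp(model$strength * model$mu_eff_mm *
                             (wed_mm - model$ref_wed_mm))
  if (clamp) ma <- pmin(pmax(ma, model$ma_limits[1]), model$ma_limits[2])
  ma
}

#' ATCM model matching a scanner archetype
#' @param scanner a [scanner_model()]
#' @param ... overrides passed to [atcm_model()]
#' @return an `atcm_model`
#' @export
atcm_model_for_scanner <- function(scanner, ...) {
  atcm_model(archetype = scanner$atcm_archetype,
             ma_limits = scanner$ma_limits,
             lateral_failure = scanner$lateral_failure, ...)
}

.is_frontal <- function(image) image$geometry$angle %in% c("PA", "AP")
.is_lateral <- function(image) grepl("^LAT", image$geometry$angle)

# attenuation-derived circular-equivalent width: mean chord of a disc of
# diameter D is pi*D/4, so D = 4/pi * mean water-equivalent path. Path
# lengths through the body are (to first order) invariant under
# displacement along the beam axis, which is what makes this estimate the
# basis of magnification compensation.
.attenuation_width <- function(image) 4 / pi * image$wepl_mm

# size-compensated archetype: divide the geometric width by the internally
# estimated magnification. The attenuation width is displacement-invariant
# while the geometric width scales with the magnification M, so their
# ratio betrays M -- but the ratio is also offset from 1 by the body's
# aspect (a frontal view measures the lateral extent geometrically and
# the AP extent attenuation-wise). The population aspect prior normalises
# that away, so a centred typical patient gives M_est = 1.
.compensate_width <- function(image, aspect_prior) {
  w <- image$width_mm
  wa <- .attenuation_width(image)
  ok <- w > 0 & wa > 0
  if (!any(ok)) return(w)
  ratio <- stats::median(w[ok] / wa[ok])
  m_est <- if (.is_lateral(image)) ratio / aspect_prior
           else ratio * aspect_prior
  w / m_est
}

#' Predict a tube current profile from one or two localisers
#'
#' Effective water-equivalent diameter per slice: with a single localiser
#' the measured width is combined with the population aspect prior (see
#' [atcm_model()]); with an orthogonal pair the elliptical rule
#' `WED = sqrt(width_frontal * width_lateral)` is used, which is why a
#' magnification error of factor M on one projection enters the dual
#' estimate only as sqrt(M). The tube current follows
#' `mA(z) = clamp(ref_ma * exp(s * mu_eff * (WED(z) - ref_wed)))`.
#' The size-compensated archetype first replaces each geometric width by
#' its magnification-corrected value; its lateral-failure variant stops
#' modulating once lateral off-centring reaches 2 cm and holds the
#' conservative constant current of its thickest slice everywhere
#' (modulation dysfunction: doses rise for every organ).
#'
#' @param model an [atcm_model()]
#' @param frontal a PA or AP `localiser_image` (or a lateral image if only
#'   a single lateral localiser was acquired)
#' @param lateral optional orthogonal LAT `localiser_image`
#' @return a `tube_current_profile` (provenance `"computed"`)
#' @export
predict_profile <- function(model, frontal, lateral = NULL) {
  if (!is.null(lateral)) {
    if (.is_frontal(frontal) == .is_frontal(lateral)) {
      stop("invalid combination: two localisers from parallel projection ",
           "axes cannot be combined")
    }
    if (.is_lateral(frontal)) { tmp <- frontal; frontal <- lateral; lateral <- tmp }
  }

  wf <- if (model$archetype == "size_compensated") .compensate_width(frontal, model$aspect_prior)
        else frontal$width_mm
  if (is.null(lateral)) {
    # geometric-mean ellipse rule with the unseen axis from the prior
    wed <- if (.is_lateral(frontal)) wf / sqrt(model$aspect_prior)
           else wf * sqrt(model$aspect_prior)
  } else {
    wl_raw <- if (model$archetype == "size_compensated") .compensate_width(lateral, model$aspect_prior)
              else lateral$width_mm
    wl <- stats::approx(lateral$z_mm, wl_raw, xout = frontal$z_mm, rule = 2)$y
    wed <- sqrt(pmax(wf, 0) * pmax(wl, 0))
  }
  ma <- atcm_ma(model, wed)
  offsets <- frontal$geometry$offset_mm
  if (model$lateral_failure && abs(offsets[["x"]]) >= 20) {
    # modulation dysfunction: the system stops tracking z and falls back
    # to a conservative constant current, the maximum its own prediction
    # asked for anywhere in the range -- every slice gets at least the
    # current of the thickest section
    ma <- rep(max(ma), length(ma))
  }
  tube_current_profile(frontal$z_mm, ma, provenance = "computed")
}

#' Apply online (real-time) modulation to a predicted profile
#'
#' Models an ATCM with real-time feedback on top of the localiser
#' prediction. The first half rotation operates without feedback at a
#' conservative start-up current (the maximum of the predicted profile);
#' from then on the current at gantry angle theta is the predicted current
#' corrected by the deviation between the attenuation actually measured up
#' to half a rotation earlier and the attenuation the localiser model
#' anticipated there:
#' `mA = pred(z) * exp(s * mu_eff * (chord_measured - chord_anticipated))`,
#' where both chords are rotation-averaged central water-equivalent path
#' lengths. When the prediction is unbiased (patient centred, localiser
#' undistorted) the correction vanishes and the online profile equals the
#' prediction; when the localiser was geometrically distorted the feedback
#' pulls the current back towards the true attenuation everywhere except
#' the start-up region -- which is what makes the scan direction matter for
#' this archetype. Angular-resolved currents are kept in
#' `rotation_resolved`; the per-z collapse drives the dose engine.
#'
#' @param model an [atcm_model()] with archetype `"online_lag"`
#' @param predicted the localiser-predicted `tube_current_profile`
#' @param phantom the `voxel_phantom` actually on the table
#' @param protocol a [scan_protocol()] (direction, collimation, pitch,
#'   offsets, scan range)
#' @param scanner a [scanner_model()] (SID)
#' @param frontal optional frontal `localiser_image` of this phantom under
#'   the setup's geometry; supplies the anticipated attenuation (apparent
#'   width and mean water-equivalent path per z). Without it the
#'   anticipated chord falls back to the WED implied by inverting the
#'   predicted profile.
#' @param materials material table
#' @param steps_per_rotation angular discretisation (default 12)
#' @return a `tube_current_profile` with `rotation_resolved` attached
#' @export
online_modulate <- function(model, predicted, phantom, protocol, scanner,
                            frontal = NULL,
                            materials = default_materials(),
                            steps_per_rotation = 12) {
  if (model$archetype != "online_lag") {
    stop("invalid archetype: online_modulate requires an 'online_lag' model, got '",
         model$archetype, "'")
  }
  sid <- scanner$sid_mm
  feed <- protocol$collimation_mm * protocol$pitch
  z0 <- protocol$z_range_mm[1]; z1 <- protocol$z_range_mm[2]
  if (protocol$direction == "craniocaudal") { tmp <- z0; z0 <- z1; z1 <- tmp }
  # z0 -> z1 is the table travel order (caudocranial: caudal to cranial)
  travel <- z1 - z0
  n_steps <- max(steps_per_rotation,
                 ceiling(abs(travel) / feed * steps_per_rotation))
  zk <- z0 + travel * (seq_len(n_steps) - 0.5) / n_steps
  thetak <- 2 * pi * abs(zk - z0) / feed
  spec <- scanner$spectra[[as.character(protocol$kvp)]]
  if (is.null(spec)) spec <- build_spectrum(protocol$kvp, 4)
  e_eff <- spectrum_mean_energy(spec, "kerma", materials)
  mu_vox <- .phantom_mu_per_mm(phantom, e_eff, materials)
  mu_w <- linear_atten_mm(materials, "soft", e_eff)
  origin <- c(phantom$origin_mm[["z"]],
              phantom$origin_mm[["y"]] + protocol$offset_mm[["y"]],
              phantom$origin_mm[["x"]] + protocol$offset_mm[["x"]])
  central_wepl <- function(theta, z) {
    src <- c(z, -sid * cos(theta), sid * sin(theta))
    tgt <- c(z, sid * cos(theta), -sid * sin(theta))
    cpp_line_integral(as.numeric(mu_vox), phantom$shape,
                      as.numeric(phantom$spacing_mm), as.numeric(origin),
                      src, tgt, min(phantom$spacing_mm) / 2) / mu_w
  }
  # anticipated rotation-mean central chord per z: ellipse with lateral
  # semi-axis from the apparent width and AP semi-axis from the mean
  # water-equivalent path (mean chord of an ellipse is pi/4 of its full
  # depth), averaged over gantry angles
  th_grid <- seq(0, pi, length.out = 37)[-37]
  anticipated <- if (!is.null(frontal)) {
    # deproject the apparent width: a centred convex body of radius r
    # projects to W = 2*L*r/sqrt(L^2 - r^2) in a divergent fan at SID L,
    # so the anticipated lateral semi-axis is r = W*L/sqrt(4L^2 + W^2);
    # displacement magnification is invisible to the scanner and stays in
    L <- frontal$geometry$sid_mm
    W <- stats::approx(frontal$z_mm, frontal$width_mm, xout = zk,
                       rule = 2)$y
    a_half <- W * L / sqrt(4 * L^2 + W^2)
    b_half <- stats::approx(frontal$z_mm, 4 / pi * frontal$wepl_mm / 2,
                            xout = zk, rule = 2)$y
    vapply(seq_along(zk), function(i) {
      a <- a_half[i]; b <- b_half[i]
      if (a <= 0 || b <= 0) return(0)
      mean(2 * a * b / sqrt(a^2 * sin(th_grid)^2 + b^2 * cos(th_grid)^2))
    }, numeric(1))
  } else {
    ma_i <- stats::approx(predicted$z_mm, predicted$ma, xout = zk,
                          rule = 2)$y
    model$ref_wed_mm + log(ma_i / model$ref_ma) /
      (model$strength * model$mu_eff_mm)
  }
  pred_at <- stats::approx(predicted$z_mm, predicted$ma, xout = zk,
                           rule = 2)$y
  lag <- steps_per_rotation %/% 2
  srot <- steps_per_rotation
  measured <- vapply(seq_len(n_steps),
                     function(k) central_wepl(thetak[k], zk[k]), numeric(1))
  ma_start <- max(predicted$ma)
  mak <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    if (k <= lag) {
      mak[k] <- ma_start
    } else {
      win <- max(1, k - lag - srot + 1):(k - lag)
      dev_mm <- mean(measured[win]) - mean(anticipated[win])
      mak[k] <- pred_at[k] * exp(model$strength * model$mu_eff_mm * dev_mm)
    }
  }
  mak <- pmin(pmax(mak, model$ma_limits[1]), model$ma_limits[2])
  # collapse: average angular samples onto the predicted profile's z grid
  zgrid <- predicted$z_mm
  half_bin <- if (length(zgrid) > 1) diff(zgrid)[1] / 2 else feed / 2
  ma_z <- vapply(zgrid, function(z) {
    sel <- abs(zk - z) <= max(half_bin, feed / steps_per_rotation)
    if (any(sel)) mean(mak[sel]) else NA_real_
  }, numeric(1))
  ma_z <- stats::approx(zgrid[!is.na(ma_z)], ma_z[!is.na(ma_z)],
                        xout = zgrid, rule = 2)$y
  tube_current_profile(zgrid, ma_z, provenance = "computed",
                       rotation_resolved = data.frame(
                         z_mm = zk, theta_rad = thetak, ma = mak))
}

# ---- DICOM extraction ------------------------------------------------------

# Minimal explicit-VR little-endian DICOM element walk. Only the tags the
# profile extraction needs are interpreted; everything else is skipped by
# length. No R DICOM parser is available in this stack, so the subset is
# implemented directly against the encoding rules.
.dicom_read_elements <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    stop("I/O error: ", path, " is not a DICOM file (missing DICM marker)")
  }
  pos <- 133L
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  u16 <- function(i) readBin(raw[i:(i + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(raw[i:(i + 3)], "integer", size = 4,
                             endian = "little")
  while (pos + 8 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); hdr <- 12L
    } else {
      len <- u16(pos + 6L); hdr <- 8L
    }
    if (len < 0 || pos + hdr + len - 1L > length(raw)) break
    key <- sprintf("%04x,%04x", group, elem)
    if (len > 0) {
      val <- raw[(pos + hdr):(pos + hdr + len - 1L)]
      out[[key]] <- rawToChar(val[val != as.raw(0)])  # strip padding nuls
    } else {
      out[[key]] <- ""
    }
    pos <- pos + hdr + len
  }
  out
}

#' Extract a tube current profile from a DICOM CT series
#'
#' Reads per-slice tube current (tag 0018,1151) and slice location
#' (0020,1041) from every DICOM file in a directory and returns the
#' profile ordered by ascending z, independent of file order on disk.
#'
#' @param series_dir directory containing single-frame CT instances
#' @return a `tube_current_profile` (provenance `"dicom"`)
#' @export
extract_profile_dicom <- function(series_dir) {
  files <- list.files(series_dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) {
    stop("I/O error: no files in DICOM series directory ", series_dir)
  }
  z <- numeric(0); ma <- numeric(0)
  for (f in files) {
    el <- .dicom_read_elements(f)
    cur <- el[["0018,1151"]]
    loc <- el[["0020,1041"]]
    if (is.null(cur) || !nzchar(trimws(cur))) {
      stop("I/O error: missing tube current attribute (0018,1151) in ", f)
    }
    if (is.null(loc) || !nzchar(trimws(loc))) {
      stop("I/O error: missing slice location attribute (0020,1041) in ", f)
    }
    z <- c(z, as.numeric(trimws(loc)))
    ma <- c(ma, as.numeric(trimws(cur)))
  }
  if (any(duplicated(z))) {
    stop("duplicate slice locations in DICOM series ", series_dir)
  }
  tube_current_profile(z, ma, provenance = "dicom")
}

# ---- NRMSE profile translation --------------------------------------------

#' Translate ATCM deviations onto a patient profile via per-run NRMSE factors
#'
#' Implements the phantom-to-patient transfer of ATCM deviations: the
#' reference-phantom profile for the deviating setup is compared
#' slice-by-slice against the phantom's reference profile; maximal runs of
#' slices where the deviating profile is consistently higher (or lower)
#' are each summarised by a normalised RMSE factor
#' `f = 1 + sign * RMSE / RMS(ref)` (run-local root-mean-square
#' normalisation, which makes a uniformly scaled deviation transfer
#' exactly multiplicatively); runs where the profiles agree within the
#' tolerance get factor 1, so identical profiles leave the patient profile
#' unchanged. Each run's fractional extent of the phantom scan range is
#' mapped onto the same fraction of the patient scan range and the
#' patient's reference currents are multiplied by the run factor.
#'
#' @param ref reference-setup phantom profile
#' @param dev deviating-setup phantom profile (resampled onto `ref`'s grid
#'   if sampled differently)
#' @param patient_ref the patient model's own reference profile
#' @param eps relative tolerance below which slices count as identical
#' @return a `tube_current_profile` (provenance `"translated"`)
#' @export
nrmse_translate <- function(ref, dev, patient_ref, eps = 0.01) {
  if (length(patient_ref$z_mm) == 0) stop("empty patient profile")
  if (length(ref$z_mm) == 0 || length(dev$z_mm) == 0) {
    stop("empty overlap: reference or deviating profile is empty")
  }
  if (length(dev$z_mm) != length(ref$z_mm) ||
        any(abs(dev$z_mm - ref$z_mm) > 1e-9)) {
    dev <- resample_profile(dev, ref$z_mm)
  }
  r <- ref$ma; d <- dev$ma
  n <- length(r)
  sgn <- sign(d - r)
  sgn[abs(d - r) <= eps * r] <- 0
  # maximal constant-sign runs
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  factors <- numeric(length(runs$values))
  for (i in seq_along(runs$values)) {
    s <- runs$values[i]
    if (s == 0) { factors[i] <- 1; next }
    idx <- starts[i]:ends[i]
    nrmse <- sqrt(mean((d[idx] - r[idx])^2)) / sqrt(mean(r[idx]^2))
    factors[i] <- 1 + s * nrmse
    if (factors[i] <= 0) {
      stop("degenerate factor: run ", i, " has non-positive factor ",
           factors[i])
    }
  }
  # map fractional run extents onto the patient scan range
  m <- length(patient_ref$ma)
  frac_pat <- (seq_len(m) - 0.5) / m
  run_of <- findInterval(frac_pat, c(0, ends / n), rightmost.closed = TRUE)
  run_of[run_of < 1] <- 1
  run_of[run_of > length(factors)] <- length(factors)
  out_ma <- patient_ref$ma * factors[run_of]
  tube_current_profile(patient_ref$z_mm, out_ma, provenance = "translated")
}

# ---- CSV round trip --------------------------------------------------------

#' Read / write tube current profiles as CSV
#'
#' Columns `z_mm`, `mA`. Reading validates positivity and non-emptiness.
#'
#' @param profile a `tube_current_profile`
#' @param path file path
#' @return `write_profile_csv`: the path, invisibly;
#'   `read_profile_csv`: a `tube_current_profile` (provenance `"file"`)
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(z_mm = profile$z_mm, mA = profile$ma),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("z_mm", "mA") %in% names(df))) {
    stop("malformed profile CSV: need columns z_mm, mA in ", path)
  }
  if (nrow(df) == 0) stop("empty-profile error: no rows in ", path)
  if (any(!is.finite(df$mA)) || any(df$mA <= 0)) {
    stop("validation error: non-positive tube current in ", path)
  }
  tube_current_profile(df$z_mm, df$mA, provenance = "file")
}
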