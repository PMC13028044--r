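# Voxel Monte Carlo dose engine for helical CT.
#
# Photon transport uses delta (Woodcock) tracking through the voxel grid
# with photoelectric absorption and Klein-Nishina incoherent scattering in
# the kerma approximation: secondary-electron energy is deposited at the
# interaction site, and a photon falling below 10 keV is terminated with
# its residual energy deposited locally. Rayleigh scattering is omitted
# (small effect on absorbed dose at CT energies, large speed win). The
# bowtie filter enters as an emission weight, equivalent in expectation to
# explicit filter transport for primaries. Absolute dose is anchored by a
# free-in-air air-kerma calibration at the isocentre.

.KEV_TO_MGY_PER_G <- 1.602176634e-10

#' Helical scan protocol
#'
#' @param kvp tube potential
#' @param collimation_mm beam collimation at isocentre
#' @param pitch helical pitch; table increment per rotation is
#'   `collimation * pitch`
#' @param rotation_time_s rotation time
#' @param direction `"caudocranial"` (reference; table travels from lung
#'   base to apex) or `"craniocaudal"`
#' @param z_range_mm scan range `c(z_base, z_apex)` in phantom coordinates
#' @param offset_mm rotation-axis offset of the phantom `c(x, y)` in mm
#'   (|dx|, |dy| <= 100)
#' @param profile the `tube_current_profile` driving the scan
#' @return object of class `scan_protocol`
#' @export
scan_protocol <- function(kvp, collimation_mm, pitch, rotation_time_s,
                          direction = c("caudocranial", "craniocaudal"),
                          z_range_mm, offset_mm = c(x = 0, y = 0),
                          profile = NULL) {
  direction <- match.arg(direction)
  z_range_mm <- sort(as.numeric(z_range_mm))
  if (diff(z_range_mm) <= 0) stop("invalid scan range: start equals end")
  offset_mm <- c(x = unname(offset_mm[["x"]]), y = unname(offset_mm[["y"]]))
  if (any(abs(offset_mm) > 100)) {
    stop("invalid parameter: offsets beyond 100 mm exceed the gantry bore")
  }
  stopifnot(pitch > 0, collimation_mm > 0, rotation_time_s > 0)
  structure(list(kvp = kvp, collimation_mm = collimation_mm, pitch = pitch,
                 rotation_time_s = rotation_time_s, direction = direction,
                 z_range_mm = z_range_mm, offset_mm = offset_mm,
                 profile = profile),
            class = "scan_protocol")
}

#' Protocol for a scanner and phantom
#'
#' Convenience constructor: scan range from the phantom's lung apex/base,
#' kVp from the BMI class, geometry from the scanner.
#'
#' @param scanner a [scanner_model()]
#' @param phantom a `voxel_phantom`
#' @param direction scan direction
#' @param offset_mm phantom off-centring `c(x, y)` mm
#' @param profile tube current profile
#' @return a [scan_protocol()]
#' @export
protocol_for <- function(scanner, phantom,
                         direction = "caudocranial",
                         offset_mm = c(x = 0, y = 0), profile = NULL) {
  scan_protocol(kvp = kvp_for_bmi(phantom$bmi_class),
                collimation_mm = scanner$collimation_mm,
                pitch = scanner$pitch,
                rotation_time_s = scanner$rotation_time_s,
                direction = direction,
                z_range_mm = c(phantom$z_base_mm, phantom$z_apex_mm),
                offset_mm = offset_mm, profile = profile)
}

# per-material mass coefficient matrices on the integer energy grid,
# restricted to the phantom material codes (air, lung, adipose, soft, bone)
.engine_coefs <- function(materials) {
  mats <- names(.MATERIAL_CODES)
  list(pe = materials$mu_pe[, mats, drop = FALSE],
       inc = materials$mu_incoherent[, mats, drop = FALSE],
       density = unname(materials$density[mats]),
       e0 = as.integer(materials$energy_kev[1]),
       energy = as.integer(materials$energy_kev))
}

.spectrum_tables <- function(spectrum) {
  list(e = as.integer(spectrum$energy_kev),
       cdf = cumsum(spectrum$fluence) / sum(spectrum$fluence))
}

.scanner_spectrum <- function(scanner, kvp) {
  s <- scanner$spectra[[as.character(kvp)]]
  if (is.null(s)) s <- build_spectrum(kvp, 4)
  s
}

# bowtie mass attenuation per mm on the engine energy grid
.bowtie_mu_grid <- function(scanner, materials) {
  linear_atten_mm(materials, scanner$bowtie$material, materials$energy_kev)
}

#' Simulate a helical CT scan
#'
#' Transports `n_photons` photons along the helical source path (table
#' increment per rotation = collimation x pitch), with emission z positions
#' importance-sampled proportional to the tube current profile, fan and
#' cone angles sampled within the collimation, the bowtie applied as an
#' emission weight, and energies drawn from the scanner spectrum. Energy
#' deposits are converted to absorbed dose through voxel mass and scaled to
#' absolute mGy with the free-in-air kerma calibration and the protocol's
#' total mAs.
#'
#' @param phantom a `voxel_phantom`
#' @param protocol a [scan_protocol()] (must carry a profile covering the
#'   scan range)
#' @param scanner a [scanner_model()]
#' @param n_photons number of photon histories (>= 1e4)
#' @param seed RNG seed (mandatory for reproducibility)
#' @param scatter logical; FALSE treats every interaction as absorption
#'   (primary-only mode for analytic benchmarks)
#' @param bowtie logical; include the bowtie emission weight
#' @param fixed_theta if non-NULL, hold the gantry at this angle (rad)
#'   instead of rotating (benchmark mode)
#' @param calibration optional precomputed [calibrate_output()] factor
#' @param materials material table
#' @return object of class `dose_map`: `dose_mgy` array aligned to the
#'   phantom grid, `n_photons`, `seed`, `calibration_mgy_per_photon_mas`,
#'   `total_mas`, `emitted_kev`, `deposited_kev`, `batch_totals_kev`
#' @export
simulate_scan <- function(phantom, protocol, scanner, n_photons = 2e5,
                          seed = 1, scatter = TRUE, bowtie = TRUE,
                          fixed_theta = NULL, calibration = NULL,
                          materials = default_materials()) {
  if (n_photons < 1e4) stop("invalid parameter: n_photons must be >= 1e4")
  profile <- protocol$profile
  if (is.null(profile)) stop("coverage error: protocol carries no profile")
  zr <- protocol$z_range_mm
  tol <- protocol$collimation_mm
  if (min(profile$z_mm) > zr[1] + tol || max(profile$z_mm) < zr[2] - tol) {
    stop("coverage error: profile z range [", min(profile$z_mm), ", ",
         max(profile$z_mm), "] does not cover the scan range [",
         zr[1], ", ", zr[2], "]")
  }
  coefs <- .engine_coefs(materials)
  spec <- .scanner_spectrum(scanner, protocol$kvp)
  st <- .spectrum_tables(spec)
  # importance-sampling table over table positions
  zfine <- seq(zr[1], zr[2], by = 1)
  wfine <- stats::approx(profile$z_mm, profile$ma, xout = zfine, rule = 2)$y
  zcdf <- cumsum(wfine); zcdf <- zcdf / zcdf[length(zcdf)]
  # gantry angle is coupled to table position from the caudal scan edge for
  # either direction: the angular phase at a given anatomy is arbitrary on a
  # real scanner, and anchoring it makes direction comparisons isolate the
  # tube-current behaviour instead of the start-angle phase
  z_start <- zr[1]
  feed <- protocol$collimation_mm * protocol$pitch
  origin <- c(phantom$origin_mm[["z"]],
              phantom$origin_mm[["y"]] + protocol$offset_mm[["y"]],
              phantom$origin_mm[["x"]] + protocol$offset_mm[["x"]])
  # majorant must bound the actual voxel densities
  dens_max <- vapply(seq_along(coefs$density) - 1L, function(code) {
    sel <- phantom$material == code
    if (any(sel)) max(phantom$density[sel]) else coefs$density[code + 1L]
  }, numeric(1))
  res <- cpp_simulate_scan(
    as.numeric(phantom$density), as.integer(phantom$material),
    phantom$shape, as.numeric(phantom$spacing_mm), as.numeric(origin),
    coefs$pe, coefs$inc, dens_max, coefs$e0,
    st$e, st$cdf, zfine, zcdf,
    sid = scanner$sid_mm, gamma_max = scanner$fan_half_angle_rad,
    collimation = protocol$collimation_mm, feed = feed,
    z_start = z_start, theta0 = 0,
    bowtie_tmax = if (bowtie) scanner$bowtie$t_max_mm else 0,
    bowtie_mu = .bowtie_mu_grid(scanner, materials),
    bowtie_on = bowtie, scatter_on = scatter,
    fixed_angle = !is.null(fixed_theta),
    fixed_theta = if (is.null(fixed_theta)) 0 else fixed_theta,
    n_photons = as.integer(n_photons), n_batches = 8L,
    seed = as.integer(seed))
  voxel_cm3 <- prod(phantom$spacing_mm) / 1000
  mass_g <- phantom$density * voxel_cm3
  if (any(mass_g < 0)) stop("internal error: negative voxel mass")
  dose_per_photon <- array(0, dim = phantom$shape)
  pos <- mass_g > 0
  dose_per_photon[pos] <- res$edep[pos] / mass_g[pos] * .KEV_TO_MGY_PER_G /
    n_photons
  if (is.null(calibration)) {
    calibration <- calibrate_output(scanner, protocol$kvp,
                                    materials = materials)
  }
  # total mAs: integral of mA over time; table speed = feed / rotation time
  total_mas <- sum(wfine) * 1 * protocol$rotation_time_s / feed
  dose <- dose_per_photon * calibration * total_mas
  structure(list(dose_mgy = dose, n_photons = n_photons, seed = seed,
                 calibration_mgy_per_photon_mas = calibration,
                 total_mas = total_mas,
                 emitted_kev = res$emitted_kev,
                 deposited_kev = res$deposited_kev,
                 batch_totals_kev = res$batch_total,
                 spacing_mm = phantom$spacing_mm,
                 shape = phantom$shape),
            class = "dose_map")
}

#' Free-in-air air kerma per emitted photon
#'
#' Scores kerma in a small disc on the central axis with no phantom
#' present, bowtie included (central-ray thickness on axis). Used for
#' output calibration and for the inverse-square benchmark.
#'
#' @param scanner a [scanner_model()]
#' @param kvp tube potential
#' @param distance_from_source_mm scoring distance from the focal spot
#' @param n_photons photon histories
#' @param seed RNG seed
#' @param r_mm scoring disc radius
#' @param bowtie include the bowtie weight
#' @param materials material table
#' @return list with `kerma_mgy_per_photon`, `batch` (per-batch estimates),
#'   `se` (standard error), `n_hits`
#' @export
free_in_air_kerma <- function(scanner, kvp, distance_from_source_mm,
                              n_photons = 2e5, seed = 1, r_mm = 5,
                              bowtie = TRUE,
                              materials = default_materials()) {
  stopifnot(distance_from_source_mm > 0)
  if (n_photons == 0) {
    return(list(kerma_mgy_per_photon = 0, batch = numeric(0), se = NA_real_,
                n_hits = 0L))
  }
  half_z <- scanner$collimation_mm / 2 *
    distance_from_source_mm / scanner$sid_mm
  if (half_z <= r_mm) {
    stop("geometry error: scoring volume larger than the beam at ",
         distance_from_source_mm, " mm")
  }
  spec <- .scanner_spectrum(scanner, kvp)
  st <- .spectrum_tables(spec)
  muen_air <- mass_atten(materials, "air", materials$energy_kev, "en")
  res <- cpp_air_kerma(st$e, st$cdf, muen_air,
                       as.integer(materials$energy_kev[1]),
                       gamma_max = scanner$fan_half_angle_rad,
                       collimation = scanner$collimation_mm,
                       sid = scanner$sid_mm,
                       d_mm = distance_from_source_mm, r_mm = r_mm,
                       bowtie_tmax = if (bowtie) scanner$bowtie$t_max_mm else 0,
                       bowtie_mu = .bowtie_mu_grid(scanner, materials),
                       bowtie_on = bowtie,
                       n_photons = as.integer(n_photons),
                       n_batches = 8L, seed = as.integer(seed))
  b <- res$batch
  res$se <- stats::sd(b) / sqrt(length(b))
  res
}

.calibration_cache <- new.env(parent = emptyenv())

#' Output calibration factor
#'
#' Converts per-photon simulated dose to absolute dose per mAs:
#' `factor = nominal air kerma per mAs / simulated kerma per photon at the
#' isocentre`, i.e. the effective number of photon histories one mAs
#' represents. Cached per (scanner geometry, kVp, seed).
#'
#' @param scanner a [scanner_model()] declaring `output_mgy_per_100mas`
#' @param kvp tube potential
#' @param n_photons photon histories for the kerma estimate
#' @param seed seed of the calibration simulation
#' @param materials material table
#' @return scalar factor (photons per mAs)
#' @export
calibrate_output <- function(scanner, kvp, n_photons = 4e5, seed = 760313,
                             materials = default_materials()) {
  if (!as.character(kvp) %in% names(scanner$output_mgy_per_100mas)) {
    stop("configuration error: scanner declares no nominal output at ",
         kvp, " kVp")
  }
  nominal <- scanner$output_mgy_per_100mas[[as.character(kvp)]]
  key <- paste(scanner$sid_mm, scanner$fan_half_angle_rad,
               scanner$collimation_mm, scanner$bowtie$t_max_mm,
               kvp, n_photons, seed, sep = "|")
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  k <- free_in_air_kerma(scanner, kvp, scanner$sid_mm,
                         n_photons = n_photons, seed = seed,
                         materials = materials)
  fac <- (nominal / 100) / k$kerma_mgy_per_photon
  .calibration_cache[[key]] <- fac
  fac
}

#' Save / load a dose map
#'
#' NIfTI volume (mGy) plus a JSON sidecar with seed, photon count and
#' calibration; round trip is identity.
#'
#' @param dosemap a `dose_map`
#' @param dir output directory
#' @export
save_dosemap <- function(dosemap, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(aperm(dosemap$dose_mgy, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(dosemap$spacing_mm)
  RNifti::writeNifti(img, file.path(dir, "dose.nii.gz"))
  side <- list(n_photons = dosemap$n_photons, seed = dosemap$seed,
               calibration_mgy_per_photon_mas =
                 dosemap$calibration_mgy_per_photon_mas,
               total_mas = dosemap$total_mas,
               emitted_kev = dosemap$emitted_kev,
               deposited_kev = dosemap$deposited_kev,
               batch_totals_kev = dosemap$batch_totals_kev,
               spacing_mm = dosemap$spacing_mm, shape = dosemap$shape)
  jsonlite::write_json(side, file.path(dir, "dose.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_dosemap
#' @export
load_dosemap <- function(dir) {
  sidecar <- file.path(dir, "dose.json")
  if (!file.exists(sidecar)) stop("I/O error: missing sidecar ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  img <- RNifti::readNifti(file.path(dir, "dose.nii.gz"))
  dose <- aperm(as.array(img), c(3, 2, 1))
  structure(list(dose_mgy = dose, n_photons = side$n_photons,
                 seed = side$seed,
                 calibration_mgy_per_photon_mas =
                   side$calibration_mgy_per_photon_mas,
                 total_mas = side$total_mas,
                 emitted_kev = side$emitted_kev,
                 deposited_kev = side$deposited_kev,
                 batch_totals_kev = side$batch_totals_kev,
                 spacing_mm = side$spacing_mm, shape = side$shape),
            class = "dose_map")
}
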