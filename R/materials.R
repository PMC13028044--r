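# Materials, X-ray spectra, bowtie filtration and output calibration for a
# parametric CT scanner model.
#
# Photon interaction coefficients are generated from a closed-form
# cross-section model rather than shipped as data files:
#   - incoherent scattering: exact Klein-Nishina total cross-section per
#     electron, scaled by the material's electrons per gram (N_A * Z/A);
#   - photoelectric absorption: effective-Z power law
#       tau/rho = C * (Z/A) * Zeff^3.6 * E^-3.05  [cm^2/g, E in keV]
#     with C calibrated against the water photoelectric coefficient at
#     30 keV (0.135 cm^2/g). Rayleigh scattering is folded out (see docs).
# The model reproduces tabulated water/aluminium coefficients to within a
# few percent over the 10-150 keV CT range, which is the band this package
# simulates, and keeps every coefficient analytic and testable.

#' @useDynLib atcmdose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.ELECTRON_REST_KEV <- 510.99895
.RE2_CM2 <- 7.940787e-26     # classical electron radius squared, cm^2
.AVOGADRO <- 6.02214076e23
.PE_CAL_C <- 5.736            # photoelectric power-law constant (see header)

# Elemental composition summary per material: mass density [g/cm^3],
# electrons-per-mass ratio Z/A, effective atomic number.
.MATERIAL_PROPS <- data.frame(
  material = c("air", "lung", "adipose", "soft", "bone", "aluminium", "pmma"),
  density  = c(0.0012047, 0.26, 0.95, 1.00, 1.85, 2.699, 1.19),
  z_over_a = c(0.49919, 0.55048, 0.55579, 0.55509, 0.51478, 0.48181, 0.53937),
  z_eff    = c(7.64, 7.42, 6.33, 7.42, 13.8, 13.0, 6.47),
  stringsAsFactors = FALSE
)

#' Total Klein-Nishina cross-section per electron
#'
#' Closed-form integral of the Klein-Nishina differential cross-section over
#' all scattering angles, in cm^2 per electron.
#'
#' @param energy_kev photon energy in keV (vectorised)
#' @return cross-section in cm^2
#' @keywords internal
klein_nishina_total <- function(energy_kev) {
  k <- energy_kev / .ELECTRON_REST_KEV
  2 * pi * .RE2_CM2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
      log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
  )
}

# Mean fraction of photon energy transferred to the electron in an
# incoherent scatter, from numerical integration of the Klein-Nishina
# differential cross-section (used for the energy-absorption coefficient).
.kn_transfer_fraction <- function(energy_kev) {
  k <- energy_kev / .ELECTRON_REST_KEV
  mu <- seq(-1, 1, length.out = 2001)  # cos(theta) grid
  vapply(k, function(kk) {
    ratio <- 1 / (1 + kk * (1 - mu))   # E'/E
    dsig <- ratio^2 * (ratio + 1 / ratio - (1 - mu^2))
    sum(dsig * (1 - ratio)) / sum(dsig)
  }, numeric(1))
}

#' Build the material interaction table
#'
#' Returns mass attenuation and mass energy-absorption coefficients for the
#' materials used by the phantom and scanner models (air, lung, adipose,
#' soft tissue/water, bone, aluminium, PMMA) on a 1 keV energy grid spanning
#' 10-150 keV.
#'
#' @param energy_kev energy grid in keV (default `10:150`)
#' @return object of class `material_table`: list with `energy_kev`,
#'   `materials` (character), `density` (named numeric, g/cm^3) and matrices
#'   `mu_pe`, `mu_incoherent`, `mu_total`, `mu_en` (cm^2/g, energy x material)
#' @examples
#' mt <- material_table()
#' mass_atten(mt, "soft", 60)   # total mass attenuation of soft tissue
#' @export
material_table <- function(energy_kev = 10:150) {
  stopifnot(all(diff(energy_kev) > 0), min(energy_kev) <= 10,
            max(energy_kev) >= 150)
  props <- .MATERIAL_PROPS
  ne <- length(energy_kev)
  nm <- nrow(props)
  sig_kn <- klein_nishina_total(energy_kev)
  f_tr <- .kn_transfer_fraction(energy_kev)
  mu_incoh <- outer(sig_kn, .AVOGADRO * props$z_over_a)
  mu_pe <- outer(energy_kev^(-3.05), .PE_CAL_C * props$z_over_a * props$z_eff^3.6)
  mu_total <- mu_pe + mu_incoh
  mu_en <- mu_pe + mu_incoh * f_tr
  dimnames(mu_pe) <- dimnames(mu_incoh) <- dimnames(mu_total) <-
    dimnames(mu_en) <- list(NULL, props$material)
  structure(list(
    energy_kev = as.numeric(energy_kev),
    materials = props$material,
    density = stats::setNames(props$density, props$material),
    mu_pe = mu_pe, mu_incoherent = mu_incoh, mu_total = mu_total,
    mu_en = mu_en
  ), class = "material_table")
}

# Memoised default table: all coefficients are deterministic.
.materials_cache <- new.env(parent = emptyenv())

#' @rdname material_table
#' @export
default_materials <- function() {
  if (is.null(.materials_cache$mt)) .materials_cache$mt <- material_table()
  .materials_cache$mt
}

#' Interpolate a mass coefficient for a material
#'
#' Log-log interpolation on the table's energy grid.
#'
#' @param materials a [material_table()]
#' @param material material id
#' @param energy_kev energies (vectorised)
#' @param kind one of `"total"`, `"pe"`, `"incoherent"`, `"en"`
#' @return mass coefficient(s) in cm^2/g
#' @export
mass_atten <- function(materials, material, energy_kev,
                       kind = c("total", "pe", "incoherent", "en")) {
  kind <- match.arg(kind)
  col <- switch(kind, total = materials$mu_total, pe = materials$mu_pe,
                incoherent = materials$mu_incoherent, en = materials$mu_en)
  if (!material %in% materials$materials) {
    stop("unknown material: ", material)
  }
  y <- col[, material]
  if (any(energy_kev < min(materials$energy_kev) |
            energy_kev > max(materials$energy_kev))) {
    stop("energy outside table grid [", min(materials$energy_kev), ", ",
         max(materials$energy_kev), "] keV")
  }
  exp(stats::approx(log(materials$energy_kev), log(y),
                    xout = log(energy_kev))$y)
}

#' Linear attenuation coefficient per mm
#'
#' @inheritParams mass_atten
#' @return linear attenuation in 1/mm at the material's nominal density
#' @export
linear_atten_mm <- function(materials, material, energy_kev, kind = "total") {
  mass_atten(materials, material, energy_kev, kind) *
    materials$density[[material]] / 10
}

#' Serialise a material table to CSV
#'
#' Long format with columns `material`, `energy_keV`, `mu_pe`,
#' `mu_incoherent`, `mu_total`, `mu_en` (all cm^2/g).
#'
#' @param materials a [material_table()]
#' @param path output file
#' @export
write_material_csv <- function(materials, path) {
  rows <- do.call(rbind, lapply(materials$materials, function(m) {
    data.frame(material = m, energy_keV = materials$energy_kev,
               mu_pe = materials$mu_pe[, m],
               mu_incoherent = materials$mu_incoherent[, m],
               mu_total = materials$mu_total[, m],
               mu_en = materials$mu_en[, m])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}


# ---- X-ray spectra ---------------------------------------------------------

#' Build a filtered bremsstrahlung spectrum
#'
#' Kramers-law bremsstrahlung shape (fluence proportional to `(kVp - E)/E`)
#' on 1 keV bins from 10 keV to the tube potential, hardened by the stated
#' aluminium filtration and normalised to unit total fluence. Characteristic
#' anode lines are not modelled; beam quality is controlled through the
#' half-value layer (see [tune_filtration_to_hvl()]), mirroring how scanner
#' spectra are matched to ionisation-chamber HVL measurements in practice.
#'
#' @param kvp tube potential in kV (60-150)
#' @param filtration_mm_al added aluminium filtration in mm (>= 0)
#' @param materials material table (for the aluminium coefficients)
#' @return object of class `spectrum`: list with `kvp`, `energy_kev` (bin
#'   centres), `fluence` (sums to 1), `filtration_mm_al`
#' @export
build_spectrum <- function(kvp, filtration_mm_al = 0,
                           materials = default_materials()) {
  if (!is.finite(kvp) || kvp < 60 || kvp > 150) {
    stop("invalid parameter: kvp must be in [60, 150], got ", kvp)
  }
  if (!is.finite(filtration_mm_al) || filtration_mm_al < 0) {
    stop("invalid parameter: filtration must be >= 0")
  }
  energy <- seq(10, floor(kvp))
  fl <- pmax(kvp - energy, 0) / energy
  if (filtration_mm_al > 0) {
    mu_al <- linear_atten_mm(materials, "aluminium", energy)
    fl <- fl * exp(-mu_al * filtration_mm_al)
  }
  s <- sum(fl)
  if (s <= 0) stop("degenerate spectrum: zero total fluence")
  structure(list(kvp = kvp, energy_kev = energy, fluence = fl / s,
                 filtration_mm_al = filtration_mm_al),
            class = "spectrum")
}

#' Mean energy of a spectrum
#'
#' @param spectrum a [build_spectrum()] object
#' @param weighting `"fluence"` or `"kerma"` (air kerma weighted; used as
#'   the effective energy for single-energy ray marching)
#' @param materials material table
#' @return energy in keV
#' @export
spectrum_mean_energy <- function(spectrum, weighting = c("fluence", "kerma"),
                                 materials = default_materials()) {
  weighting <- match.arg(weighting)
  w <- spectrum$fluence
  if (weighting == "kerma") {
    w <- w * spectrum$energy_kev *
      mass_atten(materials, "air", spectrum$energy_kev, "en")
  }
  sum(w * spectrum$energy_kev) / sum(w)
}

#' Write / read a spectrum as CSV
#'
#' Columns `energy_keV`, `value` (relative fluence).
#' @param spectrum a spectrum object
#' @param path file path
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(energy_keV = spectrum$energy_kev,
                              value = spectrum$fluence),
                   path, row.names = FALSE)
  invisible(path)
}

# Air-kerma-weighted transmission of a spectrum through x mm of aluminium,
# relative to the unattenuated beam.
.kerma_transmission <- function(spectrum, x_mm, materials) {
  e <- spectrum$energy_kev
  w <- spectrum$fluence * e * mass_atten(materials, "air", e, "en")
  mu <- linear_atten_mm(materials, "aluminium", e)
  sum(w * exp(-mu * x_mm)) / sum(w)
}

#' Half-value layer of a spectrum
#'
#' Aluminium thickness that halves the air kerma, the quantity an
#' ionisation-chamber HVL measurement reports. Kerma weighting (not fluence
#' weighting) is used, and the solution is found by bisection to
#' `|K/K0 - 0.5| < 1e-6`.
#'
#' @param spectrum a [build_spectrum()] object
#' @param materials material table
#' @return HVL in mm Al
#' @export
compute_hvl <- function(spectrum, materials = default_materials()) {
  f <- function(x) .kerma_transmission(spectrum, x, materials) - 0.5
  lo <- 0; hi <- 1
  while (f(hi) > 0 && hi < 200) hi <- hi * 2
  if (f(hi) > 0) stop("numerical error: HVL bracket not found below 200 mm")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-6) return(mid)
    if (fm > 0) lo <- mid else hi <- mid
  }
  if (abs(f((lo + hi) / 2)) < 1e-6) return((lo + hi) / 2)
  stop("numerical error: HVL bisection did not converge in 200 iterations")
}

#' Tune added filtration to match a target half-value layer
#'
#' Emulates measurement-driven spectrum generation: the Kramers shape at
#' `kvp` is hardened with the aluminium filtration whose HVL matches the
#' target to within 0.01 mm. HVL is monotone in filtration, so bisection on
#' the filtration bracket [0, 20] mm is used.
#'
#' @param kvp tube potential in kV
#' @param target_hvl_mm target HVL in mm Al
#' @param materials material table
#' @return a spectrum whose [compute_hvl()] matches `target_hvl_mm`
#' @export
tune_filtration_to_hvl <- function(kvp, target_hvl_mm,
                                   materials = default_materials()) {
  hvl_at <- function(f) compute_hvl(build_spectrum(kvp, f, materials), materials)
  lo <- 0; hi <- 20
  h_lo <- hvl_at(lo); h_hi <- hvl_at(hi)
  if (target_hvl_mm < h_lo || target_hvl_mm > h_hi) {
    stop(sprintf(
      "unachievable target: HVL %.3f mm outside achievable bracket [%.3f, %.3f] mm for %g kVp",
      target_hvl_mm, h_lo, h_hi, kvp))
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    h <- hvl_at(mid)
    if (abs(h - target_hvl_mm) < 0.01) break
    if (h < target_hvl_mm) lo <- mid else hi <- mid
  }
  build_spectrum(kvp, mid, materials)
}


# ---- Bowtie filter ---------------------------------------------------------

#' Beam-shaping (bowtie) filter
#'
#' Parabolic aluminium-equivalent thickness profile
#' `t(gamma) = t_max * (gamma / gamma_max)^2`: thinnest on the central ray,
#' thickest at the fan periphery, matching intensity to the patient
#' thickness profile when the patient is centred.
#'
#' @param gamma_max_rad maximum fan half-angle in rad
#' @param t_max_mm filter thickness at the fan edge in mm
#' @param material filter material id (default aluminium)
#' @return object of class `bowtie_filter`
#' @export
bowtie_filter <- function(gamma_max_rad, t_max_mm, material = "aluminium") {
  stopifnot(gamma_max_rad > 0, t_max_mm >= 0)
  structure(list(gamma_max_rad = gamma_max_rad, t_max_mm = t_max_mm,
                 material = material),
            class = "bowtie_filter")
}

#' Bowtie thickness at a fan angle
#' @param bowtie a [bowtie_filter()]
#' @param gamma_rad fan angle(s) in rad
#' @return thickness in mm
#' @export
bowtie_thickness <- function(bowtie, gamma_rad) {
  bowtie$t_max_mm * (gamma_rad / bowtie$gamma_max_rad)^2
}

#' Bowtie transmission
#'
#' Monoenergetic transmission `exp(-mu(E) * t(gamma))` through the filter.
#'
#' @param bowtie a [bowtie_filter()]
#' @param gamma_rad fan angle in rad (|gamma| <= fan half-angle)
#' @param energy_kev photon energy in keV
#' @param materials material table
#' @return transmission in (0, 1]
#' @export
bowtie_transmission <- function(bowtie, gamma_rad, energy_kev,
                                materials = default_materials()) {
  if (any(abs(gamma_rad) > bowtie$gamma_max_rad + 1e-12)) {
    stop("out of fan: |gamma| exceeds fan half-angle ", bowtie$gamma_max_rad)
  }
  mu <- linear_atten_mm(materials, bowtie$material, energy_kev)
  exp(-outer_drop(mu, bowtie_thickness(bowtie, gamma_rad)))
}

# elementwise product that recycles like base R but keeps scalars tidy
outer_drop <- function(a, b) a * b


# ---- Scanner model ---------------------------------------------------------

#' Parametric scanner model
#'
#' Bundles geometry, spectra, bowtie, output calibration and the ATCM
#' archetype into one object consumed by the localiser, ATCM and dose
#' engine modules.
#'
#' @param sid_mm focus-isocentre distance in mm
#' @param fan_half_angle_rad fan half-angle in rad
#' @param collimation_mm nominal beam collimation at isocentre in mm
#' @param pitch helical pitch (table travel per rotation / collimation)
#' @param rotation_time_s gantry rotation time in s
#' @param spectra named list of spectra keyed by kVp as character
#' @param bowtie a [bowtie_filter()]
#' @param output_mgy_per_100mas named numeric, air kerma free-in-air at the
#'   isocentre in mGy per 100 mAs, keyed by kVp
#' @param ma_limits tube current clamp (min, max) in mA
#' @param atcm_archetype one of `"prospective_magnification"`,
#'   `"online_lag"`, `"size_compensated"`
#' @param lateral_failure logical; archetype variant whose ATCM saturates at
#'   the mA ceiling under lateral off-centring beyond 2 cm
#' @return object of class `scanner_model`
#' @export
scanner_model <- function(sid_mm = 600,
                          fan_half_angle_rad = 0.45,
                          collimation_mm = 40,
                          pitch = 1.4,
                          rotation_time_s = 0.5,
                          spectra = NULL,
                          bowtie = bowtie_filter(0.45, 8),
                          output_mgy_per_100mas = c(`100` = 8, `120` = 12, `140` = 17),
                          ma_limits = c(10, 700),
                          atcm_archetype = "prospective_magnification",
                          lateral_failure = FALSE) {
  stopifnot(sid_mm > 0, fan_half_angle_rad > 0, collimation_mm > 0,
            rotation_time_s > 0, all(output_mgy_per_100mas > 0),
            length(ma_limits) == 2, ma_limits[1] > 0,
            ma_limits[2] > ma_limits[1])
  if (pitch < 0.5 || pitch > 2) {
    stop("invalid parameter: pitch ", pitch, " outside [0.5, 2]")
  }
  if (pitch < 1.0) warning("pitch ", pitch, " below 1.0: overlapping helix")
  if (is.null(spectra)) {
    spectra <- lapply(c(100, 120, 140), build_spectrum, filtration_mm_al = 4)
    names(spectra) <- c("100", "120", "140")
  }
  atcm_archetype <- match.arg(
    atcm_archetype,
    c("prospective_magnification", "online_lag", "size_compensated"))
  structure(list(
    sid_mm = sid_mm, fan_half_angle_rad = fan_half_angle_rad,
    collimation_mm = collimation_mm, pitch = pitch,
    rotation_time_s = rotation_time_s, spectra = spectra, bowtie = bowtie,
    output_mgy_per_100mas = output_mgy_per_100mas, ma_limits = ma_limits,
    atcm_archetype = atcm_archetype, lateral_failure = lateral_failure
  ), class = "scanner_model")
}

#' Scanner archetypes
#'
#' Four qualitative ATCM behaviour classes: a purely prospective system
#' driven by localiser magnification (`"prospective"`), a system with
#' online angular-lag feedback (`"online"`), a size-compensated system
#' robust to vertical off-centring (`"compensated"`), and the compensated
#' variant whose modulation saturates under lateral off-centring
#' (`"compensated_lateral_failure"`). These are modelling stances for
#' qualitative behaviour classes, not reconstructions of any vendor's
#' firmware.
#'
#' @param id archetype id
#' @return a [scanner_model()]
#' @export
scanner_archetype <- function(id = c("prospective", "online", "compensated",
                                     "compensated_lateral_failure")) {
  id <- match.arg(id)
  switch(id,
    prospective = scanner_model(collimation_mm = 80, pitch = 1.5,
                                atcm_archetype = "prospective_magnification"),
    online = scanner_model(pitch = 1.4, rotation_time_s = 0.6,
                           atcm_archetype = "online_lag"),
    compensated = scanner_model(pitch = 1.45,
                                atcm_archetype = "size_compensated"),
    compensated_lateral_failure =
      scanner_model(pitch = 1.35, atcm_archetype = "size_compensated",
                    lateral_failure = TRUE)
  )
}

#' Protocol kVp from BMI class
#'
#' Low-dose chest protocol rule: underweight models are scanned at 100 kVp,
#' normal and overweight at 120 kVp, obese at 140 kVp.
#'
#' @param bmi_class one of `"underweight"`, `"normal"`, `"overweight"`, `"obese"`
#' @return kVp
#' @export
kvp_for_bmi <- function(bmi_class) {
  unname(c(underweight = 100, normal = 120, overweight = 120,
           obese = 140)[bmi_class])
}
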