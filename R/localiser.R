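# Localiser (scout/topogram) acquisition as divergent fan-beam projection.
#
# The localiser is what the ATCM sees: per-slice apparent body width and
# water-equivalent path length, reconstructed at the isocentre plane. A
# patient displaced towards the X-ray source appears magnified by
# SID/(SID - d); this geometric magnification is the mechanism by which
# off-centring corrupts tube-current prediction. Projection is modelled
# slice-by-slice with a 2D fan per z (no cone divergence along z), on a
# virtual 1 mm-pitch detector at twice the source-isocentre distance.

.LOCALISER_ANGLES <- c("PA", "AP", "LAT_left", "LAT_right")

#' Projection geometry for a localiser acquisition
#'
#' @param angle one of `"PA"` (tube below the supine patient), `"AP"`
#'   (tube above), `"LAT_left"`, `"LAT_right"`
#' @param sid_mm source-isocentre distance in mm
#' @param offset_mm phantom displacement from the rotation axis,
#'   `c(x = dx, y = dy)` in mm; x+ is the patient's right, y- is a lowered
#'   table
#' @return object of class `projection_geometry`
#' @export
projection_geometry <- function(angle = "PA", sid_mm = 600,
                                offset_mm = c(x = 0, y = 0)) {
  angle <- match.arg(angle, .LOCALISER_ANGLES)
  stopifnot(sid_mm > 0)
  offset_mm <- c(x = unname(offset_mm[["x"]]), y = unname(offset_mm[["y"]]))
  structure(list(angle = angle, sid_mm = sid_mm, offset_mm = offset_mm),
            class = "projection_geometry")
}

# displacement of the phantom centre along the beam axis, positive towards
# the source
.towards_source <- function(geometry) {
  dx <- geometry$offset_mm[["x"]]; dy <- geometry$offset_mm[["y"]]
  switch(geometry$angle,
         PA = -dy, AP = dy, LAT_left = -dx, LAT_right = dx)
}

# source position (x, y) in the gantry frame
.source_position <- function(geometry) {
  s <- geometry$sid_mm
  switch(geometry$angle,
         PA = c(x = 0, y = -s), AP = c(x = 0, y = s),
         LAT_left = c(x = -s, y = 0), LAT_right = c(x = s, y = 0))
}

#' Geometric magnification factor
#'
#' For an object displaced a distance `d` along the beam axis towards the
#' source, structures at the object centre are projected onto the
#' isocentre plane enlarged by `SID / (SID - d)`; a centred object has
#' factor exactly 1.
#'
#' @param geometry a [projection_geometry()]
#' @return unitless magnification factor
#' @export
magnification_factor <- function(geometry) {
  d <- .towards_source(geometry)
  if (abs(d) >= geometry$sid_mm) {
    stop("geometry error: |displacement| ", abs(d),
         " mm not smaller than SID ", geometry$sid_mm, " mm")
  }
  geometry$sid_mm / (geometry$sid_mm - d)
}

#' Acquire a localiser image of a voxel phantom
#'
#' Casts divergent rays from the point source through every z slice to a
#' virtual detector (1 mm pitch at twice the SID), computes per-ray line
#' integrals of the linear attenuation at the localiser's effective energy
#' (kerma-weighted mean spectrum energy), and reduces each slice to (i) the
#' apparent body width at isocentre scale -- the detector extent of rays
#' whose water-equivalent path exceeds 5 mm, divided by the detector
#' magnification -- and (ii) the mean water-equivalent path length over
#' body rays.
#'
#' @param phantom a `voxel_phantom`
#' @param geometry a [projection_geometry()]
#' @param spectrum localiser spectrum (default 120 kVp, 4 mm Al)
#' @param materials material table
#' @param body_threshold_mm water-equivalent path defining a "body" ray
#' @return object of class `localiser_image`: `z_mm`, `width_mm`,
#'   `wepl_mm`, `geometry`, `kvp`, `e_eff_kev`
#' @export
project_localiser <- function(phantom, geometry,
                              spectrum = build_spectrum(120, 4),
                              materials = default_materials(),
                              body_threshold_mm = 5) {
  e_eff <- spectrum_mean_energy(spectrum, "kerma", materials)
  mu_vox <- .phantom_mu_per_mm(phantom, e_eff, materials)
  src <- .source_position(geometry)
  # origin shifted by the phantom offset: the phantom moves, the gantry
  # stays put
  origin <- c(phantom$origin_mm[["z"]],
              phantom$origin_mm[["y"]] + geometry$offset_mm[["y"]],
              phantom$origin_mm[["x"]] + geometry$offset_mm[["x"]])
  sid <- geometry$sid_mm
  half_extent <- max(abs(c(origin[2], origin[2] + (phantom$shape[2] - 1) *
                             phantom$spacing_mm[2],
                           origin[3], origin[3] + (phantom$shape[3] - 1) *
                             phantom$spacing_mm[3])))
  if (max(abs(geometry$offset_mm)) + half_extent >= sid) {
    stop("empty projection: phantom reaches the source plane; ",
         "no divergent projection exists")
  }
  # detector sized to cover the (possibly off-centred) phantom
  det_half <- 2.2 * half_extent + 20
  n_det <- 2L * as.integer(ceiling(det_half)) + 1L
  step <- min(phantom$spacing_mm) / 2
  li <- cpp_project(as.numeric(mu_vox), phantom$shape,
                    as.numeric(phantom$spacing_mm), as.numeric(origin),
                    src[["x"]], src[["y"]],
                    det_dist = 2 * sid, det_pitch = 1, n_det = n_det,
                    step = step)
  mu_w <- linear_atten_mm(materials, "soft", e_eff)
  wepl <- li / mu_w
  body <- wepl > body_threshold_mm
  width <- numeric(nrow(li))
  mean_wepl <- numeric(nrow(li))
  for (iz in seq_len(nrow(li))) {
    idx <- which(body[iz, ])
    if (length(idx) == 0) next
    width[iz] <- (max(idx) - min(idx) + 1) * 1 / 2  # detector magnification 2
    mean_wepl[iz] <- mean(wepl[iz, idx])
  }
  structure(list(z_mm = slice_z_mm(phantom), width_mm = width,
                 wepl_mm = mean_wepl, geometry = geometry,
                 kvp = spectrum$kvp, e_eff_kev = e_eff),
            class = "localiser_image")
}

# per-voxel linear attenuation (1/mm) at a single energy
.phantom_mu_per_mm <- function(phantom, energy_kev, materials) {
  codes <- phantom$material_codes
  lut <- numeric(max(codes) + 1)
  for (m in names(codes)) {
    lut[codes[[m]] + 1] <- mass_atten(materials, m, energy_kev, "total")
  }
  array(lut[phantom$material + 1L] * phantom$density / 10,
        dim = phantom$shape)
}

#' Water-equivalent diameter per slice
#'
#' Under the circular assumption the apparent body width doubles as the
#' water-equivalent diameter; otherwise the raw water-equivalent path
#' series is returned for elliptical combination by the ATCM module.
#'
#' @param image a `localiser_image`
#' @param assume_circular logical
#' @return numeric vector, mm per z
#' @export
water_equivalent_diameter <- function(image, assume_circular = TRUE) {
  if (length(image$z_mm) == 0) stop("empty localiser image")
  if (assume_circular) image$width_mm else image$wepl_mm
}

#' Serialise a localiser image to CSV
#'
#' Columns `z_mm`, `width_mm`, `wepl_mm`.
#' @param image a `localiser_image`
#' @param path output file
#' @export
write_localiser_csv <- function(image, path) {
  utils::write.csv(data.frame(z_mm = image$z_mm, width_mm = image$width_mm,
                              wepl_mm = image$wepl_mm),
                   path, row.names = FALSE)
  invisible(path)
}
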