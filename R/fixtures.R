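# Deterministic generators of small test inputs: minimal DICOM CT series
# with known per-slice tube currents, profile pairs with prescribed run
# structure, homogeneous water cylinders for analytic benchmarks, and
# paired samples with known effect size. Fixture generators are
# independent of the modules they exercise.

# ---- minimal DICOM writer --------------------------------------------------

# string value padded to even length (space for text VRs, NUL for UIDs)
.dicom_pad <- function(s, pad_byte = charToRaw(" ")) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, pad_byte)
  r
}

.dicom_element <- function(group, elem, vr, value_raw) {
  tag <- writeBin(c(as.integer(group), as.integer(elem)), raw(), size = 2,
                  endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  if (vr %in% long_vrs) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(tag, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

# single-frame CT instance with just enough structure for standard readers:
# preamble, DICM marker, file meta group (explicit VR LE transfer syntax),
# and the dataset attributes the profile extractor needs
.write_dicom_ct <- function(path, instance_number, slice_location_mm,
                            tube_current_ma, series_uid) {
  sop_class <- "1.2.840.10008.5.1.4.1.1.2"
  sop_uid <- paste0(series_uid, ".", instance_number)
  meta <- c(
    .dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dicom_element(0x0002, 0x0002, "UI", .dicom_pad(sop_class, as.raw(0))),
    .dicom_element(0x0002, 0x0003, "UI", .dicom_pad(sop_uid, as.raw(0))),
    .dicom_element(0x0002, 0x0010, "UI",
                   .dicom_pad("1.2.840.10008.1.2.1", as.raw(0)))
  )
  group_len <- .dicom_element(0x0002, 0x0000, "UL",
                              writeBin(length(meta), raw(), size = 4,
                                       endian = "little"))
  dataset <- c(
    .dicom_element(0x0008, 0x0016, "UI", .dicom_pad(sop_class, as.raw(0))),
    .dicom_element(0x0008, 0x0018, "UI", .dicom_pad(sop_uid, as.raw(0))),
    .dicom_element(0x0008, 0x0060, "CS", .dicom_pad("CT")),
    .dicom_element(0x0018, 0x1151, "IS",
                   .dicom_pad(format(as.integer(round(tube_current_ma))))),
    .dicom_element(0x0020, 0x000E, "UI", .dicom_pad(series_uid, as.raw(0))),
    .dicom_element(0x0020, 0x0013, "IS",
                   .dicom_pad(format(as.integer(instance_number)))),
    .dicom_element(0x0020, 0x1041, "DS",
                   .dicom_pad(format(slice_location_mm)))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta, dataset), con)
  invisible(path)
}

#' Write a minimal DICOM CT series fixture
#'
#' One single-frame CT instance per slice, carrying slice location and
#' tube current; instance numbers can be shuffled relative to z order to
#' exercise order-invariance of the extractor. No pixel data is written.
#'
#' @param dir output directory
#' @param ma_values per-slice tube currents in mA
#' @param z_mm per-slice locations in mm (default 5 mm steps from 0)
#' @param shuffle_order permutation of file naming (default identity)
#' @return the directory, invisibly
#' @export
make_dicom_series <- function(dir, ma_values,
                              z_mm = (seq_along(ma_values) - 1) * 5,
                              shuffle_order = seq_along(ma_values)) {
  stopifnot(length(ma_values) >= 1, all(ma_values > 0),
            length(z_mm) == length(ma_values))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series_uid <- "1.2.826.0.1.3680043.2.1125.1"
  for (i in seq_along(ma_values)) {
    k <- shuffle_order[i]
    .write_dicom_ct(file.path(dir, sprintf("slice%03d.dcm", i)),
                    instance_number = k, slice_location_mm = z_mm[k],
                    tube_current_ma = ma_values[k], series_uid = series_uid)
  }
  invisible(dir)
}

# ---- profile pairs ---------------------------------------------------------

#' Reference/deviating profile pair with prescribed run structure
#'
#' The reference profile is constant at `ref_ma`; the deviating profile
#' multiplies each run by its factor. Because the reference is constant
#' within each run, the per-run NRMSE equals |factor - 1| exactly, so the
#' translation factors are known by construction.
#'
#' @param runs list of `c(length, factor)` pairs
#' @param ref_ma reference current (default 100 mA)
#' @param dz_mm slice spacing
#' @return list with `ref` and `dev` tube current profiles and the exact
#'   per-slice factors
#' @export
make_profile_pair <- function(runs, ref_ma = 100, dz_mm = 5) {
  stopifnot(length(runs) >= 1)
  lens <- vapply(runs, `[`, numeric(1), 1)
  facs <- vapply(runs, `[`, numeric(1), 2)
  if (any(facs <= 0)) stop("non-positive factor in run structure")
  n <- sum(lens)
  z <- (seq_len(n) - 1) * dz_mm
  f <- rep(facs, lens)
  list(ref = tube_current_profile(z, rep(ref_ma, n)),
       dev = tube_current_profile(z, ref_ma * f),
       factors = f)
}

# ---- water cylinder phantom ------------------------------------------------

#' Homogeneous water cylinder phantom
#'
#' A z-symmetric cylinder of soft tissue (water-equivalent) in air, for
#' analytic benchmarks: Beer-Lambert depth dose, magnification of a known
#' diameter, direction-reversal symmetry.
#'
#' @param diameter_mm cylinder diameter
#' @param length_mm cylinder length along z
#' @param spacing_mm isotropic voxel spacing
#' @param margin_mm air margin around the cylinder
#' @return a `voxel_phantom` (organ masks empty; scan range spans the
#'   cylinder)
#' @export
water_cylinder_phantom <- function(diameter_mm = 300, length_mm = 300,
                                   spacing_mm = 5, margin_mm = 40) {
  r <- diameter_mm / 2
  nxy <- 2 * ceiling((r + margin_mm) / spacing_mm) + 1
  nz <- ceiling(length_mm / spacing_mm)
  shape <- c(nz, nxy, nxy)
  ys <- (seq_len(nxy) - (nxy + 1) / 2) * spacing_mm
  Y <- matrix(ys, nxy, nxy)
  X <- t(Y)
  disc <- X^2 + Y^2 <= r^2
  material <- array(.MATERIAL_CODES[["air"]], dim = shape)
  for (iz in seq_len(nz)) material[iz, , ][disc] <- .MATERIAL_CODES[["soft"]]
  dens_lut <- default_materials()$density[names(.MATERIAL_CODES)]
  density <- array(dens_lut[material + 1L], dim = shape)
  structure(list(
    shape = as.integer(shape),
    spacing_mm = rep(spacing_mm, 3),
    origin_mm = c(z = 0, y = ys[1], x = ys[1]),
    density = density, material = material,
    masks = list(),
    sex = "male", bmi_class = "normal",
    z_apex_mm = (nz - 1) * spacing_mm, z_base_mm = 0,
    seed = 0L, material_codes = .MATERIAL_CODES
  ), class = "voxel_phantom")
}

# ---- paired samples --------------------------------------------------------

#' Paired samples with known effect size
#'
#' `y = x + delta + noise`, noise ~ Normal(0, sigma^2), for exercising the
#' paired t, Bland-Altman and type-I-error simulations. Uses a local RNG
#' stream so the global `.Random.seed` is untouched.
#'
#' @param delta true paired effect
#' @param sigma noise SD (> 0)
#' @param n number of pairs (>= 3)
#' @param seed integer seed
#' @return list with `x`, `y`
#' @export
make_stats_pairs <- function(delta, sigma, n, seed) {
  stopifnot(n >= 3, sigma > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  x <- stats::rnorm(n, mean = 50, sd = 10)
  y <- x + delta + stats::rnorm(n, sd = sigma)
  list(x = x, y = y)
}
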