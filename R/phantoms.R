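# Synthetic anthropomorphic voxel phantoms.
#
# The cohort emulates a chest-CT study population: equal numbers of male and
# female models, four BMI classes per sex. Anatomy is parametric (stacked
# elliptical torso cross-sections with embedded ellipsoidal organs), not
# image-derived: the mechanisms this package studies -- attenuation profiles
# along z, localiser magnification, organ position relative to the scan
# range -- survive that abstraction, and the geometry is fully reproducible
# from a seed.
#
# Grid convention: arrays are indexed [z, y, x]; z+ cranial, y+ anterior
# (supine patient, towards the ceiling), x+ the patient's right. World
# coordinates are voxel centres in mm; x and y are centred on the phantom
# axis, z runs from 0 at the caudal face upward.

.MATERIAL_CODES <- c(air = 0L, lung = 1L, adipose = 2L, soft = 3L, bone = 4L)

# fractional z landmarks of the torso model (fraction of grid height)
.Z_LANDMARKS <- list(
  neck_lo = 0.88, lung_apex = 0.84, lung_base = 0.40,
  heart_lo = 0.46, heart_hi = 0.66, liver_lo = 0.14, liver_hi = 0.48,
  breast_lo = 0.46, breast_hi = 0.62, thyroid_lo = 0.885, thyroid_hi = 0.94
)

# lateral/AP torso semi-axis scaling per BMI class
.BMI_SCALE <- c(underweight = 0.82, normal = 1.00, overweight = 1.15,
                obese = 1.32)

.BMI_CLASSES <- names(.BMI_SCALE)

#' Generate a synthetic voxel phantom
#'
#' Builds a torso of stacked elliptical cross-sections with a subcutaneous
#' adipose layer, lungs, heart, liver, thyroid, spine and (for female
#' models) breasts. The torso tapers from a narrow neck to its widest
#' section in the upper abdomen; lateral and anteroposterior axes scale
#' with the BMI class. Organ semi-axes receive a small seeded jitter so
#' that every model in a cohort is anatomically distinct. The scan range
#' (`z_apex`, `z_base`) spans the lungs; the thyroid sits above the cranial
#' scan edge and the liver extends caudal of the base, so both probe doses
#' to organs at or outside the border of the scanned region.
#'
#' @param sex `"male"` or `"female"`
#' @param bmi_class one of `"underweight"`, `"normal"`, `"overweight"`, `"obese"`
#' @param seed integer seed controlling anatomical jitter
#' @param shape grid shape `c(nz, ny, nx)` (default 96 x 72 x 72)
#' @param spacing_mm voxel spacing `c(dz, dy, dx)` in mm (default 5 mm isotropic)
#' @param jitter fractional jitter amplitude on organ semi-axes (default 0.08)
#' @return object of class `voxel_phantom`: list with `shape`, `spacing_mm`,
#'   `origin_mm`, `density` (g/cm^3 array), `material` (integer array, see
#'   `material_codes`), `masks` (named list of logical arrays), `sex`,
#'   `bmi_class`, `z_apex_mm`, `z_base_mm`, `seed`
#' @export
generate_phantom <- function(sex, bmi_class, seed,
                             shape = c(96, 72, 72),
                             spacing_mm = c(5, 5, 5),
                             jitter = 0.08) {
  if (!sex %in% c("male", "female")) {
    stop("invalid parameter: sex must be 'male' or 'female', got '", sex, "'")
  }
  if (!bmi_class %in% .BMI_CLASSES) {
    stop("invalid parameter: unknown BMI class '", bmi_class, "'")
  }
  if (any(shape < 32)) {
    stop("configuration error: resolution below 32 voxels per axis cannot ",
         "contain the organ set")
  }
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  dz <- spacing_mm[1]; dy <- spacing_mm[2]; dx <- spacing_mm[3]
  zs <- (seq_len(nz) - 1) * dz
  ys <- (seq_len(ny) - (ny + 1) / 2) * dy
  xs <- (seq_len(nx) - (nx + 1) / 2) * dx
  height <- (nz - 1) * dz

  rng <- .substream_rng(seed)
  jit <- function() 1 + jitter * (2 * rng() - 1)

  s <- .BMI_SCALE[[bmi_class]] * jit()
  sex_ap <- if (sex == "female") 0.97 else 1.0

  # torso taper along z: widest in the upper abdomen, narrowing to shoulders
  zf <- zs / height
  taper <- stats::approx(c(0, 0.25, 0.6, 0.84, 0.88, 1),
                         c(1.00, 1.06, 0.97, 0.90, 0.40, 0.36),
                         xout = zf)$y
  ax_z <- 128 * s * taper            # lateral semi-axis per slice, mm
  ay_z <- 92 * s * sex_ap * taper    # AP semi-axis per slice, mm
  # neck is near-circular rather than elliptical
  neck <- zf >= .Z_LANDMARKS$neck_lo
  ay_z[neck] <- ax_z[neck] * 0.92

  # coordinate arrays [z, y, x]
  Z <- array(zs, dim = c(nz, ny, nx))
  Y <- aperm(array(ys, dim = c(ny, nz, nx)), c(2, 1, 3))
  X <- aperm(array(xs, dim = c(nx, nz, ny)), c(2, 3, 1))
  AXZ <- array(ax_z, dim = c(nz, ny, nx))
  AYZ <- array(ay_z, dim = c(nz, ny, nx))

  body <- (X / AXZ)^2 + (Y / AYZ)^2 <= 1
  fat_mm <- c(underweight = 8, normal = 14, overweight = 24, obese = 38)[[bmi_class]]
  core <- (X / pmax(AXZ - fat_mm, 1))^2 + (Y / pmax(AYZ - fat_mm, 1))^2 <= 1

  material <- array(.MATERIAL_CODES[["air"]], dim = shape)
  material[body] <- .MATERIAL_CODES[["adipose"]]
  material[body & core] <- .MATERIAL_CODES[["soft"]]

  ell <- function(cx, cy, cz, ax, ay, az) {
    ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2 <= 1
  }
  zmm <- function(f) f * height
  lm <- .Z_LANDMARKS

  z_apex <- zmm(lm$lung_apex)
  z_base <- zmm(lm$lung_base)

  # thyroid: small, anterior, in the neck just above the lung apex
  thy_c <- zmm((lm$thyroid_lo + lm$thyroid_hi) / 2)
  thyroid <- ell(0, 22 * s, thy_c, 16 * s * jit(), 11 * s * jit(),
                 zmm((lm$thyroid_hi - lm$thyroid_lo) / 2))
  thyroid <- thyroid & body

  # heart: anterior mediastinum, slightly to the patient's left (-x)
  heart_c <- zmm((lm$heart_lo + lm$heart_hi) / 2)
  heart <- ell(-12 * s, 18 * s, heart_c, 42 * s * jit(), 38 * s * jit(),
               zmm((lm$heart_hi - lm$heart_lo) / 2) * jit())
  heart <- heart & body & !thyroid

  # lungs: left and right ellipsoids spanning the scan range
  lung_c <- (z_apex + z_base) / 2
  lung_az <- (z_apex - z_base) / 2
  lung_ax <- 44 * s * jit()
  lung_ay <- 62 * s * jit()
  lungs <- ell(64 * s, -4 * s, lung_c, lung_ax, lung_ay, lung_az) |
    ell(-64 * s, -4 * s, lung_c, lung_ax, lung_ay, lung_az)
  lungs <- lungs & body & !heart & !thyroid

  # liver: right upper abdomen, crossing the caudal scan edge
  liver_c <- zmm((lm$liver_lo + lm$liver_hi) / 2)
  liver <- ell(55 * s, 6 * s, liver_c, 62 * s * jit(), 55 * s * jit(),
               zmm((lm$liver_hi - lm$liver_lo) / 2))
  liver <- liver & body & !lungs & !heart

  masks <- list(lungs = lungs, heart = heart, liver = liver,
                thyroid = thyroid)

  # breasts: adipose ellipsoids on the anterior chest wall (female only)
  if (sex == "female") {
    br_c <- zmm((lm$breast_lo + lm$breast_hi) / 2)
    br_az <- zmm((lm$breast_hi - lm$breast_lo) / 2)
    ay_at <- 92 * s * sex_ap *
      stats::approx(zf, taper, xout = (lm$breast_lo + lm$breast_hi) / 2)$y
    breasts <- ell(52 * s, ay_at * 0.88, br_c, 38 * s * jit(),
                   30 * s * jit(), br_az) |
      ell(-52 * s, ay_at * 0.88, br_c, 38 * s * jit(), 30 * s * jit(), br_az)
    breasts <- breasts & !lungs & !heart & !liver & !thyroid
    masks$breasts <- breasts
    material[breasts] <- .MATERIAL_CODES[["adipose"]]
  } else {
    masks$breasts <- array(FALSE, dim = shape)
  }

  # spine: posterior bone column (kept out of the organ masks)
  spine <- (X / (16 * s))^2 + ((Y + 0.68 * AYZ) / (14 * s))^2 <= 1
  spine <- spine & body & !Reduce(`|`, masks)
  material[spine] <- .MATERIAL_CODES[["bone"]]

  material[masks$lungs] <- .MATERIAL_CODES[["lung"]]
  material[masks$heart] <- .MATERIAL_CODES[["soft"]]
  material[masks$liver] <- .MATERIAL_CODES[["soft"]]
  material[masks$thyroid] <- .MATERIAL_CODES[["soft"]]

  dens_lut <- default_materials()$density[names(.MATERIAL_CODES)]
  density <- array(dens_lut[material + 1L], dim = shape)

  structure(list(
    shape = as.integer(shape), spacing_mm = spacing_mm,
    origin_mm = c(z = 0, y = ys[1], x = xs[1]),
    density = density, material = material, masks = masks,
    sex = sex, bmi_class = bmi_class,
    z_apex_mm = z_apex, z_base_mm = z_base, seed = as.integer(seed),
    material_codes = .MATERIAL_CODES
  ), class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("voxel_phantom: %s, %s BMI, %d x %d x %d @ %g mm\n",
              x$sex, x$bmi_class, x$shape[1], x$shape[2], x$shape[3],
              x$spacing_mm[1]))
  cat(sprintf("  scan range z = [%.0f, %.0f] mm; organs: %s\n",
              x$z_base_mm, x$z_apex_mm,
              paste(names(x$masks)[vapply(x$masks, any, logical(1))],
                    collapse = ", ")))
  invisible(x)
}

# Small deterministic uniform generator (SplitMix64-style), independent of
# R's global RNG so phantom generation never perturbs .Random.seed.
.substream_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
}

#' Cohort specification
#'
#' @param per_cell models per (sex x BMI class) cell; the default 4 yields
#'   the standard 32-model cohort (16 per sex, 8 per BMI class)
#' @param master_seed master seed; per-model seeds are derived from it
#' @param shape,spacing_mm,jitter forwarded to [generate_phantom()]
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(per_cell = 4, master_seed = 1,
                        shape = c(96, 72, 72), spacing_mm = c(5, 5, 5),
                        jitter = 0.08) {
  stopifnot(per_cell >= 0)
  structure(list(per_cell = per_cell, master_seed = master_seed,
                 shape = shape, spacing_mm = spacing_mm, jitter = jitter),
            class = "cohort_spec")
}

#' Generate a phantom cohort
#'
#' Returns `per_cell` models for every (sex, BMI class) combination, with
#' per-model seeds derived deterministically from the master seed, so two
#' cohorts built from the same spec are voxel-identical.
#'
#' @param spec a [cohort_spec()]
#' @return named list of `voxel_phantom` objects; names like `"female_obese_2"`
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  out <- list()
  idx <- 0L
  for (sex in c("male", "female")) {
    for (bmi in .BMI_CLASSES) {
      for (k in seq_len(spec$per_cell)) {
        idx <- idx + 1L
        seed <- derive_seed(spec$master_seed, idx)
        id <- paste(sex, bmi, k, sep = "_")
        out[[id]] <- generate_phantom(sex, bmi, seed, spec$shape,
                                      spec$spacing_mm, spec$jitter)
      }
    }
  }
  out
}

#' Derive a 31-bit substream seed
#'
#' Deterministic integer hash of a master seed and one or more stream
#' labels, kept below 2^31 so it is always a valid R/engine seed.
#'
#' @param master master seed (integer)
#' @param ... integers or strings identifying the substream
#' @return integer in [1, 2^31 - 2]
#' @export
derive_seed <- function(master, ...) {
  h <- as.double(master %% 2147483647)
  for (part in list(...)) {
    if (is.character(part)) {
      part <- sum(utf8ToInt(part) * seq_along(utf8ToInt(part)))
    }
    h <- (h * 48271 + as.double(part) * 16807 + 1) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

#' Reference anthropomorphic phantom
#'
#' Fixed adult-male, normal-BMI phantom standing in for the physical
#' anthropomorphic phantom on which ATCM profiles are derived before being
#' translated onto the patient models. Repeated calls are bit-identical.
#'
#' @inheritParams generate_phantom
#' @return a `voxel_phantom`
#' @export
reference_phantom <- function(shape = c(96, 72, 72),
                              spacing_mm = c(5, 5, 5)) {
  generate_phantom("male", "normal", seed = 360360L, shape = shape,
                   spacing_mm = spacing_mm, jitter = 0.08)
}

#' Per-slice body cross-sectional area
#'
#' @param phantom a `voxel_phantom`
#' @return numeric vector, area in mm^2 per z slice
#' @export
body_area_per_slice <- function(phantom) {
  nonair <- phantom$material != phantom$material_codes[["air"]]
  apply(nonair, 1, sum) * phantom$spacing_mm[2] * phantom$spacing_mm[3]
}

#' World z coordinates of the slice centres
#' @param phantom a `voxel_phantom`
#' @return numeric vector in mm
#' @export
slice_z_mm <- function(phantom) {
  phantom$origin_mm[["z"]] + (seq_len(phantom$shape[1]) - 1) * phantom$spacing_mm[1]
}

# ---- persistence -----------------------------------------------------------

#' Save / load a voxel phantom
#'
#' Density, material and each organ mask are stored as NIfTI volumes next
#' to a JSON sidecar holding labels, spacing, scan range and seed;
#' `load_phantom(save_phantom(p, dir))` is voxel-identical to `p`.
#'
#' @param phantom a `voxel_phantom`
#' @param dir output directory (created if missing)
#' @return `save_phantom`: the directory, invisibly. `load_phantom`: the
#'   phantom.
#' @export
save_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pixdim <- rev(phantom$spacing_mm)  # NIfTI stores x,y,z order
  wr <- function(arr, name) {
    img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)) * 1)  # [x, y, z]
    RNifti::pixdim(img) <- pixdim
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(phantom$density, "density")
  wr(phantom$material, "material")
  for (m in names(phantom$masks)) wr(phantom$masks[[m]], paste0("mask_", m))
  side <- list(sex = phantom$sex, bmi_class = phantom$bmi_class,
               shape = phantom$shape, spacing_mm = phantom$spacing_mm,
               origin_mm = as.list(phantom$origin_mm),
               z_apex_mm = phantom$z_apex_mm, z_base_mm = phantom$z_base_mm,
               seed = phantom$seed, masks = names(phantom$masks),
               material_codes = as.list(phantom$material_codes))
  jsonlite::write_json(side, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_phantom
#' @export
load_phantom <- function(dir) {
  sidecar <- file.path(dir, "phantom.json")
  if (!file.exists(sidecar)) {
    stop("I/O error: missing sidecar file ", sidecar)
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  rd <- function(name) {
    f <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(f)) stop("I/O error: missing volume ", f)
    img <- RNifti::readNifti(f)
    aperm(as.array(img), c(3, 2, 1))  # back to [z, y, x]
  }
  density <- rd("density")
  material <- array(as.integer(round(rd("material"))), dim = side$shape)
  masks <- lapply(side$masks, function(m) rd(paste0("mask_", m)) > 0.5)
  names(masks) <- side$masks
  structure(list(
    shape = as.integer(side$shape), spacing_mm = side$spacing_mm,
    origin_mm = unlist(side$origin_mm),
    density = density, material = material, masks = masks,
    sex = side$sex, bmi_class = side$bmi_class,
    z_apex_mm = side$z_apex_mm, z_base_mm = side$z_base_mm,
    seed = as.integer(side$seed),
    material_codes = unlist(side$material_codes)
  ), class = "voxel_phantom")
}
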