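# shared fixtures for the test suite; everything is built in code

# small phantoms keep the per-test cost low; organ layout is unchanged
small_shape <- c(64, 48, 48)

fixture_env <- new.env(parent = emptyenv())

# memoised heavy objects (built once per test run)
fx <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

fx_cylinder <- function() fx("cyl300", function() water_cylinder_phantom(300))

fx_scanner <- function() fx("scanner", function() scanner_archetype("prospective"))

# synthetic localiser image with prescribed widths (bypasses projection)
synthetic_localiser <- function(width_mm, wepl_mm = width_mm * pi / 4,
                                angle = "PA", sid = 600,
                                offset = c(x = 0, y = 0)) {
  n <- length(width_mm)
  structure(list(z_mm = seq(0, by = 5, length.out = n),
                 width_mm = width_mm, wepl_mm = wepl_mm,
                 geometry = projection_geometry(angle, sid, offset),
                 kvp = 120, e_eff_kev = 47.4),
            class = "localiser_image")
}

# monoenergetic pseudo-spectrum (single 1 keV bin)
mono_spectrum <- function(energy_kev, kvp = 120) {
  structure(list(kvp = kvp, energy_kev = energy_kev, fluence = 1,
                 filtration_mm_al = 0),
            class = "spectrum")
}

# scanner with a narrow fan and no bowtie, for pencil-beam style benchmarks
benchmark_scanner <- function(energy_kev = 60) {
  scanner_model(fan_half_angle_rad = 0.05,
                bowtie = bowtie_filter(0.05, 0),
                spectra = list(`120` = mono_spectrum(energy_kev)))
}

flat_profile <- function(z0 = 0, z1 = 295, ma = 100) {
  tube_current_profile(c(z0, z1), c(ma, ma))
}
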