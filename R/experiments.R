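# Orchestration of the full deviation grid: localiser projection angles,
# scan directions, vertical and lateral off-centring, each preceded by a
# single PA or dual PA+LAT localiser, over a synthetic cohort and the
# scanner archetypes.
#
# The pipeline mirrors the two-stage experimental method: ATCM profiles
# are derived on the fixed reference phantom for the reference and every
# deviating setup, the deviation is summarised by per-run NRMSE factors
# and translated onto each voxel model's own reference profile, and the
# translated profile drives the Monte Carlo dose simulation of that model
# under the setup's geometry (offsets applied to both the localiser and
# the rotation axis; the patient does not move between scout and scan).

#' Experiment configuration
#'
#' The default grid is desk-scale: one model per (sex x BMI) cell (8
#' models), offsets 0/±2/±6 cm, 2e5 photons per simulation. The full
#' 32-model grid with all ±2/4/6 cm offsets is
#' `experiment_config(cohort = cohort_spec(per_cell = 4),
#' vertical_offsets_mm = c(-60, -40, -20, 20, 40, 60), ...)`.
#'
#' @param archetypes scanner archetype ids (see [scanner_archetype()])
#' @param cohort a [cohort_spec()]
#' @param localiser_angles deviating localiser sets compared against the
#'   PA reference
#' @param directions deviating scan directions (reference is caudocranial)
#' @param vertical_offsets_mm table-height deviations (y; negative = below
#'   isocentre)
#' @param lateral_offsets_mm lateral deviations (x; positive = patient's
#'   right)
#' @param pairings localiser pairings evaluated at each off-centre or
#'   direction setup
#' @param n_photons photon histories per simulation
#' @param master_seed master seed; per-(model, setup) seeds derive from it
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(archetypes = c("prospective", "online",
                                             "compensated",
                                             "compensated_lateral_failure"),
                              cohort = cohort_spec(per_cell = 1),
                              localiser_angles = c("AP", "LAT", "PA+LAT",
                                                   "AP+LAT"),
                              directions = "craniocaudal",
                              vertical_offsets_mm = c(-60, -20, 20, 60),
                              lateral_offsets_mm = c(-60, -20, 20, 60),
                              pairings = c("single", "dual"),
                              n_photons = 2e5,
                              master_seed = 1) {
  structure(list(archetypes = archetypes, cohort = cohort,
                 localiser_angles = localiser_angles,
                 directions = directions,
                 vertical_offsets_mm = vertical_offsets_mm,
                 lateral_offsets_mm = lateral_offsets_mm,
                 pairings = pairings, n_photons = n_photons,
                 master_seed = master_seed),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Maps a YAML document onto [experiment_config()]. Recognised keys
#' mirror the constructor arguments; `cohort:` takes `per_cell`,
#' `master_seed`, `shape`, `spacing_mm`, `jitter`. Unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file
#' @return an `experiment_config`
#' @export
experiment_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("archetypes", "cohort", "localiser_angles", "directions",
             "vertical_offsets_mm", "lateral_offsets_mm", "pairings",
             "n_photons", "master_seed")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_spec, y$cohort)
  do.call(experiment_config, y)
}

# enumerate the deviation setups; the reference setup is always first
setup_table <- function(config) {
  rows <- list(data.frame(setup = "reference", family = "reference",
                          localiser = "PA", direction = "caudocranial",
                          dx = 0, dy = 0, stringsAsFactors = FALSE))
  for (ang in config$localiser_angles) {
    rows[[length(rows) + 1]] <- data.frame(
      setup = paste0("loc_", gsub("\\+", "_", ang)), family = "localiser",
      localiser = ang, direction = "caudocranial", dx = 0, dy = 0)
  }
  for (dir in config$directions) {
    for (p in config$pairings) {
      rows[[length(rows) + 1]] <- data.frame(
        setup = paste0("dir_", substr(dir, 1, 2), "_", p),
        family = "direction",
        localiser = if (p == "single") "PA" else "PA+LAT",
        direction = dir, dx = 0, dy = 0)
    }
  }
  for (dy in config$vertical_offsets_mm) {
    for (p in config$pairings) {
      rows[[length(rows) + 1]] <- data.frame(
        setup = sprintf("y%+d_%s", dy, p), family = "vertical",
        localiser = if (p == "single") "PA" else "PA+LAT",
        direction = "caudocranial", dx = 0, dy = dy)
    }
  }
  for (dx in config$lateral_offsets_mm) {
    for (p in config$pairings) {
      rows[[length(rows) + 1]] <- data.frame(
        setup = sprintf("x%+d_%s", dx, p), family = "lateral",
        localiser = if (p == "single") "PA" else "PA+LAT",
        direction = "caudocranial", dx = dx, dy = 0)
    }
  }
  df <- do.call(rbind, rows)
  df$pairing <- ifelse(grepl("\\+", df$localiser), "dual", "single")
  df
}

# split "PA+LAT" etc. into projection angle labels
.parse_localiser <- function(spec) {
  parts <- strsplit(spec, "+", fixed = TRUE)[[1]]
  vapply(parts, function(p) switch(p, PA = "PA", AP = "AP",
                                   LAT = "LAT_left",
                                   stop("unknown localiser angle: ", p)),
         character(1))
}

# cached localiser acquisition
.localiser_for <- function(phantom, phantom_id, angle, dx, dy, scanner,
                           cache) {
  key <- paste(phantom_id, angle, dx, dy, sep = "|")
  if (is.null(cache[[key]])) {
    geom <- projection_geometry(angle, sid_mm = scanner$sid_mm,
                                offset_mm = c(x = dx, y = dy))
    cache[[key]] <- project_localiser(phantom, geom)
  }
  cache[[key]]
}

# predicted ATCM profile of `phantom` for one setup, restricted to the
# phantom's scan range; localiser images cached in `cache`
.setup_profile <- function(phantom, phantom_id, setup, scanner, model,
                           cache) {
  angles <- .parse_localiser(setup$localiser)
  imgs <- lapply(angles, function(a) {
    .localiser_for(phantom, phantom_id, a, setup$dx, setup$dy, scanner,
                   cache)
  })
  prof <- if (length(imgs) == 1) predict_profile(model, imgs[[1]])
          else predict_profile(model, imgs[[1]], imgs[[2]])
  keep <- prof$z_mm >= phantom$z_base_mm & prof$z_mm <= phantom$z_apex_mm
  tube_current_profile(prof$z_mm[keep], prof$ma[keep],
                       provenance = prof$provenance)
}

# simulate one (model, setup) combination and return its organ-dose rows
.simulate_setup <- function(phantom, model_id, setup, scanner, atcm,
                            profile, archetype, n_photons, seed,
                            calibration, frontal = NULL) {
  protocol <- protocol_for(scanner, phantom, direction = setup$direction,
                           offset_mm = c(x = setup$dx, y = setup$dy))
  prof <- profile
  if (atcm$archetype == "online_lag") {
    prof <- online_modulate(atcm, profile, phantom, protocol, scanner,
                            frontal = frontal)
  }
  protocol$profile <- prof
  dm <- simulate_scan(phantom, protocol, scanner, n_photons = n_photons,
                      seed = seed, calibration = calibration)
  od <- organ_dose(dm, phantom)
  od$model <- model_id
  od$archetype <- archetype
  od$setup <- setup$setup
  od$family <- setup$family
  od$pairing <- setup$pairing
  od$kvp <- protocol$kvp
  od$seed <- seed
  od
}

#' Run the reference setup over the cohort
#'
#' Per model: PA localiser, caudocranial helical scan at the BMI-mapped
#' kVp, centred; establishes the reference organ doses every deviation is
#' compared against.
#'
#' @param config an [experiment_config()]
#' @param archetype scanner archetype id
#' @param models optional pre-generated cohort (list of phantoms)
#' @return list with `organ_doses` (data frame) and `profiles` (per-model
#'   reference profiles)
#' @export
run_reference <- function(config, archetype = config$archetypes[1],
                          models = NULL) {
  scanner <- scanner_archetype(archetype)
  atcm <- atcm_model_for_scanner(scanner)
  if (is.null(models)) models <- generate_cohort(config$cohort)
  cache <- new.env(parent = emptyenv())
  setups <- setup_table(config)
  ref_setup <- setups[setups$setup == "reference", ]
  rows <- list(); profiles <- list()
  for (model_id in names(models)) {
    ph <- models[[model_id]]
    prof <- .setup_profile(ph, model_id, ref_setup, scanner, atcm, cache)
    profiles[[model_id]] <- prof
    seed <- derive_seed(config$master_seed, archetype, model_id, "reference")
    cal <- calibrate_output(scanner, kvp_for_bmi(ph$bmi_class))
    frontal <- if (atcm$archetype == "online_lag") {
      .localiser_for(ph, model_id, "PA", 0, 0, scanner, cache)
    }
    rows[[model_id]] <- .simulate_setup(ph, model_id, ref_setup, scanner,
                                        atcm, prof, archetype,
                                        config$n_photons, seed, cal,
                                        frontal = frontal)
  }
  list(organ_doses = do.call(rbind, rows), profiles = profiles)
}

#' Run the full deviation grid
#'
#' Executes every setup of the configuration for every archetype and
#' model: reference-phantom ATCM profiles for the setup and the reference,
#' NRMSE translation onto the model's reference profile, online
#' re-modulation where the archetype demands it, Monte Carlo simulation
#' with the setup's offsets applied to the rotation axis, organ-dose
#' extraction, relative dose differences against the model's own
#' reference, and the per-family statistics.
#'
#' @param config an [experiment_config()]
#' @return object of class `result_bundle`: `organ_doses`, `rel_diff`,
#'   `stats`, `setups`, `config`
#' @export
run_grid <- function(config = experiment_config()) {
  models <- generate_cohort(config$cohort)
  setups <- setup_table(config)
  refph <- reference_phantom()
  all_rows <- list()
  for (archetype in config$archetypes) {
    scanner <- scanner_archetype(archetype)
    atcm <- atcm_model_for_scanner(scanner)
    cache <- new.env(parent = emptyenv())
    ref <- run_reference(config, archetype, models = models)
    all_rows[[paste0(archetype, "_ref")]] <- ref$organ_doses
    refph_ref <- .setup_profile(refph, "refph",
                                setups[setups$setup == "reference", ],
                                scanner, atcm, cache)
    for (si in which(setups$setup != "reference")) {
      setup <- setups[si, ]
      refph_dev <- .setup_profile(refph, "refph", setup, scanner, atcm,
                                  cache)
      for (model_id in names(models)) {
        ph <- models[[model_id]]
        translated <- nrmse_translate(refph_ref, refph_dev,
                                      ref$profiles[[model_id]])
        seed <- derive_seed(config$master_seed, archetype, model_id,
                            setup$setup)
        cal <- calibrate_output(scanner, kvp_for_bmi(ph$bmi_class))
        frontal <- if (atcm$archetype == "online_lag") {
          .localiser_for(ph, model_id, "PA", setup$dx, setup$dy, scanner,
                         cache)
        }
        all_rows[[paste(archetype, model_id, setup$setup, sep = "~")]] <-
          .simulate_setup(ph, model_id, setup, scanner, atcm, translated,
                          archetype, config$n_photons, seed, cal,
                          frontal = frontal)
      }
    }
  }
  organ_doses <- do.call(rbind, all_rows)
  rownames(organ_doses) <- NULL
  rel_diff <- .relative_differences(organ_doses)
  stats <- .grid_statistics(organ_doses, rel_diff, setups)
  structure(list(organ_doses = organ_doses, rel_diff = rel_diff,
                 stats = stats, setups = setups, config = config),
            class = "result_bundle")
}

# Eq.-style relative differences of every deviating setup against the
# model's own reference, per archetype and organ
.relative_differences <- function(organ_doses) {
  ref <- organ_doses[organ_doses$setup == "reference",
                     c("model", "archetype", "organ", "dose_mgy")]
  names(ref)[names(ref) == "dose_mgy"] <- "dose_ref"
  dev <- organ_doses[organ_doses$setup != "reference", ]
  m <- merge(dev, ref, by = c("model", "archetype", "organ"))
  m$rel_diff_pct <- relative_difference(m$dose_mgy, m$dose_ref)
  m[order(m$archetype, m$setup, m$model, m$organ),
    c("model", "archetype", "setup", "family", "pairing", "organ",
      "dose_mgy", "dose_ref", "rel_diff_pct")]
}

# family statistics: RM-ANOVA + Dunnett for localiser and off-centring
# families, paired t for direction, Bland-Altman for single-vs-dual
.grid_statistics <- function(organ_doses, rel_diff, setups) {
  out <- list()
  for (arch in unique(organ_doses$archetype)) {
    oda <- organ_doses[organ_doses$archetype == arch, ]
    for (org in unique(oda$organ)) {
      od <- oda[oda$organ == org, ]
      wide <- function(setup_ids) {
        ids <- c("reference", setup_ids)
        mods <- Reduce(intersect,
                       lapply(ids, function(s) od$model[od$setup == s]))
        if (length(mods) < 3) return(NULL)
        mat <- sapply(ids, function(s) {
          od$dose_mgy[match(paste(mods, s), paste(od$model, od$setup))]
        })
        rownames(mat) <- mods
        mat
      }
      add_family <- function(family, pairing) {
        ids <- setups$setup[setups$family == family &
                              setups$pairing == pairing]
        ids <- intersect(ids, od$setup)
        if (length(ids) == 0) return()
        mat <- wide(ids)
        if (is.null(mat) || ncol(mat) < 2) return()
        res <- rm_anova_dunnett(mat, control = 1)
        out[[length(out) + 1]] <<- data.frame(
          archetype = arch, organ = org, family = family,
          pairing = pairing, test = "rm_anova_dunnett",
          comparison = res$comparisons$condition,
          statistic = res$comparisons$t, df = res$df2,
          p_adjusted = res$comparisons$p_adjusted, f_stat = res$F)
      }
      for (p in c("single", "dual")) {
        add_family("localiser", p)
        add_family("vertical", p)
        add_family("lateral", p)
        # direction: paired t against the reference
        ids <- setups$setup[setups$family == "direction" &
                              setups$pairing == p]
        ids <- intersect(ids, od$setup)
        for (id in ids) {
          mat <- wide(id)
          if (is.null(mat)) next
          tt <- paired_t(mat[, 2], mat[, 1])
          out[[length(out) + 1]] <- data.frame(
            archetype = arch, organ = org, family = "direction",
            pairing = p, test = "paired_t", comparison = id,
            statistic = tt$t, df = tt$df, p_adjusted = tt$p, f_stat = NA)
        }
      }
      # Bland-Altman single vs dual per matched deviation
      rda <- rel_diff[rel_diff$archetype == arch & rel_diff$organ == org, ]
      singles <- setups[setups$pairing == "single" &
                          setups$family %in% c("vertical", "lateral",
                                               "direction"), ]
      for (k in seq_len(nrow(singles))) {
        s_id <- singles$setup[k]
        d_id <- sub("single$", "dual", s_id)
        if (!d_id %in% rda$setup) next
        xs <- rda[rda$setup == s_id, c("model", "rel_diff_pct")]
        xd <- rda[rda$setup == d_id, c("model", "rel_diff_pct")]
        mods <- intersect(xs$model, xd$model)
        if (length(mods) < 2) next
        ba <- bland_altman(xs$rel_diff_pct[match(mods, xs$model)],
                           xd$rel_diff_pct[match(mods, xd$model)])
        out[[length(out) + 1]] <- data.frame(
          archetype = arch, organ = org, family = singles$family[k],
          pairing = "single_vs_dual", test = "bland_altman",
          comparison = sub("_single$", "", s_id), statistic = ba$bias,
          df = ba$n - 1, p_adjusted = ba$p_bias, f_stat = NA)
      }
    }
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise a result bundle
#'
#' Per (archetype, setup, organ): mean and SD of the relative dose
#' difference across models, in percent.
#'
#' @param bundle a `result_bundle` from [run_grid()]
#' @return data frame `archetype`, `setup`, `family`, `pairing`, `organ`,
#'   `n_models`, `mean_rel_diff_pct`, `sd_rel_diff_pct`
#' @export
summarize_grid <- function(bundle) {
  rd <- bundle$rel_diff
  agg <- stats::aggregate(rel_diff_pct ~ archetype + setup + family +
                            pairing + organ, data = rd,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = stats::sd(v)))
  out <- data.frame(agg[, c("archetype", "setup", "family", "pairing",
                            "organ")],
                    n_models = agg$rel_diff_pct[, "n"],
                    mean_rel_diff_pct = agg$rel_diff_pct[, "mean"],
                    sd_rel_diff_pct = agg$rel_diff_pct[, "sd"])
  out[order(out$archetype, out$family, out$setup, out$organ), ]
}

#' Write a result bundle to CSV files
#'
#' Writes `organ_doses.csv`, `relative_differences.csv`,
#' `stats_summary.csv`, `summary.csv` and a JSON manifest (config, setups
#' and an md5 of the organ-dose table) into a directory. Output is
#' byte-identical across reruns with the same config and master seed.
#'
#' @param bundle a `result_bundle`
#' @param dir output directory
#' @return the directory, invisibly
#' @export
write_result_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$organ_doses, file.path(dir, "organ_doses.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$rel_diff,
                   file.path(dir, "relative_differences.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$stats)) {
    utils::write.csv(bundle$stats, file.path(dir, "stats_summary.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(summarize_grid(bundle), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    archetypes = bundle$config$archetypes,
    master_seed = bundle$config$master_seed,
    n_photons = bundle$config$n_photons,
    n_models = length(unique(bundle$organ_doses$model)),
    setups = bundle$setups$setup,
    organ_doses_md5 = unname(tools::md5sum(file.path(dir,
                                                     "organ_doses.csv"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Plot a grid summary
#'
#' Mean relative dose difference per organ and setup for one archetype and
#' family, with model-to-model SD whiskers.
#'
#' @param bundle a `result_bundle`
#' @param archetype archetype to plot
#' @param family setup family to plot
#' @param file optional PNG path
#' @return the summary data frame used for the plot, invisibly
#' @export
plot_family <- function(bundle, archetype, family, file = NULL) {
  sm <- summarize_grid(bundle)
  sm <- sm[sm$archetype == archetype & sm$family == family, ]
  if (nrow(sm) == 0) stop("no rows for ", archetype, "/", family)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  setups <- unique(sm$setup)
  organs <- unique(sm$organ)
  x <- seq_along(setups)
  graphics::plot(NULL, xlim = range(x) + c(-0.5, 0.5),
                 ylim = range(c(sm$mean_rel_diff_pct - sm$sd_rel_diff_pct,
                                sm$mean_rel_diff_pct + sm$sd_rel_diff_pct,
                                0)),
                 xaxt = "n", xlab = "setup",
                 ylab = "mean relative dose difference (%)",
                 main = paste(archetype, family))
  graphics::axis(1, at = x, labels = setups, las = 2, cex.axis = 0.8)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  for (i in seq_along(organs)) {
    ss <- sm[sm$organ == organs[i], ]
    xi <- match(ss$setup, setups) + (i - (length(organs) + 1) / 2) * 0.1
    graphics::points(xi, ss$mean_rel_diff_pct, col = i, pch = 16)
    graphics::arrows(xi, ss$mean_rel_diff_pct - ss$sd_rel_diff_pct,
                     xi, ss$mean_rel_diff_pct + ss$sd_rel_diff_pct,
                     length = 0.02, angle = 90, code = 3, col = i)
  }
  graphics::legend("topright", legend = organs, col = seq_along(organs),
                   pch = 16, cex = 0.8)
  invisible(sm)
}
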