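# Organ dose extraction and the statistical comparisons between deviating
# setups and the reference scan: relative dose differences, paired t,
# one-way repeated-measures ANOVA with Dunnett many-to-one post hoc, and
# Bland-Altman agreement between single- and dual-localiser scenarios.

.ORGANS <- c("lungs", "heart", "breasts", "liver", "thyroid")

#' Mean organ doses from a dose map
#'
#' Overlays each organ mask on the 3D dose distribution and reports the
#' voxel-mean absorbed dose (masks are single-material, so mass weighting
#' would change nothing), plus the Monte Carlo standard error estimated as
#' the voxel-dose SD over the mask divided by sqrt(number of voxels).
#'
#' @param dosemap a `dose_map` aligned to the phantom grid
#' @param phantom the `voxel_phantom` providing the masks
#' @param organs organ names to extract (default: all present)
#' @return data frame with columns `organ`, `dose_mgy`, `n_voxels`,
#'   `se_mgy`; breast rows appear only for female models
#' @export
organ_dose <- function(dosemap, phantom, organs = .ORGANS) {
  if (!all(dosemap$shape == phantom$shape)) {
    stop("grid mismatch between dose map and phantom")
  }
  rows <- lapply(organs, function(org) {
    mask <- phantom$masks[[org]]
    if (is.null(mask) || !any(mask)) {
      if (org == "breasts" && phantom$sex == "male") return(NULL)
      stop("missing organ: mask '", org, "' is empty for this phantom")
    }
    d <- dosemap$dose_mgy[mask]
    data.frame(organ = org, dose_mgy = mean(d), n_voxels = length(d),
               se_mgy = stats::sd(d) / sqrt(length(d)))
  })
  do.call(rbind, rows)
}

#' Relative dose difference (percent)
#'
#' The symmetric relative difference between a deviating and a reference
#' organ dose,
#' `(dose_dev - dose_ref) / ((dose_dev + dose_ref) / 2) * 100`,
#' antisymmetric under swapping the arguments and bounded in (-200, 200)
#' for positive doses.
#'
#' @param dose_dev organ dose under the deviating setup, mGy
#' @param dose_ref organ dose under the reference setup, mGy
#' @return relative difference in percent (vectorised)
#' @export
relative_difference <- function(dose_dev, dose_ref) {
  if (any(dose_dev + dose_ref <= 0)) {
    stop("undefined ratio: dose_dev + dose_ref must be positive")
  }
  (dose_dev - dose_ref) / ((dose_dev + dose_ref) / 2) * 100
}

#' Paired t test
#'
#' Classical paired t on the per-model differences, two-sided.
#'
#' @param x,y paired per-model values (equal length >= 2)
#' @return list with `t`, `df`, `p`, `mean_diff`, and `degenerate` flag set
#'   when the differences have zero variance
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  d <- x - y
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0,
                  degenerate = FALSE))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (sd_d / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       mean_diff = mean(d), degenerate = FALSE)
}

#' One-way repeated-measures ANOVA with Dunnett post hoc
#'
#' F statistic from the subject-blocked one-way RM-ANOVA (condition sum of
#' squares over the subject-by-condition error), then Dunnett many-to-one
#' comparisons of every condition against the control, with adjusted p
#' values from the null distribution of the maximum absolute of the
#' correlated t statistics (equicorrelation 1/2), evaluated by seeded
#' Monte Carlo.
#'
#' @param data numeric matrix, rows = subjects (models), columns =
#'   conditions; complete design required
#' @param control control condition (column name or index)
#' @param n_draws Monte Carlo draws for the max-|t| null
#' @param mc_seed seed of the critical-value simulation (fixed by default
#'   so adjusted p values are reproducible)
#' @return list with `F`, `df1`, `df2`, `p_anova`, and data frame
#'   `comparisons` (`condition`, `mean_diff`, `t`, `p_adjusted`)
#' @export
rm_anova_dunnett <- function(data, control = 1, n_draws = 1e5,
                             mc_seed = 550657) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("incomplete design: missing cells")
  n <- nrow(data); k <- ncol(data)
  if (k < 2 || n < 3) stop("need >= 2 conditions and >= 3 subjects")
  if (is.character(control)) control <- match(control, colnames(data))
  cond <- factor(rep(seq_len(k), each = n))
  subj <- factor(rep(seq_len(n), k))
  y <- as.vector(data)
  fit <- stats::aov(y ~ cond + Error(subj))
  tab <- summary(fit)[["Error: Within"]][[1]]
  ms_cond <- tab["cond", "Mean Sq"]
  ms_err <- tab["Residuals", "Mean Sq"]
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  # guard against floating-point dust when condition means are identical
  scale_ms <- max(stats::var(y), .Machine$double.xmin)
  if (ms_cond < 1e-10 * scale_ms) ms_cond <- 0
  if (ms_err < 1e-10 * scale_ms) ms_err <- 0
  Fstat <- if (ms_err > 0) ms_cond / ms_err else if (ms_cond > 0) Inf else 0
  p_anova <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  se <- sqrt(2 * ms_err / n)
  others <- setdiff(seq_len(k), control)
  mean_diff <- colMeans(data)[others] - mean(data[, control])
  tvals <- if (se > 0) mean_diff / se else {
    ifelse(mean_diff == 0, 0, sign(mean_diff) * Inf)
  }
  # null of max |T| over the k-1 many-to-one comparisons: T_j = Z_j / S
  # with Z equicorrelated (rho = 1/2) standard normals and S^2 ~ chi2_df2/df2
  maxt <- .dunnett_maxt_null(k - 1, df2, n_draws, mc_seed)
  p_adj <- vapply(tvals, function(t) mean(maxt >= abs(t)), numeric(1))
  p_adj <- pmax(p_adj, 1 / n_draws)
  list(F = Fstat, df1 = df1, df2 = df2, p_anova = p_anova,
       comparisons = data.frame(
         condition = if (!is.null(colnames(data))) colnames(data)[others]
                     else as.character(others),
         mean_diff = unname(mean_diff), t = unname(tvals),
         p_adjusted = unname(p_adj)))
}

# draws of max_j |T_j| for the many-to-one comparison null; local RNG so
# the global .Random.seed is untouched
.dunnett_maxt_null <- function(m, df, n_draws, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  # Z_j = (W_j + W_0)/sqrt(2) with iid standard normals gives rho = 1/2
  w0 <- stats::rnorm(n_draws)
  mx <- rep(0, n_draws)
  for (j in seq_len(m)) {
    z <- (stats::rnorm(n_draws) + w0) / sqrt(2)
    mx <- pmax(mx, abs(z))
  }
  s <- sqrt(stats::rchisq(n_draws, df) / df)
  mx / s
}

#' Bland-Altman agreement analysis
#'
#' Agreement between the relative dose differences observed after a single
#' and after a dual localiser: bias = mean paired difference
#' (single - dual), limits of agreement = bias +/- 1.96 SD, and a
#' one-sample t for whether the bias differs from zero. A positive bias
#' means the quantity was higher in the single-localiser scenario.
#'
#' @param x_single per-model values from the single-localiser scenario (%)
#' @param x_dual per-model values from the dual-localiser scenario (%)
#' @return object of class `bland_altman`: `bias`, `sd`, `loa` (length-2),
#'   `n`, `t`, `p_bias`
#' @export
bland_altman <- function(x_single, x_dual) {
  if (length(x_single) != length(x_dual) || length(x_single) < 2) {
    stop("insufficient data: need >= 2 complete pairs")
  }
  d <- x_single - x_dual
  bias <- mean(d); s <- stats::sd(d); n <- length(d)
  tt <- if (s > 0) bias / (s / sqrt(n)) else if (bias == 0) 0 else sign(bias) * Inf
  p <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), n - 1)
  structure(list(bias = bias, sd = s, loa = c(bias - 1.96 * s, bias + 1.96 * s),
                 n = n, t = tt, p_bias = p),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f], n = %d, p(bias) = %.3g\n",
              x$bias, x$loa[1], x$loa[2], x$n, x$p_bias))
  invisible(x)
}

#' Normality diagnostics (non-gating)
#'
#' Shapiro-Wilk p value reported for transparency; nothing in the pipeline
#' is gated on it.
#'
#' @param x numeric vector
#' @return p value
#' @export
normality_diagnostic <- function(x) {
  if (length(unique(x)) < 3) return(NA_real_)
  stats::shapiro.test(x)$p.value
}
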