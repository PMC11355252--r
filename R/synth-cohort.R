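#' Published per-group summary statistics used to calibrate the generator
#'
#' Means and standard deviations of the continuous base features in the good
#' (A, n = 32) and poor (B, n = 11) 6-month prognosis groups of the source
#' cohort, as printed in the study's baseline table. Lengths are micrometres,
#' areas are pixels squared of the trimmed mask, BCVA is logMAR, axial length
#' millimetres, disease duration months.
#'
#' @return A data.frame with columns `feature`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`.
#' @export
cohort_reference_parameters <- function() {
  p <- rbind(
    c("Age", 65.59, 6.51, 67.18, 4.63),
    c("Preoperative BCVA", 0.46, 0.24, 0.81, 0.34),
    c("Axial length", 23.98, 1.38, 24.05, 1.56),
    c("Disease duration", 1.72, 2.05, 3.18, 3.46),
    c("BDM", 724.66, 189.13, 958.45, 399.37),
    c("Hole-min", 295.50, 107.49, 423.09, 175.49),
    c("OPL-DL", 465.09, 140.14, 492.36, 170.95),
    c("ELM-DL", 320.63, 120.25, 480.82, 221.77),
    c("EZ-DL", 359.00, 172.47, 517.09, 263.87),
    c("Green-sDL", 462.91, 134.37, 533.73, 148.32),
    c("ONL-DL", 313.28, 115.73, 434.09, 186.22),
    c("Sky blue-sDL", 297.13, 120.35, 458.27, 220.81),
    c("Blue-sDL", 372.25, 168.61, 530.82, 256.59),
    c("Area IRF", 1437.72, 910.70, 2240.36, 1653.83),
    c("Area-green", 7268.78, 1414.01, 7122.45, 1195.36),
    c("Area-yellow", 5263.59, 1220.27, 5068.27, 1463.88),
    c("Area-sky_blue", 1585.31, 327.78, 1560.64, 215.41),
    c("Area-blue", 1701.56, 417.81, 1744.73, 472.78)
  )
  out <- data.frame(feature = p[, 1],
                    mean_a = as.numeric(p[, 2]), sd_a = as.numeric(p[, 3]),
                    mean_b = as.numeric(p[, 4]), sd_b = as.numeric(p[, 5]))
  out
}

#' @describeIn cohort_reference_parameters printed SDs of the difference
#'   combination features, used to recover within-group correlations between
#'   their two base lengths.
#' @export
cohort_reference_difference_sds <- function() {
  d <- rbind(
    c("OPL-DL", "ONL-DL", 114.31, 46.37),
    c("ELM-DL", "ONL-DL", 42.69, 76.45),
    c("OPL-DL", "Green-sDL", 95.99, 55.85),
    c("ELM-DL", "Sky blue-sDL", 30.58, 22.67),
    c("EZ-DL", "Sky blue-sDL", 82.83, 51.32),
    c("EZ-DL", "Blue-sDL", 25.11, 22.21),
    c("BDM", "Blue-sDL", 127.58, 231.34),
    c("BDM", "Hole-min", 134.12, 250.01)
  )
  data.frame(x = d[, 1], y = d[, 2],
             sd_diff_a = as.numeric(d[, 3]), sd_diff_b = as.numeric(d[, 4]))
}

#' @describeIn cohort_reference_parameters per-group level probabilities of
#'   the categorical features, from the printed per-group counts. Where only
#'   one level's count is printed (ILM peeling), the remainder is split
#'   evenly over the other levels.
#' @export
cohort_reference_categorical_probs <- function() {
  list(
    "Sex" = list(A = c(10, 22) / 32, B = c(4, 7) / 11),
    "Method" = list(A = c(1, 31) / 32, B = c(0, 11) / 11),
    "Affected eye" = list(A = c(18, 14) / 32, B = c(6, 5) / 11),
    "Stage" = list(A = c(3, 24, 5) / 32, B = c(3, 7, 1) / 11),
    "ILM" = list(A = c(22, 5, 5) / 32, B = c(4, 3.5, 3.5) / 11),
    "VMT" = list(A = c(20, 12) / 32, B = c(6, 5) / 11),
    "PVD" = list(A = c(27, 5) / 32, B = c(10, 1) / 11)
  )
}

#' Within-group correlation implied by the SD of a difference feature
#'
#' If a cohort table reports standard deviations for two features X and Y and
#' for their difference X - Y within the same group, the within-group Pearson
#' correlation is identified by
#' Var(X - Y) = Var(X) + Var(Y) - 2 rho sd(X) sd(Y), i.e.
#' rho = (sd_x^2 + sd_y^2 - sd_diff^2) / (2 sd_x sd_y).
#'
#' @param sd_x,sd_y standard deviations of the two features (> 0).
#' @param sd_diff standard deviation of their difference.
#' @return The implied correlation in `[-1, 1]`.
#' @export
#' @examples
#' derive_within_group_correlation(140.14, 115.73, 114.31)  # about 0.615
derive_within_group_correlation <- function(sd_x, sd_y, sd_diff) {
  stopifnot(is.numeric(sd_x), is.numeric(sd_y), is.numeric(sd_diff))
  if (sd_x <= 0 || sd_y <= 0)
    mh_stop("mh_invalid", "sd_x and sd_y must be positive")
  if (sd_diff < 0) mh_stop("mh_invalid", "sd_diff must be non-negative")
  rho <- (sd_x^2 + sd_y^2 - sd_diff^2) / (2 * sd_x * sd_y)
  if (abs(rho) > 1 + 1e-12)
    mh_stop("mh_infeasible_variance",
            "implied correlation %.4f is outside [-1, 1]: inconsistent SDs",
            rho)
  min(1, max(-1, rho))
}

#' @describeIn cohort_reference_parameters correlation overrides implied by
#'   the printed difference-feature SDs via
#'   [derive_within_group_correlation()], per group, as a
#'   `data.frame(x, y, group, rho)`.
#' @param params,diffs reference tables to derive from.
#' @export
derived_correlation_overrides <- function(params = cohort_reference_parameters(),
                                          diffs = cohort_reference_difference_sds()) {
  sd_of <- function(f, g) {
    i <- match(f, params$feature)
    if (g == "A") params$sd_a[i] else params$sd_b[i]
  }
  out <- do.call(rbind, lapply(seq_len(nrow(diffs)), function(i) {
    row <- diffs[i, ]
    data.frame(
      x = rep(row$x, 2), y = rep(row$y, 2), group = c("A", "B"),
      rho = c(
        derive_within_group_correlation(sd_of(row$x, "A"), sd_of(row$y, "A"),
                                        row$sd_diff_a),
        derive_within_group_correlation(sd_of(row$x, "B"), sd_of(row$y, "B"),
                                        row$sd_diff_b)
      ))
  }))
  rownames(out) <- NULL
  out
}

#' Configuration of the synthetic cohort generator
#'
#' Assembles and validates the parameters of the group-conditional Gaussian
#' cohort sampler. Defaults reproduce the study conditions: group sizes 32
#' (good prognosis) and 11 (poor prognosis), continuous base features
#' calibrated to the published per-group means and SDs, within-group
#' correlations recovered from the printed difference-feature SDs where the
#' variance identity applies, a default correlation of 0.5 for the remaining
#' morphometric pairs and 0 between clinical and morphometric features, and
#' categorical features drawn from the published per-group proportions.
#'
#' @param n_group_a,n_group_b group sizes (each >= 2).
#' @param feature_params data.frame as [cohort_reference_parameters()].
#' @param correlation_overrides data.frame with columns `x`, `y`, `group`
#'   (`"A"`/`"B"`) and `rho`, overriding the default correlation for specific
#'   pairs of continuous base features.
#' @param default_correlation correlation assigned to morphometric pairs with
#'   no override.
#' @param clinical_correlation correlation between clinical continuous and
#'   morphometric features (and among clinical features).
#' @param categorical_probs named list of per-group level probabilities.
#' @param seed integer master seed for [sample_feature_table()].
#' @return An object of class `mh_generator_config`.
#' @export
generator_config <- function(n_group_a = 32L, n_group_b = 11L,
                             feature_params = cohort_reference_parameters(),
                             correlation_overrides = derived_correlation_overrides(feature_params),
                             default_correlation = 0.5,
                             clinical_correlation = 0,
                             categorical_probs = cohort_reference_categorical_probs(),
                             seed = 1L) {
  stopifnot(n_group_a >= 2, n_group_b >= 2)
  stopifnot(all(c("feature", "mean_a", "sd_a", "mean_b", "sd_b") %in%
                  names(feature_params)))
  if (any(feature_params$sd_a < 0) || any(feature_params$sd_b < 0))
    mh_stop("mh_invalid", "feature SDs must be non-negative")
  if (abs(default_correlation) > 1 || abs(clinical_correlation) > 1)
    mh_stop("mh_invalid", "correlations must lie in [-1, 1]")
  if (nrow(correlation_overrides) &&
      any(abs(correlation_overrides$rho) > 1))
    mh_stop("mh_invalid", "correlation overrides must lie in [-1, 1]")
  fn <- mh_feature_names()
  base <- c(fn$clinical_continuous, fn$lengths, fn$areas)
  missing <- setdiff(base, feature_params$feature)
  if (length(missing))
    mh_stop("mh_invalid", "feature_params misses base features: %s",
            paste(missing, collapse = ", "))
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 feature_params = feature_params,
                 correlation_overrides = correlation_overrides,
                 default_correlation = default_correlation,
                 clinical_correlation = clinical_correlation,
                 categorical_probs = categorical_probs,
                 seed = as.integer(seed)),
            class = "mh_generator_config")
}

# Assemble the within-group correlation matrix over the continuous base
# features and repair it to the nearest positive-semidefinite correlation
# matrix when needed. The repair is reported via attributes "adjusted" and
# "max_change" and a message.
group_correlation_matrix <- function(config, group) {
  fn <- mh_feature_names()
  clin <- fn$clinical_continuous
  morpho <- c(fn$lengths, fn$areas)
  base <- c(clin, morpho)
  k <- length(base)
  R <- matrix(config$clinical_correlation, k, k, dimnames = list(base, base))
  R[morpho, morpho] <- config$default_correlation
  ov <- config$correlation_overrides
  ov <- ov[ov$group == group, , drop = FALSE]
  for (i in seq_len(nrow(ov))) {
    R[ov$x[i], ov$y[i]] <- R[ov$y[i], ov$x[i]] <- ov$rho[i]
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  adjusted <- min(ev) < 1e-8
  if (adjusted) {
    R2 <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    dimnames(R2) <- dimnames(R)
    max_change <- max(abs(R2 - R))
    message(sprintf(
      "group %s correlation matrix adjusted to nearest PSD (max |change| %.3f)",
      group, max_change))
    attr(R2, "adjusted") <- TRUE
    attr(R2, "max_change") <- max_change
    return(R2)
  }
  attr(R, "adjusted") <- FALSE
  attr(R, "max_change") <- 0
  R
}

# Sample n records of the continuous base features for one group, resampling
# records with a negative length/area (or a zero ratio denominator) so that
# configured means are preserved rather than distorted by clipping.
sample_group_continuous <- function(config, group, n) {
  fn <- mh_feature_names()
  base <- c(fn$clinical_continuous, fn$lengths, fn$areas)
  nonneg <- c(fn$lengths, fn$areas)
  p <- config$feature_params
  idx <- match(base, p$feature)
  mu <- if (group == "A") p$mean_a[idx] else p$mean_b[idx]
  s <- if (group == "A") p$sd_a[idx] else p$sd_b[idx]
  names(mu) <- names(s) <- base
  R <- group_correlation_matrix(config, group)
  psd_adjusted <- isTRUE(attr(R, "adjusted"))
  R <- R[base, base]
  Sigma <- R * (s %o% s)
  denoms <- unique(vapply(mh_combination_defs(),
                          function(d) if (d$op == "ratio") d$y else "",
                          character(1)))
  denoms <- setdiff(denoms, "")
  X <- MASS::mvrnorm(n, mu, Sigma)
  if (n == 1) X <- matrix(X, nrow = 1, dimnames = list(NULL, base))
  bad_rows <- function(M) {
    which(apply(M[, nonneg, drop = FALSE] < 0, 1, any) |
            apply(M[, denoms, drop = FALSE] == 0, 1, any))
  }
  bad <- bad_rows(X)
  resampled <- 0L
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > 10000L)
      mh_stop("mh_psd_failure",
              "could not draw non-negative records for group %s", group)
    resampled <- resampled + length(bad)
    Y <- MASS::mvrnorm(length(bad), mu, Sigma)
    if (length(bad) == 1) Y <- matrix(Y, nrow = 1, dimnames = list(NULL, base))
    X[bad, ] <- Y
    bad <- bad[bad %in% bad_rows(X)]
  }
  attr(X, "resampled") <- resampled
  attr(X, "psd_adjusted") <- psd_adjusted
  X
}

# Add the 16 combination columns, computed exactly from the base columns.
add_combination_features <- function(d) {
  for (def in mh_combination_defs()) {
    d[[def$name]] <- if (def$op == "diff") d[[def$x]] - d[[def$y]]
    else d[[def$x]] / d[[def$y]]
  }
  d
}

#' Sample a synthetic patient feature table
#'
#' Draws a cohort of `n_group_a + n_group_b` synthetic patients. Continuous
#' base features come from group-conditional multivariate Gaussians with the
#' configured means, SDs and within-group correlations (repaired to the
#' nearest positive-semidefinite correlation matrix when necessary); records
#' with a negative length or area are resampled. Categorical features are
#' drawn from the configured per-group level probabilities. The 16 combination
#' features are then computed deterministically from the sampled base
#' features. Output is bit-identical for a fixed `config$seed`.
#'
#' @param config an [generator_config()] object.
#' @return A data.frame of 41 feature columns plus a `Group` factor,
#'   in canonical column order, with attributes `resampled` (number of
#'   record redraws) and `psd_adjusted`.
#' @export
#' @examples
#' tab <- sample_feature_table(generator_config(seed = 1))
#' dim(tab)  # 43 x 42
sample_feature_table <- function(config = generator_config()) {
  stopifnot(inherits(config, "mh_generator_config"))
  set.seed(config$seed)
  fn <- mh_feature_names()
  XA <- sample_group_continuous(config, "A", config$n_group_a)
  XB <- sample_group_continuous(config, "B", config$n_group_b)
  X <- rbind(XA, XB)
  d <- as.data.frame(X, check.names = FALSE)
  grp <- c(rep("A", config$n_group_a), rep("B", config$n_group_b))
  lev <- mh_categorical_levels()
  for (f in fn$categorical) {
    pr <- config$categorical_probs[[f]]
    if (is.null(pr))
      mh_stop("mh_invalid", "no categorical probabilities for '%s'", f)
    vals <- character(length(grp))
    for (g in c("A", "B")) {
      i <- grp == g
      vals[i] <- sample(lev[[f]], sum(i), replace = TRUE, prob = pr[[g]])
    }
    d[[f]] <- factor(vals, levels = lev[[f]])
  }
  d <- add_combination_features(d)
  d$Group <- factor(grp, levels = c("A", "B"))
  d <- d[, c(fn$all, "Group")]
  rownames(d) <- NULL
  attr(d, "resampled") <- attr(XA, "resampled") + attr(XB, "resampled")
  attr(d, "psd_adjusted") <- attr(XA, "psd_adjusted") || attr(XB, "psd_adjusted")
  d
}
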