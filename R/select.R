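# Explanatory-variable selection: per-feature two-group tests at alpha, then
# iterative multicollinearity elimination by auxiliary-regression R^2
# (VIF > 10 <=> R^2 > 0.9).

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided two-sample KS test used for continuous features. The exact
#' p-value is computed when `n_a * n_b <= 10^4` (conditional on ties when
#' present), the asymptotic distribution otherwise.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @return List with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    mh_stop("mh_invalid", "both samples must be non-empty")
  exact <- length(sample_a) * length(sample_b) <= 1e4
  res <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = exact))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Fisher's exact test for an r x c contingency table
#'
#' Two-sided exact test used for categorical features: the classical
#' hypergeometric test for 2 x 2 tables and the Freeman-Halton extension for
#' larger tables (exact enumeration up to a total count of 60, seeded Monte
#' Carlo with 10^5 draws beyond). A degenerate table (an all-zero row or
#' column) returns p = 1 with a warning.
#'
#' @param table matrix of non-negative integer counts, at least 2 x 2.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    mh_stop("mh_invalid", "counts must be non-negative integers")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    mh_stop("mh_invalid", "table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin: p-value fixed at 1")
    return(1)
  }
  if (sum(tab) <= 60)
    stats::fisher.test(tab)$p.value
  else
    stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e5)$p.value
}

#' Wilcoxon signed-rank test for paired acuities
#'
#' Two-sided signed-rank test of a location shift between paired
#' measurements, e.g. preoperative versus 6-month BCVA. Zero differences are
#' dropped and ties mid-ranked (the exact distribution is used when free of
#' ties and zeros). All-zero differences give p = 1.
#'
#' @param paired_before,paired_after numeric vectors of equal length >= 5.
#' @return The two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(paired_before, paired_after) {
  if (length(paired_before) != length(paired_after))
    mh_stop("mh_invalid", "paired samples must have equal length")
  if (length(paired_before) < 5)
    mh_stop("mh_invalid", "need at least 5 pairs")
  d <- paired_after - paired_before
  if (all(d == 0)) return(1)
  suppressWarnings(
    stats::wilcox.test(paired_after, paired_before, paired = TRUE)$p.value)
}

#' Screen features by two-group significance
#'
#' Tests every feature of the table for a difference between the two
#' prognosis groups: continuous features by [ks_two_sample()], categorical
#' features by [fisher_exact()] on the level-by-group contingency table. No
#' multiplicity correction is applied. Features with `p < alpha` become the
#' candidate explanatory variables, in canonical table order. A constant
#' feature gets p = 1.
#'
#' @param table feature data.frame with a `Group` column.
#' @param alpha significance level (default 0.05).
#' @return List with `p_values` (data.frame `feature`, `type`, `p`) and
#'   `candidates` (character vector).
#' @export
significance_filter <- function(table, alpha = 0.05) {
  if (!"Group" %in% names(table))
    mh_stop("mh_invalid", "table must contain a Group column")
  grp <- table$Group
  if (min(table(grp)) < 2)
    mh_stop("mh_invalid", "need at least 2 records per group")
  feats <- setdiff(names(table), "Group")
  res <- lapply(feats, function(f) {
    x <- table[[f]]
    if (is.numeric(x)) {
      if (length(unique(x)) == 1)
        return(data.frame(feature = f, type = "continuous", p = 1))
      a <- x[grp == "A"]; b <- x[grp == "B"]
      data.frame(feature = f, type = "continuous",
                 p = ks_two_sample(a, b)$p.value)
    } else {
      tab <- table(factor(x), grp)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      p <- if (nrow(tab) < 2) 1 else fisher_exact(tab)
      data.frame(feature = f, type = "categorical", p = p)
    }
  })
  p_values <- do.call(rbind, res)
  list(p_values = p_values,
       candidates = p_values$feature[p_values$p < alpha])
}

#' Variance inflation factor from an auxiliary R-squared
#'
#' @param r2 coefficient of determination in `[0, 1)`.
#' @return `1 / (1 - r2)`; 0.9 maps to the conventional VIF threshold of 10.
#' @export
vif_from_r2 <- function(r2) {
  if (any(r2 < 0) || any(r2 >= 1))
    mh_stop("mh_invalid", "r2 must lie in [0, 1)")
  1 / (1 - r2)
}

# numeric design column for a candidate feature (factors -> 0-based codes)
feature_column <- function(x) {
  if (is.numeric(x)) x else as.numeric(as.factor(x)) - 1
}

#' Iterative multicollinearity elimination
#'
#' Regresses each candidate on all other remaining candidates by ordinary
#' least squares and records the R-squared. While the largest R-squared
#' exceeds the threshold (0.9, i.e. VIF 10), the offending feature is dropped
#' - exactly one per iteration, ties broken toward the feature later in
#' canonical table order - and the regressions are repeated. A perfectly
#' collinear feature gets R-squared 1 and is dropped first.
#'
#' @param table feature data.frame.
#' @param candidates character vector of candidate features (>= 1).
#' @param r2_threshold elimination threshold on R-squared.
#' @return An object of class `mh_selection`: `p_values` (if attached by
#'   [select_variables()]), `candidates`, `trace` (per-iteration R-squared
#'   and dropped feature) and `final_variables`.
#' @export
vif_eliminate <- function(table, candidates, r2_threshold = 0.9) {
  stopifnot(length(candidates) >= 1)
  miss <- setdiff(candidates, names(table))
  if (length(miss))
    mh_stop("mh_invalid", "candidates absent from table: %s",
            paste(miss, collapse = ", "))
  candidates <- candidates[order(match(candidates, names(table)))]
  X <- sapply(table[candidates], feature_column)
  X <- matrix(X, ncol = length(candidates),
              dimnames = list(NULL, candidates))
  if (nrow(X) <= length(candidates))
    mh_stop("mh_invalid", "need more records than candidates")
  remaining <- candidates
  trace <- list()
  it <- 0L
  while (length(remaining) >= 2) {
    it <- it + 1L
    r2 <- vapply(remaining, function(f) {
      others <- setdiff(remaining, f)
      fit <- stats::lm.fit(cbind(1, X[, others, drop = FALSE]), X[, f])
      rss <- sum(fit$residuals^2)
      tss <- sum((X[, f] - mean(X[, f]))^2)
      if (tss == 0) return(1)
      min(1, max(0, 1 - rss / tss))
    }, numeric(1))
    worst <- max(r2)
    if (worst <= r2_threshold) {
      trace[[it]] <- list(iteration = it, r2 = r2, dropped = NA_character_)
      break
    }
    # ties: drop the feature later in canonical order (candidates are in
    # canonical order already)
    at_max <- which(r2 >= worst - 1e-12)
    drop <- remaining[at_max[length(at_max)]]
    trace[[it]] <- list(iteration = it, r2 = r2, dropped = drop)
    remaining <- setdiff(remaining, drop)
  }
  if (length(remaining) == 1 && it == 0L)
    trace[[1]] <- list(iteration = 1L,
                       r2 = stats::setNames(0, remaining),
                       dropped = NA_character_)
  structure(list(p_values = NULL, candidates = candidates, trace = trace,
                 final_variables = remaining),
            class = "mh_selection")
}

#' Full explanatory-variable selection
#'
#' [significance_filter()] followed by [vif_eliminate()]. When no feature
#' reaches significance the single lowest-p feature is retained as the only
#' candidate (with a warning), so that downstream modelling always has at
#' least one explanatory variable.
#'
#' @inheritParams significance_filter
#' @inheritParams vif_eliminate
#' @return An `mh_selection` object carrying the 41 p-values, candidates,
#'   elimination trace and final variables.
#' @export
select_variables <- function(table, alpha = 0.05, r2_threshold = 0.9) {
  sf <- significance_filter(table, alpha)
  cand <- sf$candidates
  if (!length(cand)) {
    warning("no feature significant at alpha; retaining the lowest-p feature")
    cand <- sf$p_values$feature[which.min(sf$p_values$p)]
  }
  sel <- if (length(cand) >= 2) vif_eliminate(table, cand, r2_threshold)
  else structure(list(p_values = NULL, candidates = cand, trace = list(),
                      final_variables = cand), class = "mh_selection")
  sel$p_values <- sf$p_values
  sel
}

#' @export
print.mh_selection <- function(x, ...) {
  cat(sprintf("mh_selection: %d candidate(s) -> %d explanatory variable(s)\n",
              length(x$candidates), length(x$final_variables)))
  for (tr in x$trace) {
    cat(sprintf("  iteration %d: max R^2 %.3f%s\n", tr$iteration, max(tr$r2),
                if (is.na(tr$dropped)) " (stop)"
                else paste0(", dropped ", tr$dropped)))
  }
  cat("  final:", paste(x$final_variables, collapse = ", "), "\n")
  invisible(x)
}
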