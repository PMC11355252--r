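# The prognosis classifier: L2-penalised logistic regression on z-scored
# explanatory variables, hyperparameter fixing by frequency over repeated CV,
# and a precision-favouring decision threshold.

#' Pipeline configuration
#'
#' Collects the tunable parameters of the prognosis pipeline. Defaults follow
#' the study conditions: positive class is Group B (poor prognosis), the
#' acuity threshold is 0.15 logMAR (decimal 0.7), candidate screening at
#' alpha 0.05, multicollinearity elimination at R-squared 0.9, stratified
#' 5-fold cross-validation repeated 100 times, regularisation grid
#' {0.001, 0.01, 0.1, 1, 10, 100} fixed by the F-measure of the
#' threshold-aligned classifier over 100 pre-tests, and the
#' precision >= recall alignment rule.
#'
#' @param positive_class group label scored as the positive (poor-prognosis)
#'   class.
#' @param bcva_threshold_decimal decimal acuity separating good from poor
#'   prognosis (>= threshold is good).
#' @param alpha significance level of the candidate screen.
#' @param r2_threshold auxiliary-regression R-squared above which a candidate
#'   is eliminated.
#' @param k_folds folds of the stratified cross-validation (>= 2).
#' @param n_repeats evaluation repeats (>= 1).
#' @param n_pretests tuning repeats used to fix the hyperparameter.
#' @param c_grid positive regularisation constants (larger = weaker penalty).
#' @param tuning_objective `"auc"`, `"f1"` or `"accuracy"`.
#' @param alignment_rule `"precision"` (feasible thresholds satisfy
#'   precision >= recall) or `"accuracy"` (accuracy >= recall).
#' @param ci_method `"t"` or `"z"` quantiles for the 95% confidence
#'   intervals.
#' @param seed master seed; every random draw of the pipeline flows from it.
#' @return An object of class `mh_pipeline_config`.
#' @export
pipeline_config <- function(positive_class = "B",
                            bcva_threshold_decimal = 0.7,
                            alpha = 0.05,
                            r2_threshold = 0.9,
                            k_folds = 5L,
                            n_repeats = 100L,
                            n_pretests = 100L,
                            c_grid = c(0.001, 0.01, 0.1, 1, 10, 100),
                            tuning_objective = c("f1", "auc", "accuracy"),
                            alignment_rule = c("precision", "accuracy"),
                            ci_method = c("t", "z"),
                            seed = 1L) {
  tuning_objective <- match.arg(tuning_objective)
  alignment_rule <- match.arg(alignment_rule)
  ci_method <- match.arg(ci_method)
  if (k_folds < 2) mh_stop("mh_invalid", "k_folds must be >= 2")
  if (n_repeats < 1 || n_pretests < 1)
    mh_stop("mh_invalid", "repeat counts must be >= 1")
  if (!length(c_grid) || any(c_grid <= 0))
    mh_stop("mh_invalid", "c_grid must be non-empty and positive")
  if (bcva_threshold_decimal <= 0 || bcva_threshold_decimal > 1)
    mh_stop("mh_invalid", "bcva_threshold_decimal must lie in (0, 1]")
  structure(list(positive_class = positive_class,
                 bcva_threshold_decimal = bcva_threshold_decimal,
                 alpha = alpha, r2_threshold = r2_threshold,
                 k_folds = as.integer(k_folds),
                 n_repeats = as.integer(n_repeats),
                 n_pretests = as.integer(n_pretests),
                 c_grid = sort(c_grid),
                 tuning_objective = tuning_objective,
                 alignment_rule = alignment_rule,
                 ci_method = ci_method,
                 seed = as.integer(seed)),
            class = "mh_pipeline_config")
}

#' Acuity conversions and prognosis group assignment
#'
#' Decimal acuity and logMAR are related by `logMAR = -log10(decimal)`; the
#' prognosis threshold of decimal 0.7 corresponds to 0.15 logMAR (2 dp).
#' `assign_group()` labels a 6-month decimal acuity: `"A"` (good) when
#' `>= threshold`, `"B"` (poor) otherwise.
#'
#' @param bcva_decimal positive decimal acuity (vectorised).
#' @param threshold decimal threshold, default 0.7.
#' @return `assign_group()`: character vector of `"A"`/`"B"`.
#' @export
assign_group <- function(bcva_decimal, threshold = 0.7) {
  if (any(bcva_decimal <= 0))
    mh_stop("mh_invalid", "decimal acuity must be positive")
  ifelse(bcva_decimal >= threshold, "A", "B")
}

#' @rdname assign_group
#' @export
decimal_to_logmar <- function(bcva_decimal) -log10(bcva_decimal)

#' @rdname assign_group
#' @export
logmar_to_decimal <- function(bcva_logmar) 10^(-bcva_logmar)

#' Z-score features with training-set parameters
#'
#' Centres and scales columns by the training mean and sample (n-1) standard
#' deviation; new data are always transformed with the training parameters
#' only.
#'
#' @param train numeric matrix of training features.
#' @param apply_to matrix to transform (default the training data).
#' @return List with `z` (transformed matrix), `center` and `scale`.
#' @export
standardize <- function(train, apply_to = train) {
  train <- as.matrix(train)
  apply_to <- as.matrix(apply_to)
  center <- colMeans(train)
  scale <- apply(train, 2, stats::sd)
  if (any(scale == 0))
    mh_stop("mh_invalid", "zero-variance feature: %s",
            paste(colnames(train)[scale == 0], collapse = ", "))
  z <- sweep(sweep(apply_to, 2, center), 2, scale, "/")
  list(z = z, center = center, scale = scale)
}

# Penalised negative log-likelihood: -loglik + ||beta||^2 / (2 c), intercept
# unpenalised (the scikit-learn "C" convention: larger c = weaker penalty).
penalized_nll <- function(beta, X1, y, c_value) {
  eta <- drop(X1 %*% beta)
  # log(1 + exp(eta)) - y * eta, computed stably
  nll <- sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta)
  nll + sum(beta[-1]^2) / (2 * c_value)
}

#' Fit an L2-penalised logistic regression
#'
#' Maximises the binomial log-likelihood penalised by `||beta||^2 / (2 c)`
#' (intercept unpenalised) by iteratively reweighted least squares with step
#' halving, to a gradient norm below 1e-6. Inputs are expected standardized;
#' the coefficients are then standard regression coefficients directly
#' comparable across features.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 vector (1 = positive class); both classes must be present.
#' @param c_value positive regularisation constant.
#' @return An object of class `mh_logistic` with `intercept`,
#'   `coefficients`, `c_value`, `converged`.
#' @export
fit_logistic <- function(x, y, c_value = 0.1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    mh_stop("mh_invalid", "y must contain both classes coded 0/1")
  if (any(!is.finite(x))) mh_stop("mh_invalid", "non-finite features")
  X1 <- cbind(1, x)
  p <- ncol(X1)
  pen <- c(0, rep(1 / c_value, p - 1))
  beta <- numeric(p)
  converged <- FALSE
  nll <- penalized_nll(beta, X1, y, c_value)
  for (i in seq_len(200)) {
    mu <- stats::plogis(drop(X1 %*% beta))
    g <- drop(crossprod(X1, mu - y)) + pen * beta
    if (sqrt(sum(g^2)) < 1e-6) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1 * w, X1)
    diag(H) <- diag(H) + pen
    step <- solve(H, g)
    # step halving keeps the objective monotone
    for (h in 0:30) {
      cand <- beta - step / 2^h
      new_nll <- penalized_nll(cand, X1, y, c_value)
      if (new_nll <= nll + 1e-12) break
    }
    beta <- cand
    nll <- new_nll
  }
  if (!converged) warning("IRLS did not reach gradient tolerance 1e-6")
  cf <- beta[-1]
  names(cf) <- colnames(x)
  structure(list(intercept = beta[1], coefficients = cf,
                 c_value = c_value, converged = converged),
            class = "mh_logistic")
}

#' @export
predict.mh_logistic <- function(object, newdata, ...) {
  stats::plogis(drop(as.matrix(newdata) %*% object$coefficients) +
                  object$intercept)
}

#' Align the decision threshold so precision dominates recall
#'
#' Sweeps candidate thresholds (midpoints of sorted unique scores plus
#' sentinels below the minimum and above the maximum score), keeps those
#' satisfying the alignment rule - precision >= recall by default, a
#' threshold predicting no positives counting as precision 1 and recall 0,
#' so the feasible set is never empty - and returns the feasible threshold
#' with the largest F-measure, ties resolved toward the higher threshold.
#'
#' @param scores predicted positive-class probabilities.
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive class.
#' @param rule `"precision"` or `"accuracy"` (feasibility compares that
#'   metric against recall).
#' @return The selected threshold; scores `>= threshold` predict positive.
#' @export
align_threshold <- function(scores, labels, rule = c("precision", "accuracy")) {
  rule <- match.arg(rule)
  y <- as.logical(as.numeric(labels))
  if (!any(y) || all(y))
    mh_stop("mh_invalid", "both classes must be present")
  s <- sort(unique(scores))
  cand <- c(s[1] / 2, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            (s[length(s)] + 1) / 2)
  best_t <- NA_real_
  best_f <- -Inf
  for (t in cand) {
    pred <- scores >= t
    tp <- sum(pred & y)
    prec <- if (sum(pred) == 0) 1 else tp / sum(pred)
    rec <- tp / sum(y)
    acc <- mean(pred == y)
    feasible <- if (rule == "precision") prec >= rec else acc >= rec
    if (!feasible) next
    f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    if (f > best_f || (f == best_f && t > best_t)) {
      best_f <- f
      best_t <- t
    }
  }
  best_t
}

# Fit one model bundle on raw (unstandardised) training data: standardise,
# fit at c_value, align the threshold on the training scores. Test-fold data
# never enter here.
fit_model_bundle <- function(x_train, y_train, c_value,
                             alignment_rule = "precision") {
  st <- standardize(x_train)
  fit <- fit_logistic(st$z, y_train, c_value)
  scores <- predict(fit, st$z)
  thr <- align_threshold(scores, y_train, rule = alignment_rule)
  structure(list(feature_means = st$center, feature_sds = st$scale,
                 coefficients = fit$coefficients, intercept = fit$intercept,
                 c_value = c_value, threshold = thr,
                 converged = fit$converged),
            class = "mh_model_bundle")
}

#' @export
predict.mh_model_bundle <- function(object, newdata, ...) {
  z <- sweep(sweep(as.matrix(newdata), 2, object$feature_means), 2,
             object$feature_sds, "/")
  stats::plogis(drop(z %*% object$coefficients) + object$intercept)
}

#' @export
print.mh_model_bundle <- function(x, ...) {
  cat(sprintf("mh_model_bundle: c = %g, threshold = %.3f\n",
              x$c_value, x$threshold))
  print(round(c("(intercept)" = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Fix the regularisation constant by frequency over repeated CV
#'
#' For each of `n_pretests` seeded repetitions, runs stratified k-fold
#' cross-validation for every constant in the grid, scores each constant by
#' the pooled-test-fold objective (AUC by default) and records the per-repeat
#' winner (ties toward stronger regularisation, i.e. the smaller constant).
#' The returned constant is the mode of the winners, ties again toward the
#' smaller constant.
#'
#' @param table feature table with a `Group` column.
#' @param variables explanatory variables to use.
#' @param config an [pipeline_config()]; uses `c_grid`, `n_pretests`,
#'   `k_folds`, `tuning_objective`, `alignment_rule` and the current RNG
#'   state (seed it upstream).
#' @return List with `c_star`, `frequencies` (named counts over the grid) and
#'   `winners` (per-repeat winning constants).
#' @export
tune_hyperparameter <- function(table, variables, config = pipeline_config()) {
  y <- as.integer(table$Group == config$positive_class)
  X <- design_matrix(table, variables)
  grid <- config$c_grid
  winners <- numeric(config$n_pretests)
  for (r in seq_len(config$n_pretests)) {
    folds <- stratified_kfold_indices(y, k = config$k_folds)
    obj <- numeric(length(grid))
    scores <- matrix(NA_real_, nrow(X), length(grid))
    preds <- matrix(NA, nrow(X), length(grid))
    for (f in seq_len(config$k_folds)) {
      tr <- folds != f
      st <- standardize(X[tr, , drop = FALSE], X)
      for (j in seq_along(grid)) {
        fit <- fit_logistic(st$z[tr, , drop = FALSE], y[tr], grid[j])
        sc <- predict(fit, st$z[!tr, , drop = FALSE])
        scores[!tr, j] <- sc
        if (config$tuning_objective != "auc") {
          thr <- align_threshold(predict(fit, st$z[tr, , drop = FALSE]),
                                 y[tr], rule = config$alignment_rule)
          preds[!tr, j] <- sc >= thr
        }
      }
    }
    for (j in seq_along(grid)) {
      obj[j] <- switch(config$tuning_objective,
        auc = auc_rank(y, scores[, j]),
        f1 = {
          tp <- sum(preds[, j] & y == 1)
          prec <- if (sum(preds[, j]) == 0) 1 else tp / sum(preds[, j])
          rec <- tp / sum(y)
          if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
        },
        accuracy = mean((preds[, j] == 1) == (y == 1)))
    }
    winners[r] <- grid[which.max(obj)]  # first max = smallest c on ties
  }
  freq <- table(factor(winners, levels = grid))
  c_star <- grid[which.max(freq)]
  list(c_star = c_star, frequencies = freq, winners = winners)
}

#' Summarise coefficients across model bundles
#'
#' Per-feature mean, sample SD, 95% confidence interval and box-and-whisker
#' statistics (1.5 IQR whiskers, values beyond them listed as outliers) over
#' a collection of fitted bundles with identical feature sets.
#'
#' @param bundles list of `mh_model_bundle` (or any objects with a
#'   `coefficients` vector), length >= 2.
#' @param ci_method `"t"` or `"z"`.
#' @return A data.frame with one row per feature and a `boxplot` attribute.
#' @export
collect_coefficients <- function(bundles, ci_method = "t") {
  stopifnot(length(bundles) >= 2)
  feats <- names(bundles[[1]]$coefficients)
  same <- vapply(bundles, function(b)
    identical(names(b$coefficients), feats), logical(1))
  if (!all(same))
    mh_stop("mh_invalid", "bundles have inconsistent feature sets")
  M <- matrix(unlist(lapply(bundles, `[[`, "coefficients")),
              ncol = length(feats), byrow = TRUE,
              dimnames = list(NULL, feats))
  n <- nrow(M)
  mean_ <- colMeans(M)
  sd_ <- apply(M, 2, stats::sd)
  ci <- t(vapply(seq_along(feats), function(j)
    confidence_interval(mean = mean_[j], sd = sd_[j], n = n,
                        method = ci_method), numeric(2)))
  box <- lapply(seq_along(feats), function(j) {
    q <- stats::quantile(M[, j], c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    inside <- M[M[, j] >= lo & M[, j] <= hi, j]
    list(q1 = q[1], median = q[2], q3 = q[3],
         whisker_low = min(inside), whisker_high = max(inside),
         outliers = M[M[, j] < lo | M[, j] > hi, j])
  })
  names(box) <- feats
  out <- data.frame(feature = feats, mean = mean_, sd = sd_,
                    ci_low = ci[, 1], ci_high = ci[, 2], row.names = NULL)
  attr(out, "boxplot") <- box
  out
}

# numeric design matrix for a set of explanatory variables
design_matrix <- function(table, variables) {
  X <- vapply(variables, function(v) feature_column(table[[v]]),
              numeric(nrow(table)))
  X <- matrix(X, nrow = nrow(table), dimnames = list(NULL, variables))
  X
}
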