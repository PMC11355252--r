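test_that("group assignment and acuity conversions match the threshold", {
  expect_equal(assign_group(0.7), "A")
  expect_equal(assign_group(0.69), "B")
  expect_equal(assign_group(c(1.0, 0.2)), c("A", "B"))
  expect_error(assign_group(0), class = "mh_invalid")
  expect_equal(round(decimal_to_logmar(0.7), 2), 0.15)
  expect_equal(logmar_to_decimal(decimal_to_logmar(0.37)), 0.37)
})

test_that("standardisation uses training parameters with sample SD", {
  st <- standardize(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(drop(st$z), c(-1, 0, 1))
  st2 <- standardize(matrix(c(1, 2, 3), ncol = 1), matrix(2, ncol = 1))
  expect_equal(drop(st2$z), 0)
  tr <- matrix(rnorm(40), ncol = 2)
  st3 <- standardize(tr)
  expect_equal(unname(colMeans(st3$z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(st3$z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(standardize(matrix(1, 5, 1)), class = "mh_invalid")
})

test_that("penalised logistic fit is symmetric on a symmetric toy set", {
  fit <- fit_logistic(matrix(c(-1, 1), ncol = 1), c(1, 0), c_value = 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_lt(fit$coefficients[[1]], 0)
  expect_error(fit_logistic(matrix(1:4, ncol = 1), c(1, 1, 1, 1)),
               class = "mh_invalid")
})

test_that("fit matches a brute-force penalised-likelihood oracle (n = 8)", {
  set.seed(10)
  x <- matrix(c(-1.2, -0.8, -0.5, -0.1, 0.2, 0.6, 0.9, 1.4), ncol = 1)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  for (cv in c(0.1, 1, 10)) {
    fit <- fit_logistic(x, y, c_value = cv)
    # independent objective written here, minimised by Nelder-Mead
    obj <- function(b) {
      eta <- b[1] + x[, 1] * b[2]
      sum(log(1 + exp(eta)) - y * eta) + b[2]^2 / (2 * cv)
    }
    o <- stats::optim(c(0, 0), obj, control = list(reltol = 1e-14,
                                                   maxit = 5000))
    expect_equal(unname(fit$intercept), o$par[1], tolerance = 1e-3)
    expect_equal(unname(fit$coefficients[[1]]), o$par[2], tolerance = 1e-3)
  }
})

test_that("fit agrees with ridge-penalised glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(11)
  n <- 120
  X <- matrix(rnorm(3 * n), ncol = 3)
  y <- rbinom(n, 1, plogis(X %*% c(1, -0.5, 0.2)))
  cv <- 0.5
  fit <- fit_logistic(X, y, c_value = cv)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = 1 / (n * cv), standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(unname(fit$coefficients), unname(g$beta[, 1]),
               tolerance = 1e-3)
})

test_that("duplicating every record is equivalent to halving c", {
  set.seed(12)
  X <- matrix(rnorm(60), ncol = 2)
  y <- rbinom(30, 1, 0.5); y[1:3] <- 1; y[4:6] <- 0
  f1 <- fit_logistic(X, y, c_value = 1)
  f2 <- fit_logistic(rbind(X, X), c(y, y), c_value = 0.5)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-6)
})

test_that("weakening the penalty never lowers the training log-likelihood", {
  set.seed(13)
  X <- matrix(rnorm(80), ncol = 2)
  y <- rbinom(40, 1, plogis(X %*% c(2, -1)))
  loglik <- function(fit) {
    eta <- fit$intercept + drop(X %*% fit$coefficients)
    sum(y * eta - log(1 + exp(eta)))
  }
  lls <- vapply(c(0.001, 0.01, 0.1, 1, 10, 100),
                function(cv) loglik(fit_logistic(X, y, cv)), numeric(1))
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("standardised coefficients are invariant to affine rescaling", {
  set.seed(14)
  X <- matrix(rnorm(100), ncol = 2)
  y <- rbinom(50, 1, plogis(X %*% c(1, -1)))
  b1 <- fit_model_bundle(X, y, c_value = 0.1)
  X2 <- X
  X2[, 1] <- 1000 * X2[, 1] + 37
  b2 <- fit_model_bundle(X2, y, c_value = 0.1)
  expect_equal(unname(b1$coefficients), unname(b2$coefficients),
               tolerance = 1e-6)
  expect_equal(b1$threshold, b2$threshold, tolerance = 1e-9)
})

test_that("threshold alignment favours precision and maximises F", {
  t1 <- align_threshold(c(0.9, 0.8, 0.7, 0.2), c(1, 1, 0, 0))
  expect_equal(t1, 0.75)
  # perfectly separated scores admit an F = 1 solution
  sc <- c(0.95, 0.9, 0.2, 0.1)
  y <- c(1, 1, 0, 0)
  m <- binary_metrics(y, sc, align_threshold(sc, y))
  expect_equal(m$f_measure, 1)
  # all positives score below all negatives: sentinel, recall 0, precision 1
  t3 <- align_threshold(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  m3 <- binary_metrics(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9), t3)
  expect_equal(m3$recall, 0)
  expect_equal(m3$precision, 1)
  # the rule's guarantee on the data it was tuned on
  set.seed(15)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- runif(n)
    th <- align_threshold(s, y)
    mm <- binary_metrics(y, s, th)
    expect_gte(mm$precision, mm$recall)
  }
})

test_that("accuracy alignment rule is available", {
  set.seed(16)
  y <- c(rep(1, 10), rep(0, 30))
  s <- plogis(rnorm(40) + 2 * y)
  th <- align_threshold(s, y, rule = "accuracy")
  m <- binary_metrics(y, s, th)
  expect_gte(m$accuracy, m$recall)
})

test_that("hyperparameter fixing returns the modal constant", {
  tab <- suppressMessages(sample_feature_table(generator_config(seed = 4)))
  cfg <- pipeline_config(c_grid = 0.1, n_pretests = 10, seed = 4)
  set.seed(4)
  tn <- tune_hyperparameter(tab, c("Preoperative BCVA", "ONL-DL"), cfg)
  expect_equal(tn$c_star, 0.1)
  expect_equal(unname(as.integer(tn$frequencies)), 10L)

  # two-point grid where the weak penalty strictly dominates the AUC on a
  # cohort with two anti-correlated informative features
  set.seed(17)
  n <- 200
  x1 <- rnorm(n); x2 <- 0.95 * x1 + sqrt(1 - 0.95^2) * rnorm(n)
  y <- rbinom(n, 1, plogis(6 * (x1 - x2)))
  d <- data.frame(x1 = x1, x2 = x2,
                  Group = factor(ifelse(y == 1, "B", "A")))
  cfg2 <- pipeline_config(c_grid = c(1e-4, 10), n_pretests = 10,
                          tuning_objective = "auc", seed = 17)
  set.seed(17)
  tn2 <- tune_hyperparameter(d, c("x1", "x2"), cfg2)
  expect_equal(tn2$c_star, 10)
  expect_equal(length(unique(tn2$winners)), 1L)
})

test_that("coefficient collection summarises across bundles", {
  b <- function(v) structure(list(coefficients = c(f1 = v)),
                             class = "mh_model_bundle")
  rep1 <- collect_coefficients(list(b(0.3), b(0.3), b(0.3)))
  expect_equal(rep1$sd, 0)
  expect_equal(rep1$ci_low, rep1$mean)
  rep2 <- collect_coefficients(list(b(0.2), b(0.4)))
  expect_equal(rep2$mean, 0.3)
  expect_equal(rep2$sd, sd(c(0.2, 0.4)))
  expect_error(collect_coefficients(list(b(1),
    structure(list(coefficients = c(other = 1)), class = "mh_model_bundle"))),
    class = "mh_invalid")
})

test_that("marginal coefficient signs follow the published group contrasts", {
  tab <- suppressMessages(sample_feature_table(
    generator_config(n_group_a = 3200, n_group_b = 1100, seed = 6)))
  y <- as.integer(tab$Group == "B")
  signs <- c("Preoperative BCVA" = 1, "ONL-DL" = 1,
             "(OPL-DL) - (ONL-DL)" = -1, "(OPL-DL)/(ONL-DL)" = -1)
  for (f in names(signs)) {
    b <- fit_model_bundle(matrix(tab[[f]], ncol = 1,
                                 dimnames = list(NULL, f)), y, c_value = 0.1)
    expect_equal(sign(b$coefficients[[1]]), unname(signs[f]))
  }
})
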