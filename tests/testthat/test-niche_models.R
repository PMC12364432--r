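toy_train <- function(n_pos = 50, n_neg = 50, sep = 2, seed = 1) {
  set.seed(seed)
  data.frame(label = rep(c(1L, 0L), c(n_pos, n_neg)),
             provenance = rep(c("presence", "background"), c(n_pos, n_neg)),
             a = c(rnorm(n_pos, sep), rnorm(n_neg, 0)),
             b = rnorm(n_pos + n_neg))
}

test_that("bioclim envelope scores 1 at the presence median and 0 outside the range", {
  set.seed(2)
  train <- data.frame(label = 1L, provenance = "presence",
                      a = rnorm(21), b = runif(21))
  m <- fit_bioclim(train)
  med <- data.frame(a = median(train$a), b = median(train$b))
  expect_equal(predict(m, med), 1)
  expect_equal(predict(m, data.frame(a = max(train$a) + 1, b = median(train$b))), 0)
  expect_equal(predict(m, data.frame(a = median(train$a), b = min(train$b) - 1)), 0)
  expect_error(fit_bioclim(train[1:4, ]), "5 presences")
})

test_that("bioclim interior scores equal the direct mid-rank CDF computation", {
  vals_a <- c(1, 2, 3, 5, 8, 9, 12)
  vals_b <- c(0.1, 0.4, 0.5, 0.6, 0.6, 0.9, 1.3)
  train <- data.frame(label = 1L, provenance = "presence",
                      a = vals_a, b = vals_b)
  m <- fit_bioclim(train)
  cdf <- function(s, x) (sum(s < x) + 0.5 * sum(s == x)) / length(s)
  for (q in list(c(3.5, 0.6), c(8, 0.2), c(1, 1.0))) {
    want <- min(1 - abs(2 * cdf(vals_a, q[1]) - 1),
                1 - abs(2 * cdf(vals_b, q[2]) - 1))
    expect_equal(predict(m, data.frame(a = q[1], b = q[2])), want)
  }
  # constant predictor: degenerate envelope scores 1 at the constant only
  const <- data.frame(label = 1L, provenance = "presence",
                      a = vals_a, k = rep(4, 7))
  mc <- fit_bioclim(const)
  expect_equal(predict(mc, data.frame(a = 3, k = 4)),
               1 - abs(2 * cdf(vals_a, 3) - 1))  # k axis contributes 1
  expect_equal(predict(mc, data.frame(a = median(vals_a), k = 4)), 1)
  expect_equal(predict(mc, data.frame(a = median(vals_a), k = 5)), 0)
})

test_that("ridge logistic recovers known coefficients and matches glm as ridge -> 0", {
  set.seed(3)
  n <- 1500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 1 * x1 - 1.5 * x2))
  train <- data.frame(label = y, provenance = "sim", x1 = x1, x2 = x2)
  fit <- fit_logistic(train, ridge = 1e-8)
  ref <- glm(y ~ x1 + x2, family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_true(fit$converged)
  expect_error(fit_logistic(transform(train, label = 1L)), "identical")
})

test_that("a large ridge shrinks coefficients to zero and predictions to prevalence", {
  train <- toy_train(80, 120, sep = 3, seed = 4)
  fit <- fit_logistic(train, ridge = 1e8)
  expect_lt(max(abs(fit$coefficients[-1])), 1e-4)
  expect_equal(unique(round(predict(fit, train[c("a", "b")]), 4)),
               round(80 / 200, 4))
})

test_that("separated classes stay finite under the ridge", {
  train <- data.frame(label = rep(c(1L, 0L), each = 10),
                      provenance = "x",
                      a = c(rnorm(10, 10), rnorm(10, -10)))
  fit <- fit_logistic(train, ridge = 0.01)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("predict_map projects models over stacks with nodata propagation", {
  st <- stack_from(a = matrix(rnorm(100), 10), b = matrix(rnorm(100), 10))
  st$layers$a[1, 1] <- NA
  zero <- structure(list(kind = "logistic",
                         coefficients = c(`(intercept)` = 0, a = 0, b = 0),
                         variables = c("a", "b")),
                    class = c("logistic_model", "niche_model"))
  m <- predict_map(zero, st)
  expect_true(is.na(m$values[1, 1]))
  expect_true(all(m$values[-1] == 0.5))
  expect_identical(predict_map(zero, st)$values, m$values)
  bad <- stack_from(a = matrix(0, 10, 10))
  expect_error(predict_map(zero, bad), "lacks variable")
  train <- toy_train(seed = 5)
  bc <- fit_bioclim(train)
  full <- stack_from(a = matrix(rnorm(100, 2), 10), b = matrix(rnorm(100), 10))
  vals <- predict_map(bc, full)$values
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("AUC equals the rank-pair probability, with monotone invariance", {
  expect_equal(auc(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc(c(0.3, 0.5), c(0.3, 0.5)), 0.5)
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  set.seed(6)
  pos <- round(runif(40), 2); neg <- round(runif(60), 2)
  expect_equal(auc(pos, neg), auc_oracle(pos, neg))
  expect_equal(auc(qlogis(pmin(pmax(pos, 1e-6), 1 - 1e-6)),
                   qlogis(pmin(pmax(neg, 1e-6), 1 - 1e-6))),
               auc(pos, neg))
  skip_if_not_installed("pROC")
  proc <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(40, 60)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(auc(pos, neg), proc)
})

test_that("TSS matches confusion-matrix counting at any threshold", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  labels <- c(1, 1, 1, 0, 0, 0)
  expect_equal(tss_at(scores, labels, 0.5), 1)
  expect_equal(tss_at(scores, labels, 0.05), 0)  # everything positive
  set.seed(7)
  sc <- runif(50); lb <- rbinom(50, 1, 0.4)
  for (thr in c(0.2, 0.5, 0.8)) {
    tp <- sum(sc >= thr & lb == 1); fn <- sum(sc < thr & lb == 1)
    tn <- sum(sc < thr & lb == 0); fp <- sum(sc >= thr & lb == 0)
    expect_equal(tss_at(sc, lb, thr), tp / (tp + fn) + tn / (tn + fp) - 1)
  }
})

test_that("max(se+sp) threshold attains the dense-sweep maximum", {
  sep_scores <- c(0.1, 0.2, 0.7, 0.9)
  sep_labels <- c(0, 0, 1, 1)
  thr <- max_sens_spec_threshold(sep_scores, sep_labels)
  expect_gt(thr, 0.2); expect_lte(thr, 0.7)
  one_pos <- max_sens_spec_threshold(c(0.3, 0.1, 0.95), c(0, 0, 1))
  expect_gt(one_pos, 0.3); expect_lte(one_pos, 0.95)
  set.seed(8)
  for (i in 1:50) {
    sc <- runif(30); lb <- rbinom(30, 1, 0.5)
    if (length(unique(lb)) < 2) next
    thr <- max_sens_spec_threshold(sc, lb)
    sweep <- seq(min(sc) - 0.01, max(sc) + 0.01, length.out = 1000)
    best <- max(vapply(sweep, function(t) tss_at(sc, lb, t), numeric(1)))
    expect_gte(tss_at(sc, lb, thr) + 1e-12, best)
  }
})

test_that("bootstrap evaluation is stratified, seeded and sized as configured", {
  train <- toy_train(60, 200, sep = 3, seed = 9)
  res <- bootstrap_fit_eval("logistic", train, n_replicates = 10,
                            train_fraction = 0.7, seed = 42)
  expect_length(res, 10)
  ev <- do.call(rbind, lapply(res, `[[`, "evaluation"))
  expect_equal(ev$replicate, 1:10)
  expect_gt(mean(ev$auc), 0.9)
  res2 <- bootstrap_fit_eval("logistic", train, n_replicates = 10,
                             train_fraction = 0.7, seed = 42)
  expect_identical(lapply(res, `[[`, "evaluation"),
                   lapply(res2, `[[`, "evaluation"))
  tbl <- evaluation_table(list(logistic = res))
  expect_equal(tbl$auc, mean(ev$auc))
  expect_equal(tbl$tss_sd, sd(ev$tss))
})

test_that("plugin scorers join the contract and are range-checked", {
  pm <- plugin_model(function(nd) plogis(nd$a), "a", label = "toy")
  expect_equal(pm$kind, "plugin")
  expect_equal(predict(pm, data.frame(a = 0)), 0.5)
  bad <- plugin_model(function(nd) nd$a * 10, "a")
  expect_error(predict(bad, data.frame(a = 1)), "\\[0, 1\\]")
})
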