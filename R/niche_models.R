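# Suitability models under a uniform scorer contract (predict() onto a
# predictor data frame, values in [0, 1]): Bioclim envelope and ridge
# logistic regression ship natively; anything else joins through
# plugin_model(). Evaluation: ROC AUC, TSS, and max(se+sp) thresholding on
# repeated stratified 70/30 splits.

#' Assemble a training set
#'
#' @param stack A [climate_stack()] supplying predictor values.
#' @param occ An [occurrence_set()]; presences become label 1, congener
#'   absences and background points label 0 (provenance retained).
#' @param variables Optional subset of layer names.
#' @return Data frame with columns \code{label}, \code{provenance} and one
#'   column per predictor.
#' @export
make_training <- function(stack, occ, variables = NULL) {
  pred <- extract_predictors(stack, occ)
  if (!is.null(variables)) {
    miss <- setdiff(variables, names(pred))
    if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
    pred <- pred[variables]
  }
  label <- ifelse(occ$role == "presence", 1L, 0L)
  if (sum(label == 1) < 1 || sum(label == 0) < 1)
    stop("training set needs at least one presence and one zero-label row")
  cbind(data.frame(label = label, provenance = occ$role), pred)
}

#' Predictor columns of a training set
#'
#' @param train A training set from [make_training()].
#' @return Data frame of the predictor columns only.
#' @export
training_predictors <- function(train) {
  as.data.frame(train[, setdiff(names(train), c("label", "provenance")),
                      drop = FALSE])
}

# Mid-rank empirical CDF: F(x) = (#{s < x} + 0.5 #{s == x}) / n, so the
# presence median scores F = 0.5 and values outside the range score 0 or 1.
midrank_cdf <- function(sorted_vals, x) {
  n <- length(sorted_vals)
  le <- findInterval(x, sorted_vals)
  lt <- findInterval(x, sorted_vals, left.open = TRUE)
  (lt + 0.5 * (le - lt)) / n
}

#' Fit a Bioclim climate envelope
#'
#' Presence-only envelope: for each variable the presence empirical CDF
#' \code{F_v} is stored and a query scores
#' \code{min_v (1 - |2 F_v(x_v) - 1|)}, i.e. 1 at the componentwise presence
#' median, falling to 0 outside the presence range (classic min-aggregation
#' envelope). Zero-label rows are ignored by the fit.
#'
#' @param train Training set from [make_training()] with >= 5 presences.
#' @return A \code{bioclim_model}.
#' @export
fit_bioclim <- function(train) {
  pres <- training_predictors(train)[train$label == 1, , drop = FALSE]
  if (nrow(pres) < 5) stop("need at least 5 presences")
  structure(list(kind = "bioclim",
                 envelopes = lapply(pres, function(v) sort(v)),
                 variables = names(pres)),
            class = c("bioclim_model", "niche_model"))
}

#' @export
predict.bioclim_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  score <- rep(1, nrow(newdata))
  for (v in object$variables) {
    f <- midrank_cdf(object$envelopes[[v]], newdata[[v]])
    score <- pmin(score, 1 - abs(2 * f - 1))
  }
  pmin(1, pmax(0, score))
}

#' Fit a ridge-penalised logistic regression
#'
#' Maximises the Bernoulli log-likelihood with linear terms minus
#' \code{ridge/2 * sum(beta^2)} (intercept unpenalised) by iteratively
#' reweighted least squares; the ridge keeps complete separation finite.
#' Convergence when the largest coefficient update falls below \code{tol};
#' otherwise a warning reports the iteration count.
#'
#' @param train Training set from [make_training()].
#' @param ridge Ridge penalty (>= 0; default 1e-4).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on coefficient updates.
#' @return A \code{logistic_model} with \code{coefficients} (intercept
#'   first), \code{converged}, \code{iterations}.
#' @export
fit_logistic <- function(train, ridge = 1e-4, max_iter = 100, tol = 1e-8) {
  y <- train$label
  if (length(unique(y)) < 2) stop("all labels identical; cannot fit")
  x <- as.matrix(training_predictors(train))
  X <- cbind(`(intercept)` = 1, x)
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("IRLS did not converge in ", iter, " iterations")
  names(beta) <- colnames(X)
  structure(list(kind = "logistic", coefficients = beta,
                 variables = colnames(x), ridge = ridge,
                 converged = converged, iterations = iter),
            class = c("logistic_model", "niche_model"))
}

#' @export
predict.logistic_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(newdata[object$variables])
  drop(stats::plogis(object$coefficients[1] +
                       x %*% object$coefficients[-1]))
}

#' Wrap an external scorer as an ensemble-compatible model
#'
#' The plugin contract: any function mapping a predictor data frame to
#' scores in [0, 1] may join the ensemble (random forest, SVM, GAM, boosted
#' trees, MaxEnt, ... fitted elsewhere).
#'
#' @param predict_fun Function(newdata) -> numeric scores in [0, 1].
#' @param variables Predictor names the scorer expects.
#' @param label Free-text algorithm label.
#' @return A \code{plugin_model}.
#' @export
plugin_model <- function(predict_fun, variables, label = "plugin") {
  stopifnot(is.function(predict_fun))
  structure(list(kind = "plugin", predict_fun = predict_fun,
                 variables = variables, label = label),
            class = c("plugin_model", "niche_model"))
}

#' @export
predict.plugin_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  s <- object$predict_fun(newdata)
  if (any(is.finite(s) & (s < -1e-9 | s > 1 + 1e-9)))
    stop("plugin scores must lie in [0, 1]")
  pmin(1, pmax(0, s))
}

#' Project a fitted model over a climate stack
#'
#' @param model A fitted \code{niche_model}.
#' @param stack A [climate_stack()] supplying all model variables.
#' @return A [suitability_map()]; nodata cells propagate as NA.
#' @export
predict_map <- function(model, stack) {
  miss <- setdiff(model$variables, names(stack$layers))
  if (length(miss)) stop("stack lacks variable(s): ", paste(miss, collapse = ", "))
  newdata <- as.data.frame(lapply(stack$layers[model$variables], as.vector))
  names(newdata) <- model$variables
  ok <- stats::complete.cases(newdata)
  vals <- rep(NA_real_, nrow(newdata))
  if (any(ok)) vals[ok] <- predict(model, newdata[ok, , drop = FALSE])
  suitability_map(matrix(vals, stack$spec$n_rows, stack$spec$n_cols),
                  stack$spec,
                  provenance = list(kind = model$kind,
                                    scenario = stack$scenario))
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank statistic: the probability that a presence score
#' exceeds an absence score, ties counted half.
#'
#' @param scores_pos,scores_neg Scores at presences / zero-label points.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores_pos, scores_neg) {
  stopifnot(length(scores_pos) > 0, length(scores_neg) > 0)
  r <- rank(c(scores_pos, scores_neg))
  np <- length(scores_pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(scores_neg))
}

#' True skill statistic at a threshold
#'
#' Sensitivity + specificity - 1, with "predicted positive" defined as
#' score >= threshold.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes present).
#' @param threshold Classification threshold.
#' @return TSS in [-1, 1].
#' @export
tss_at <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels), any(labels == 1), any(labels == 0))
  pred <- scores >= threshold
  se <- sum(pred & labels == 1) / sum(labels == 1)
  sp <- sum(!pred & labels == 0) / sum(labels == 0)
  se + sp - 1
}

#' Threshold maximising sensitivity + specificity
#'
#' Candidates are the midpoints between adjacent sorted unique scores plus
#' one candidate below all scores and one above; ties return the smallest
#' maximising candidate.
#'
#' @inheritParams tss_at
#' @return The max(se+sp) threshold.
#' @export
max_sens_spec_threshold <- function(scores, labels) {
  stopifnot(any(labels == 1), any(labels == 0))
  u <- sort(unique(scores))
  span <- if (length(u) > 1) u[length(u)] - u[1] else 1
  cand <- c(u[1] - 0.01 * span - 1e-9,
            if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 0.01 * span + 1e-9)
  tss <- vapply(cand, function(t) tss_at(scores, labels, t), numeric(1))
  cand[which.max(tss)]  # which.max returns the first (smallest) maximiser
}

#' Fit and evaluate a model over stratified bootstrap replicates
#'
#' Per replicate a stratified random 70/30 split (subsampling without
#' replacement) is drawn, the model fit on the training part and AUC, TSS
#' and the max(se+sp) threshold computed on the held-out part. A replicate
#' whose test part loses a class is redrawn (bounded retries).
#'
#' @param model_kind \code{"bioclim"}, \code{"logistic"}, or a factory
#'   function(train) -> fitted model.
#' @param data Training set from [make_training()].
#' @param n_replicates Number of replicates (default 10).
#' @param train_fraction Training share (default 0.7).
#' @param seed Integer seed; identical seeds give identical splits.
#' @param ... Passed to the fitting function.
#' @return List of \code{n_replicates} elements, each with \code{model} and
#'   \code{evaluation} (auc, tss, threshold, replicate).
#' @export
bootstrap_fit_eval <- function(model_kind, data, n_replicates = 10,
                               train_fraction = 0.7, seed = 1, ...) {
  fitter <- if (is.function(model_kind)) model_kind
            else switch(model_kind,
                        bioclim = fit_bioclim,
                        logistic = fit_logistic,
                        stop("unknown model kind: ", model_kind))
  idx_pos <- which(data$label == 1)
  idx_neg <- which(data$label == 0)
  n_tr_pos <- floor(train_fraction * length(idx_pos))
  n_tr_neg <- floor(train_fraction * length(idx_neg))
  if (n_tr_pos < 1 || n_tr_neg < 1 ||
      n_tr_pos == length(idx_pos) || n_tr_neg == length(idx_neg))
    stop("not enough rows in each class for a ", train_fraction, " split")
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(rep_i) {
      for (try in seq_len(25)) {
        tr <- c(sample(idx_pos, n_tr_pos), sample(idx_neg, n_tr_neg))
        te <- setdiff(seq_len(nrow(data)), tr)
        if (any(data$label[te] == 1) && any(data$label[te] == 0)) break
      }
      model <- fitter(data[tr, , drop = FALSE], ...)
      sc <- predict(model, training_predictors(data[te, , drop = FALSE]))
      lab <- data$label[te]
      thr <- max_sens_spec_threshold(sc, lab)
      list(model = model,
           evaluation = data.frame(replicate = rep_i,
                                   auc = auc(sc[lab == 1], sc[lab == 0]),
                                   tss = tss_at(sc, lab, thr),
                                   threshold = thr))
    })
  })
}

#' Summarise replicate evaluations as an algorithm table
#'
#' @param fits Named list: algorithm -> result of [bootstrap_fit_eval()].
#' @return Data frame with mean and sd of AUC and TSS and the mean
#'   max(se+sp) threshold per algorithm.
#' @export
evaluation_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(alg) {
    ev <- do.call(rbind, lapply(fits[[alg]], `[[`, "evaluation"))
    data.frame(algorithm = alg,
               auc = mean(ev$auc), auc_sd = stats::sd(ev$auc),
               tss = mean(ev$tss), tss_sd = stats::sd(ev$tss),
               max_se_sp = mean(ev$threshold))
  }))
}
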