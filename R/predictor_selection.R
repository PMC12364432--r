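# Collinearity screening of candidate bioclimatic predictors (VIF and
# pairwise Pearson filters) and permutation-based variable importance.

#' Extract predictor values at point locations
#'
#' @param stack A [climate_stack()].
#' @param occ An [occurrence_set()] (or any data frame with x/y).
#' @return Data frame, one column per layer, rows aligned with \code{occ};
#'   the point roles (if present) are attached as attribute \code{"roles"}.
#' @export
extract_predictors <- function(stack, occ) {
  loc <- cell_from_xy(stack$spec, occ$x, occ$y)
  out <- as.data.frame(lapply(stack$layers, function(l) l[cbind(loc$row, loc$col)]))
  names(out) <- names(stack$layers)
  if (!is.null(occ$role)) attr(out, "roles") <- occ$role
  out
}

#' Variance inflation factor of one predictor
#'
#' VIF = 1 / (1 - R^2) of the OLS regression of \code{variable} on all other
#' columns. An effectively perfect fit (R^2 >= 1 - 1e-12) returns \code{Inf}.
#'
#' @param table Numeric data frame of predictor columns (>= 2 columns and
#'   more rows than columns).
#' @param variable Column name.
#' @return The VIF (>= 1), possibly \code{Inf}.
#' @export
vif <- function(table, variable) {
  table <- as.data.frame(table)
  stopifnot(variable %in% names(table), ncol(table) >= 2)
  if (nrow(table) < ncol(table) + 1)
    stop("need more rows than predictors to compute VIF")
  if (any(vapply(table, function(col) stats::var(col) == 0, logical(1))))
    stop("constant column in predictor table")
  others <- setdiff(names(table), variable)
  fml <- stats::reformulate(sprintf("`%s`", others), response = sprintf("`%s`", variable))
  fit <- stats::lm(fml, data = table)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # near-perfect fits intended
  if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
}

#' Greedy stepwise VIF filter
#'
#' While any variable's VIF is at or above the threshold, the variable with
#' the largest VIF is removed; ties break alphabetically. Survivors all have
#' VIF below the threshold.
#'
#' @param table Predictor data frame.
#' @param threshold VIF cutoff (default 9).
#' @return Character vector of retained variable names.
#' @export
stepwise_vif_filter <- function(table, threshold = 9) {
  table <- as.data.frame(table)
  keep <- names(table)
  while (length(keep) >= 2) {
    v <- vapply(keep, function(nm) vif(table[keep], nm), numeric(1))
    if (max(v) < threshold) break
    worst <- keep[v == max(v)]
    keep <- setdiff(keep, sort(worst)[1])
  }
  keep
}

#' Pairwise Pearson correlation filter
#'
#' While any remaining pair has |r| at or above the threshold, the member of
#' the worst (largest |r|) pair with the larger mean absolute correlation
#' against all remaining variables is dropped; remaining ties break
#' alphabetically (the later name is dropped).
#'
#' @param table Predictor data frame.
#' @param r_threshold Absolute-correlation cutoff (default 0.6).
#' @return Character vector of retained variable names.
#' @export
correlation_filter <- function(table, r_threshold = 0.6) {
  table <- as.data.frame(table)
  keep <- names(table)
  while (length(keep) >= 2) {
    cm <- abs(stats::cor(table[keep]))
    diag(cm) <- 0
    if (max(cm) < r_threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- sort(keep[worst])
    mean_abs <- colSums(cm) / (length(keep) - 1)
    drop <- if (mean_abs[pair[1]] > mean_abs[pair[2]]) pair[1]
            else if (mean_abs[pair[2]] > mean_abs[pair[1]]) pair[2]
            else pair[2]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Permutation variable importance
#'
#' For each variable, its column is permuted and the model re-applied.
#' \code{importance_correlation} is 1 - Pearson r between original and
#' permuted predictions; \code{importance_auc} is the drop in AUC
#' (labels required). Both are averaged over permutations and floored at 0.
#'
#' @param model A fitted model with a \code{predict} method onto the table.
#' @param table Predictor data frame.
#' @param labels Optional 0/1 vector for the AUC-based importance.
#' @param seed Integer seed.
#' @param n_permutations Permutations per variable (default 5).
#' @return Data frame: variable, importance_correlation, importance_auc.
#' @export
variable_importance <- function(model, table, labels = NULL, seed = 1,
                                n_permutations = 5) {
  table <- as.data.frame(table)
  base_pred <- predict(model, table)
  base_auc <- if (!is.null(labels))
    auc(base_pred[labels == 1], base_pred[labels == 0]) else NA_real_
  res <- with_seed(seed, {
    lapply(names(table), function(v) {
      ic <- ia <- numeric(n_permutations)
      for (k in seq_len(n_permutations)) {
        perm <- table
        perm[[v]] <- sample(perm[[v]])
        pp <- predict(model, perm)
        r <- suppressWarnings(stats::cor(base_pred, pp))
        ic[k] <- if (is.na(r)) 0 else 1 - r
        ia[k] <- if (is.null(labels)) NA_real_
                 else base_auc - auc(pp[labels == 1], pp[labels == 0])
      }
      c(max(0, mean(ic)), if (is.null(labels)) NA_real_ else max(0, mean(ia)))
    })
  })
  data.frame(variable = names(table),
             importance_correlation = vapply(res, `[`, numeric(1), 1),
             importance_auc = vapply(res, `[`, numeric(1), 2))
}
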