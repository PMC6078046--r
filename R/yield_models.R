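# Multiple-linear-regression prediction of log-log residual yields:
# exhaustive best-subset search, K-fold cross-validation, and the published
# prediction equations.

#' Published yield-prediction equations
#'
#' Loads the versioned constants file with the published regression models
#' `Mod_hlCarss = -0.06 - 0.37 P1 + 6.12 P2 + 0.06 P3` and
#' `Mod_Fil = -0.02 - 0.63 P1 + 5.30 P2 + 0.06 P3 - 7.84e-06 P4 + 0.0007 P5`.
#'
#' @param file optional path to an alternative constants JSON (same schema).
#' @return Named list of models, each with `response`, `intercept`,
#'   `coefficients`.
#' @export
published_models <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "published_models.json",
                        package = "carpyield", mustWork = TRUE)
  jsonlite::read_json(file, simplifyVector = TRUE)$models
}

#' Apply a published prediction equation
#'
#' @param predictors named list, vector, or data frame with the columns the
#'   chosen model needs (`P1..P3` for `Mod_hlCarss`, `P1..P5` for
#'   `Mod_Fil`).
#' @param which model name.
#' @param models constants as returned by [published_models()] (overridable).
#' @return Predicted log-residual yield value(s) (the "Mod" trait).
#' @examples
#' apply_published_model(c(P1 = 0, P2 = 0, P3 = 0), "Mod_hlCarss")  # -0.06
#' @export
apply_published_model <- function(predictors,
                                  which = c("Mod_hlCarss", "Mod_Fil"),
                                  models = published_models()) {
  which <- match.arg(which, choices = names(models))
  m <- models[[which]]
  co <- unlist(m$coefficients)
  predictors <- as.list(predictors)
  missing_p <- setdiff(names(co), names(predictors))
  if (length(missing_p))
    stop("missing predictor(s) for ", which, ": ",
         paste(missing_p, collapse = ", "))
  out <- rep(m$intercept, length(predictors[[names(co)[1]]]))
  for (p in names(co)) out <- out + co[[p]] * predictors[[p]]
  out
}

fit_subset <- function(X, y) {
  fit <- lm(y ~ ., data = X)
  sm <- suppressWarnings(summary(fit))  # noiseless fits trip summary.lm
  list(fit = fit, r2 = sm$r.squared,
       F = unname(sm$fstatistic["value"]))
}

#' K-fold cross-validated R-squared
#'
#' Randomly partitions the data into `K` (seeded) folds; each fold is
#' predicted from a model fitted on the other `K - 1`, and
#' `R2cv = 1 - sum((y - yhat_cv)^2) / sum((y - mean(y))^2)`. `K = n` gives
#' leave-one-out.
#'
#' @param X data frame of predictors.
#' @param y response vector.
#' @param K number of folds (2..n, default 20).
#' @param seed RNG seed for the partition.
#' @return `R2cv` (scalar; can be negative for a useless model).
#' @export
crossval_r2 <- function(X, y, K = 20, seed = 1) {
  n <- length(y)
  stopifnot(nrow(X) == n, K >= 2, K <= n)
  folds <- with_seed(seed, sample(rep(seq_len(K), length.out = n)))
  if (min(table(folds)) + 0 < 1) stop("empty fold")
  if (n - max(table(folds)) < ncol(X) + 1)
    stop("a training set is smaller than the predictor count + 1")
  pred <- numeric(n)
  for (k in seq_len(K)) {
    test <- folds == k
    fit <- lm(y ~ ., data = cbind(X[!test, , drop = FALSE], y = y[!test]))
    pred[test] <- predict(fit, newdata = X[test, , drop = FALSE])
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Exhaustive best-subset regression with cross-validated selection
#'
#' Searches all predictor subsets up to `max_size`, recording the best model
#' per size by R-squared (within a size, R-squared and the overall F rank
#' subsets identically). Because R-squared is non-decreasing in subset size,
#' the final model is chosen as the per-size winner with the highest K-fold
#' cross-validated R-squared, ties broken toward fewer predictors; a fixed
#' size can be forced to reproduce a published subset.
#'
#' @param candidates data frame of candidate predictors.
#' @param y response vector.
#' @param max_size largest subset size searched (default all candidates).
#' @param K,seed cross-validation folds and partition seed.
#' @param force_size optionally return the best model of exactly this size.
#' @return Object of class `subset_search`: `per_size` (data frame with
#'   size, predictors, r2, F, r2cv), `selected` (list: predictors,
#'   coefficients, r2, F, r2cv, n, K).
#' @export
best_subset_regression <- function(candidates, y, max_size = ncol(candidates),
                                   K = 20, seed = 1, force_size = NULL) {
  stopifnot(is.data.frame(candidates), nrow(candidates) == length(y))
  n <- length(y)
  if (n <= ncol(candidates) + 1)
    stop("need more observations than candidates + 1")
  X1 <- cbind(`(Intercept)` = 1, as.matrix(candidates))
  q <- qr(X1)
  if (q$rank < ncol(X1)) {
    bad <- colnames(X1)[q$pivot[(q$rank + 1):ncol(X1)]]
    stop("collinear candidate set; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  per_size <- list()
  for (s in seq_len(max_size)) {
    combos <- combn(names(candidates), s, simplify = FALSE)
    best <- NULL
    for (cs in combos) {
      f <- fit_subset(candidates[cs], y)
      if (is.null(best) || f$r2 > best$r2) best <- c(f, list(predictors = cs))
    }
    best$r2cv <- crossval_r2(candidates[best$predictors], y, K = K, seed = seed)
    per_size[[s]] <- best
  }
  tab <- data.frame(size = seq_len(max_size),
                    predictors = vapply(per_size, function(b)
                      paste(b$predictors, collapse = "+"), ""),
                    r2 = vapply(per_size, `[[`, 1, "r2"),
                    F = vapply(per_size, `[[`, 1, "F"),
                    r2cv = vapply(per_size, `[[`, 1, "r2cv"))
  pick <- if (!is.null(force_size)) force_size
          else which(tab$r2cv >= max(tab$r2cv) - 1e-12)[1]
  sel <- per_size[[pick]]
  selected <- list(predictors = sel$predictors,
                   coefficients = coef(sel$fit),
                   r2 = sel$r2, F = sel$F, r2cv = sel$r2cv,
                   n = n, K = K)
  structure(list(per_size = tab, selected = selected),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, digits = 3, ...) {
  cat("Best-subset regression search:\n")
  print(cbind(x$per_size[1:2], round(x$per_size[3:5], digits)))
  cat("Selected:", paste(x$selected$predictors, collapse = " + "),
      sprintf("(R2 = %.3f, R2cv = %.3f, F = %.1f, n = %d)\n",
              x$selected$r2, x$selected$r2cv, x$selected$F, x$selected$n))
  invisible(x)
}
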