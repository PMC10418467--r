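# Linear QSAR models: the shipped discriminant and regression equations,
# OLS refits with leave-one-out validation, a two-group canonical LDA and
# a stepwise selector.

#' Linear QSAR model
#'
#' A plain intercept-plus-coefficients container covering both the
#' discriminant function and the regression equation shipped with the
#' package.
#'
#' @param kind `"discriminant"` or `"regression"`.
#' @param intercept Intercept.
#' @param coefficients Named numeric vector of descriptor coefficients.
#' @return An object of class `linear_model`.
#' @export
#' @examples
#' m <- linear_model("regression", 1, c(X0v = 2))
#' evaluate_linear_model(m, tibble::tibble(X0v = c(0, 1)))
linear_model <- function(kind = c("discriminant", "regression"),
                         intercept, coefficients) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients), length(coefficients) >= 1,
            !is.null(names(coefficients)), all(nzchar(names(coefficients))))
  structure(
    list(kind = kind, intercept = unname(intercept),
         coefficients = coefficients),
    class = "linear_model"
  )
}

#' @export
print.linear_model <- function(x, ...) {
  terms <- sprintf("%+.4g*%s", x$coefficients, names(x$coefficients))
  cat("<linear_model:", x$kind, ">\n  ",
      sprintf("%.4g ", x$intercept), paste(terms, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Evaluate a linear model on descriptor values
#'
#' `intercept + sum(coefficient * descriptor)` for every row of a
#' descriptor table.
#'
#' @param model A [linear_model].
#' @param descriptors A data frame (or named list for a single compound)
#'   containing every descriptor the model names.
#' @return A numeric vector, one value per row.
#' @export
evaluate_linear_model <- function(model, descriptors) {
  stopifnot(inherits(model, "linear_model"))
  if (!is.data.frame(descriptors)) {
    descriptors <- tibble::as_tibble(descriptors[names(model$coefficients)])
  }
  missing <- setdiff(names(model$coefficients), names(descriptors))
  if (length(missing)) {
    stop("descriptor(s) missing from input: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(descriptors[names(model$coefficients)])
  drop(model$intercept + X %*% model$coefficients)
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  evaluate_linear_model(object, newdata)
}

# design matrix with intercept from data + predictor names, with rank check
.design <- function(data, predictors) {
  missing <- setdiff(predictors, names(data))
  if (length(missing)) {
    stop("predictor(s) missing from data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(data[predictors]))
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  X
}

#' Fit an ordinary least squares QSAR regression
#'
#' Regresses a response (typically experimental pIC50) on a set of
#' descriptor columns and reports the fit statistics used for QSAR model
#' quality: R^2, the standard error of the estimate
#' \eqn{\sqrt{SS_{res}/(n - p - 1)}}, and the leave-one-out prediction
#' coefficient Q^2 (see [loo_q2()]).
#'
#' @param data A data frame holding response and descriptor columns.
#' @param response Name of the response column.
#' @param predictors Character vector of descriptor column names.
#' @return An object of class `qsar_ols` with components `fit` (the `lm`),
#'   `model` (a [linear_model]), and `stats`. [generics::tidy()] and
#'   [generics::glance()] methods are provided.
#' @export
#' @examples
#' d <- synthetic_qsar_dataset(n = 30, beta = c(1, -2), sigma = 0.1,
#'                             seed = 1)
#' glance(fit_ols(d, "y", c("x1", "x2")))
fit_ols <- function(data, response, predictors) {
  data <- tibble::as_tibble(data)
  stopifnot(response %in% names(data))
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  .design(data, predictors)  # rank guard with a clear error
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = sprintf("`%s`", response))
  fit <- stats::lm(fml, data = data)
  names(fit$coefficients) <- c("(Intercept)", predictors)
  y <- data[[response]]
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  see <- sqrt(ss_res / (n - p - 1))
  q2 <- if (n >= p + 3) loo_q2(data, response, predictors) else NA_real_
  model <- linear_model("regression",
                        intercept = stats::coef(fit)[["(Intercept)"]],
                        coefficients = stats::coef(fit)[predictors])
  structure(
    list(fit = fit, model = model,
         stats = tibble::tibble(r2 = r2, q2 = q2, see = see,
                                n = n, p = p)),
    class = "qsar_ols"
  )
}

#' @export
print.qsar_ols <- function(x, ...) {
  print(x$model)
  cat(sprintf("  n = %d, R2 = %.3f, Q2 = %.3f, SEE = %.3f\n",
              x$stats$n, x$stats$r2, x$stats$q2, x$stats$see))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.qsar_ols <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @export
glance.qsar_ols <- function(x, ...) {
  x$stats
}

#' Leave-one-out Q^2
#'
#' The cross-validated prediction coefficient
#' \eqn{Q^2 = 1 - \sum_i (y_i - \hat y_{(-i)})^2 / \sum_i (y_i - \bar y)^2},
#' with each \eqn{\hat y_{(-i)}} predicted by the model refit without
#' observation `i`. Computed through the hat-matrix identity
#' \eqn{y_i - \hat y_{(-i)} = e_i / (1 - h_{ii})}, which equals the naive
#' refit-n-times procedure exactly for OLS.
#'
#' @inheritParams fit_ols
#' @return A number, at most 1 (negative when the model predicts worse
#'   than the mean).
#' @export
loo_q2 <- function(data, response, predictors) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  p <- length(predictors)
  if (n < p + 3) stop("need n >= p + 3 for leave-one-out", call. = FALSE)
  X <- .design(data, predictors)
  y <- data[[response]]
  qr_x <- qr(X)
  h <- rowSums(qr.Q(qr_x)^2)
  if (any(h >= 1 - 1e-12)) {
    stop("a leave-one-out fold is rank deficient", call. = FALSE)
  }
  e <- stats::residuals(stats::lsfit(X, y, intercept = FALSE))
  press <- sum((e / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' Two-group linear discriminant analysis
#'
#' Fits the canonical discriminant axis separating two classes, with the
#' conventions of classic QSAR discriminant work: unstandardized
#' coefficients scaled so the pooled within-group variance of the scores is
#' 1, intercept centring the scores on the weighted grand mean, Wilks'
#' lambda from the canonical eigenvalue (equivalently `det(W)/det(T)`),
#' and per-sample posteriors from Mahalanobis distances to the class
#' centroids with equal priors.
#'
#' @param data A data frame with descriptor columns and a class column.
#' @param class Name of the class column; it must contain exactly two
#'   levels. `positive` names the class whose scores are oriented upward.
#' @param predictors Character vector of descriptor column names.
#' @param positive Level treated as the positive (active) class; defaults
#'   to `"A"` if present, else the first level.
#' @return An object of class `qsar_lda`: `model` (a [linear_model] of
#'   kind discriminant), `stats` (`wilks_lambda`, `eigenvalue`, `n`) and
#'   `posteriors` (per-sample scores, Mahalanobis distances, posterior
#'   probability of the positive class, predicted class).
#' @export
fit_lda <- function(data, class, predictors, positive = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot(class %in% names(data))
  labels <- as.character(data[[class]])
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("need exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- if ("A" %in% lev) "A" else lev[1]
  if (!positive %in% lev) stop("`positive` is not a class level",
                               call. = FALSE)
  negative <- setdiff(lev, positive)
  X <- as.matrix(data[predictors])
  n <- nrow(X)
  g1 <- labels == positive
  if (!any(g1) || all(g1)) stop("both classes must be non-empty",
                                call. = FALSE)

  m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[!g1, , drop = FALSE])
  center <- function(M) sweep(M, 2, colMeans(M))
  W <- crossprod(center(X[g1, , drop = FALSE])) +
       crossprod(center(X[!g1, , drop = FALSE]))
  Tm <- crossprod(center(X))
  Sw <- W / (n - 2)
  ok <- tryCatch({solve(Sw); TRUE}, error = function(e) FALSE)
  if (!ok) stop("pooled within-class covariance is singular", call. = FALSE)

  raw <- solve(Sw, m1 - m0)
  # scale so pooled within-group score variance is 1
  b <- raw / sqrt(drop(t(raw) %*% Sw %*% raw))
  intercept <- -drop(colMeans(X) %*% b)
  scores <- drop(X %*% b) + intercept
  # canonical eigenvalue of W^{-1} B along the axis; lambda = 1/(1 + eig)
  B <- Tm - W
  eig <- drop(t(b) %*% B %*% b) / drop(t(b) %*% W %*% b)
  wilks <- 1 / (1 + eig)

  d1 <- stats::mahalanobis(X, m1, Sw)
  d0 <- stats::mahalanobis(X, m0, Sw)
  p1 <- exp(-d1 / 2) / (exp(-d1 / 2) + exp(-d0 / 2))
  posteriors <- tibble::tibble(
    score = scores,
    mahal_positive = d1,
    mahal_negative = d0,
    posterior = p1,
    predicted = ifelse(d1 <= d0, positive, negative)
  )
  model <- linear_model("discriminant", intercept = intercept,
                        coefficients = stats::setNames(b, predictors))
  structure(
    list(model = model,
         stats = tibble::tibble(wilks_lambda = wilks, eigenvalue = eig,
                                n = n),
         posteriors = posteriors,
         classes = c(positive = positive, negative = negative)),
    class = "qsar_lda"
  )
}

#' @export
print.qsar_lda <- function(x, ...) {
  print(x$model)
  acc <- mean(x$posteriors$predicted ==
                ifelse(x$posteriors$mahal_positive <=
                         x$posteriors$mahal_negative,
                       x$classes[["positive"]], x$classes[["negative"]]))
  cat(sprintf("  n = %d, Wilks' lambda = %.3f\n", x$stats$n,
              x$stats$wilks_lambda))
  invisible(x)
}

#' @export
glance.qsar_lda <- function(x, ...) {
  x$stats
}

#' @export
tidy.qsar_lda <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$model$coefficients)),
    estimate = c(x$model$intercept, unname(x$model$coefficients))
  )
}

#' Stepwise descriptor selection by partial F
#'
#' Greedy forward selection with backward elimination, the procedure
#' classical QSAR packages use to pick descriptors: at each step the
#' candidate with the largest partial F enters if it exceeds `f_enter`,
#' then any included descriptor whose partial F has dropped below
#' `f_remove` leaves. For `mode = "lda"` the two-group discriminant
#' problem is handled through the equivalent regression on a class
#' indicator. Ties break alphabetically; candidates that would make the
#' design rank deficient are skipped.
#'
#' @param data A data frame of candidate descriptor columns plus the
#'   target.
#' @param target Name of the response (numeric for `"ols"`, two-level for
#'   `"lda"`).
#' @param candidates Character vector of candidate descriptor names;
#'   defaults to every numeric column except the target.
#' @param mode `"ols"` or `"lda"`.
#' @param f_enter,f_remove F-to-enter and F-to-remove thresholds
#'   (`f_enter > f_remove`).
#' @param max_steps Safety cap on iterations.
#' @return Character vector of selected descriptor names (possibly empty).
#' @export
stepwise_select <- function(data, target, candidates = NULL,
                            mode = c("ols", "lda"),
                            f_enter = 3.84, f_remove = 2.71,
                            max_steps = 100L) {
  mode <- match.arg(mode)
  stopifnot(f_enter > f_remove)
  data <- tibble::as_tibble(data)
  if (is.null(candidates)) {
    candidates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          target)
  }
  candidates <- sort(candidates)
  y <- if (mode == "lda") {
    lev <- sort(unique(as.character(data[[target]])))
    if (length(lev) != 2) stop("lda mode needs two classes", call. = FALSE)
    as.numeric(as.character(data[[target]]) == lev[2])
  } else {
    data[[target]]
  }
  n <- nrow(data)
  X_all <- as.matrix(data[candidates])

  rss <- function(cols) {
    X <- cbind(1, X_all[, cols, drop = FALSE])
    if (qr(X)$rank < ncol(X)) return(NA_real_)
    sum(stats::lsfit(X, y, intercept = FALSE)$residuals^2)
  }
  partial_f <- function(rss_small, rss_big, df_big) {
    (rss_small - rss_big) / (rss_big / df_big)
  }

  selected <- character(0)
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    # forward
    rss0 <- rss(selected)
    pool <- setdiff(candidates, selected)
    if (length(pool) && n > length(selected) + 2) {
      fs <- vapply(pool, function(v) {
        r <- rss(c(selected, v))
        df <- n - length(selected) - 2
        if (is.na(r) || df <= 0 || r <= 0) return(-Inf)
        partial_f(rss0, r, df)
      }, numeric(1))
      best <- which.max(fs)  # ties: first alphabetically (pool is sorted)
      if (is.finite(fs[best]) && fs[best] > f_enter) {
        selected <- sort(c(selected, pool[best]))
        changed <- TRUE
      }
    }
    # backward
    if (length(selected) > 1) {
      repeat {
        rss_full <- rss(selected)
        df <- n - length(selected) - 1
        fs <- vapply(selected, function(v) {
          partial_f(rss(setdiff(selected, v)), rss_full, df)
        }, numeric(1))
        worst <- which.min(fs)
        if (fs[worst] < f_remove) {
          selected <- selected[-worst]
          changed <- TRUE
        } else break
      }
    }
    if (!changed) break
  }
  selected
}
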