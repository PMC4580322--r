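#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). Errors on a
#' constant vector, where the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for a constant vector")
  cor(x, y, method = "spearman")
}

#' Screen predictor pairs for collinearity
#'
#' Lists every unordered predictor pair with |Spearman rho| strictly above
#' the cutoff; such pairs are barred from co-occurring in any fitted model
#' subset.
#'
#' @param predictors A tibble / data frame of numeric predictor columns (>= 2).
#' @param cutoff Absolute-rho cutoff (default 0.8, strict inequality).
#' @return A tibble with columns `var1`, `var2`, `rho` (possibly 0 rows).
#' @export
collinearity_screen <- function(predictors, cutoff = 0.8) {
  stopifnot(ncol(predictors) >= 2)
  nms <- names(predictors)
  pairs <- combn(nms, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    tibble::tibble(var1 = v1, var2 = v2,
                   rho = spearman_rho(predictors[[v1]], predictors[[v2]]))
  })
  out[abs(out$rho) > cutoff, , drop = FALSE]
}

#' Ordinary least squares with comparison AIC
#'
#' Fits `y ~ X` with an intercept and returns the coefficients, residual sum
#' of squares, and the Gaussian profile-likelihood AIC
#' `n * log(RSS / n) + 2 * (p + 2)` (the +2 counts the intercept and the
#' error variance; additive constants are omitted consistently, so AIC
#' differences between subsets are unaffected).
#'
#' @param y Response vector.
#' @param X A tibble / data frame of predictors (possibly zero columns for
#'   the intercept-only model).
#' @return A list: `coefficients`, `rss`, `aic`, `n`, `p`.
#' @export
fit_ols <- function(y, X) {
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) abort("need n > p + 1 observations")
  df <- if (p > 0) data.frame(y = y, X) else data.frame(y = y)
  fit <- lm(y ~ ., data = df)
  if (anyNA(coef(fit))) {
    abort(paste0("rank-deficient design; drop collinear column(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  rss <- sum(fit$residuals^2)
  if (rss <= 1e-16 * max(1, sum(y^2))) {
    abort("degenerate perfect fit: RSS is (numerically) zero, AIC unbounded below")
  }
  list(coefficients = coef(fit), rss = rss,
       aic = n * log(rss / n) + 2 * (p + 2), n = n, p = p)
}

#' All-subsets linear-model selection by AIC
#'
#' Fits every admissible predictor subset (including the intercept-only
#' model), excluding any subset that contains a collinear pair flagged by
#' [collinearity_screen()], and selects the subset with the lowest AIC. The
#' full fit table is retained for audit.
#'
#' @param data A data frame holding the response and predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of candidate predictor columns.
#' @param cutoff Collinearity cutoff passed to [collinearity_screen()].
#' @return An object of class `aic_selection`: list with `fits` (tibble: one
#'   row per subset with predictors, p, rss, aic, coefficients list-column),
#'   `best` (the lowest-AIC row), `excluded_pairs`.
#' @export
all_subsets_aic <- function(data, response, predictors, cutoff = 0.8) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  y <- data[[response]]
  excl <- if (length(predictors) >= 2) {
    collinearity_screen(data[predictors], cutoff = cutoff)
  } else tibble::tibble(var1 = character(), var2 = character(), rho = double())
  subsets <- unlist(lapply(0:length(predictors), function(k) {
    if (k == 0) list(character(0)) else
      apply(combn(predictors, k), 2, identity, simplify = FALSE)
  }), recursive = FALSE)
  admissible <- purrr::keep(subsets, function(s) {
    if (nrow(excl) == 0) return(TRUE)
    !any(excl$var1 %in% s & excl$var2 %in% s)
  })
  if (length(admissible) == 0) abort("no admissible predictor subset")
  fits <- purrr::map_dfr(admissible, function(s) {
    f <- fit_ols(y, data[s])
    tibble::tibble(predictors = paste(s, collapse = "+"),
                   p = f$p, rss = f$rss, aic = f$aic,
                   coefficients = list(f$coefficients))
  })
  best <- fits[which.min(fits$aic), , drop = FALSE]
  structure(list(fits = fits, best = best, excluded_pairs = excl,
                 response = response),
            class = "aic_selection")
}

#' @export
print.aic_selection <- function(x, ...) {
  cat(sprintf("<aic_selection> response %s: %d subset(s) fitted, best = {%s} (AIC %.2f)\n",
              x$response, nrow(x$fits),
              ifelse(x$best$predictors == "", "intercept only", x$best$predictors),
              x$best$aic))
  invisible(x)
}

#' @export
tidy.aic_selection <- function(x, ...) {
  dplyr::arrange(x$fits, .data$aic)
}

#' @export
glance.aic_selection <- function(x, ...) {
  tibble::tibble(best_predictors = x$best$predictors, best_aic = x$best$aic,
                 n_subsets = nrow(x$fits), n_excluded_pairs = nrow(x$excluded_pairs))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Mann-Whitney U with mid-ranks: exact two-sided p by enumeration when
#' n + m <= 12 and there are no ties, otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param a,b Numeric samples (non-empty).
#' @return A one-row tibble: `statistic` (U for sample `a`), `p_value`,
#'   `exact` (logical), `n`, `m`.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("empty sample")
  if (length(unique(c(a, b))) == 1) { # fully tie-saturated: no evidence either way
    return(tibble::tibble(statistic = length(a) * length(b) / 2, p_value = 1,
                          exact = FALSE, n = length(a), m = length(b)))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic), p_value = min(ht$p.value, 1),
                 exact = exact, n = length(a), m = length(b))
}

#' Tukey HSD (Tukey-Kramer) pairwise comparisons
#'
#' All-pairs comparison of group means after a one-way ANOVA, with the
#' Tukey-Kramer unequal-n standard error and adjusted p-values from the
#' studentized-range distribution with N - k degrees of freedom.
#'
#' @param data A data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column (>= 3 groups, each n >= 2).
#' @return A tibble: `group1`, `group2`, `diff` (mean2 - mean1), `q`
#'   (studentized range statistic), `p_adj`; attributes `df` and `mse`.
#' @export
tukey_hsd <- function(data, value, group) {
  g <- factor(data[[group]])
  y <- data[[value]]
  k <- nlevels(g)
  if (k < 3) abort("fewer than 3 groups: use a two-sample test instead")
  ns <- table(g)
  if (any(ns < 2)) abort("every group needs n >= 2")
  N <- length(y)
  fit <- aov(y ~ g)
  mse <- sum(fit$residuals^2) / (N - k)
  means <- tapply(y, g, mean)
  pairs <- combn(levels(g), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    d <- means[[g2]] - means[[g1]]
    se <- sqrt(mse / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- abs(d) / se
    tibble::tibble(group1 = g1, group2 = g2, diff = d, q = q,
                   p_adj = ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE))
  })
  attr(out, "df") <- N - k
  attr(out, "mse") <- mse
  out
}
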