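#' Spearman rank-correlation matrix
#'
#' Pairwise Spearman correlations (mid-ranks for ties, pairwise deletion
#' of missing values) between all numeric columns of a subject-level
#' table, with two-sided p values from the t approximation.
#'
#' @param data data frame of subject-level variables; non-numeric columns
#'   are dropped.
#' @param min_pairs minimum number of complete pairs required per cell
#'   (default 4); cells with fewer pairs, or involving a constant column,
#'   are `NA`.
#' @return An object of class `spearman_matrix`: list of matrices `rho`,
#'   `p` and `n`.
#' @export
spearman_matrix <- function(data, min_pairs = 4) {
  num <- data[vapply(data, is.numeric, logical(1))]
  vars <- names(num)
  m <- length(vars)
  if (m < 2) stop("need at least two numeric columns")
  rho <- p <- n <- matrix(NA_real_, m, m, dimnames = list(vars, vars))
  for (i in seq_len(m)) {
    for (j in i:m) {
      ok <- stats::complete.cases(num[[i]], num[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < min_pairs) next
      x <- num[[i]][ok]; y <- num[[j]][ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      if (i == j) {
        rho[i, j] <- 1; p[i, j] <- NA
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = p, n = n), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat("Spearman rank correlations (", nrow(x$rho), " variables)\n", sep = "")
  print(round(x$rho, digits))
  invisible(x)
}

# build the standardized design; group-like 2-level predictors are coded
# 0/1 before z-scoring so their coefficients are comparable
standardize_columns <- function(df) {
  out <- df
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) != 2) {
        stop("categorical predictor '", nm, "' must have exactly 2 levels")
      }
      v <- as.numeric(as.character(v) == lev[2])
    }
    out[[nm]] <- zscore(as.numeric(v), nm)
  }
  out
}

#' Univariate (multiple) regression of one cosinor parameter
#'
#' OLS of a single z-scored cosinor parameter on a z-scored predictor
#' (two-level group labels are coded 0/1 first), optionally adjusting for
#' the standard confounder set (age, BMI, step count, and available
#' segment count as cardiac data-quality proxy). Reports standardized
#' coefficients with both small-sample t and large-sample z inference.
#' Complete cases only; the number of rows used is recorded.
#'
#' @param data subject-level data frame.
#' @param outcome name of the outcome column (one cosinor parameter).
#' @param predictor name of the predictor of interest.
#' @param covariates character vector of confounder columns used when
#'   `adjust = TRUE`.
#' @param adjust include the covariates? (default `FALSE`).
#' @return An object of class `association_result` with one row per
#'   coefficient: standardized estimate, SE, t, p (t-based), z-based p,
#'   plus `n`, `outcome`, `adjusted`.
#' @export
fit_univariate_models <- function(data, outcome, predictor,
                                  covariates = c("age", "bmi", "step_count",
                                                 "valid_segments"),
                                  adjust = FALSE) {
  preds <- c(predictor, if (adjust) covariates)
  miss <- setdiff(c(outcome, preds), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[c(outcome, preds)])
  df <- data[cc, c(outcome, preds)]
  X <- standardize_columns(df[preds])
  y <- zscore(as.numeric(df[[outcome]]), outcome)
  dm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qx <- qr(dm)
  if (qx$rank < ncol(dm)) {
    drop_cols <- colnames(dm)[qx$pivot[(qx$rank + 1):ncol(dm)]]
    stop("collinear design; offending column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  fit <- stats::lm.fit(dm, y)
  n <- nrow(dm); pcol <- ncol(dm)
  sigma2 <- sum(fit$residuals^2) / (n - pcol)
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtXinv))
  est <- fit$coefficients
  tstat <- est / se
  res <- data.frame(
    term = colnames(dm), estimate = unname(est), se = unname(se),
    statistic = unname(tstat),
    p_t = 2 * stats::pt(abs(tstat), n - pcol, lower.tail = FALSE),
    p_z = 2 * stats::pnorm(abs(tstat), lower.tail = FALSE),
    row.names = NULL)
  structure(list(model = "univariate_ols", outcome = outcome,
                 predictor = predictor, adjusted = adjust, n = n,
                 coefficients = res),
            class = "association_result")
}

#' Multivariate regression of the cosinor parameter triplet
#'
#' Regression of (MESOR, amplitude, acrophase) jointly on a shared
#' predictor set: with identical regressors across equations the
#' coefficient estimates equal equation-by-equation OLS, so each outcome
#' is fitted separately and reported together with large-sample z
#' statistics on the standardized coefficients (small-sample t p values
#' are reported alongside). Subjects missing any of the three outcomes are
#' dropped, with a message.
#'
#' @param data subject-level data frame.
#' @param outcomes character vector of the three outcome columns.
#' @param predictor name of the predictor of interest.
#' @param covariates confounders added when `adjust = TRUE`.
#' @param adjust include the covariates? (default `FALSE`).
#' @return An `association_result` whose `coefficients` table has one row
#'   per outcome x term.
#' @export
fit_multivariate_model <- function(data, outcomes, predictor,
                                   covariates = c("age", "bmi", "step_count",
                                                  "valid_segments"),
                                   adjust = FALSE) {
  if (length(outcomes) < 2) stop("'outcomes' must name several columns")
  preds <- c(predictor, if (adjust) covariates)
  miss <- setdiff(c(outcomes, preds), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[c(outcomes, preds)])
  if (any(!cc)) {
    message("dropping ", sum(!cc), " subject(s) with incomplete outcome/predictor data")
  }
  df <- data[cc, , drop = FALSE]
  per_eq <- lapply(outcomes, function(oc) {
    r <- fit_univariate_models(df, oc, predictor, covariates, adjust)
    cbind(outcome = oc, r$coefficients)
  })
  tab <- do.call(rbind, per_eq)
  structure(list(model = "multivariate_ols", outcome = outcomes,
                 predictor = predictor, adjusted = adjust, n = sum(cc),
                 coefficients = tab),
            class = "association_result")
}

#' @export
print.association_result <- function(x, digits = 3, ...) {
  cat(x$model, if (x$adjusted) "(adjusted)" else "(unadjusted)",
      "- n =", x$n, "\n")
  cat("outcome:", paste(x$outcome, collapse = ", "),
      "  predictor:", x$predictor, "\n")
  tab <- x$coefficients
  numcols <- vapply(tab, is.numeric, logical(1))
  tab[numcols] <- lapply(tab[numcols], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg adjustment helper for association tables
#'
#' Off by default in all analyses (exploratory reporting); call this on an
#' [association_result] to append BH-adjusted p values.
#'
#' @param result an `association_result`.
#' @param column which p-value column to adjust (default `"p_z"`).
#' @return The result with a `p_adj` column added.
#' @export
adjust_pvalues <- function(result, column = "p_z") {
  stopifnot(inherits(result, "association_result"))
  keep <- result$coefficients$term != "(Intercept)"
  p <- result$coefficients[[column]]
  result$coefficients$p_adj <- NA_real_
  result$coefficients$p_adj[keep] <- stats::p.adjust(p[keep], method = "BH")
  result
}
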