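# Hormone -> topology multilinear model with leave-one-out
# cross-validation, Spearman correlation screen with FDR, and variance
# inflation factor diagnostics.

#' Specify the multilinear model
#'
#' @param response name of the response column (a topology delta).
#' @param predictors names of the hormone-delta predictor columns.
#' @param nuisance names of the nuisance covariate columns (contrast
#'   indicator for the repeated measures, age, education, cycle length).
#' @param standardize_predictors z-score the predictor columns before
#'   fitting (coefficient signs unaffected).
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(response = "response",
                       predictors = c("d_estradiol", "d_progesterone",
                                      "d_lh", "d_fsh"),
                       nuisance = c("contrast", "age", "education",
                                    "cycle_length"),
                       standardize_predictors = TRUE) {
  structure(list(response = response, predictors = predictors,
                 nuisance = nuisance,
                 standardize_predictors = standardize_predictors),
            class = "model_spec")
}

# design matrix (with intercept) + response; errors name collinear columns
.model_design <- function(spec, data) {
  cols <- c(spec$predictors, spec$nuisance)
  missing <- setdiff(c(spec$response, cols), names(data))
  if (length(missing)) {
    stop("data lacks column(s): ", paste(missing, collapse = ", "))
  }
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  for (cn in cols) {
    v <- data[[cn]]
    if (is.character(v) || is.factor(v)) {
      v <- as.numeric(factor(v)) - 1  # two-level indicator
    }
    if (cn %in% spec$predictors && spec$standardize_predictors) {
      v <- as.vector(scale(v))
    }
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cn
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(X = X, y = data[[spec$response]])
}

#' Fit the multilinear model by ordinary least squares
#'
#' @param spec a \code{\link{model_spec}}.
#' @param data data.frame with one row per observation (subject x
#'   contrast).
#' @return object of class \code{model_fit}: \code{coefficients} table
#'   (estimate, se, t, p per term), \code{r_squared}, \code{fitted},
#'   \code{residuals}, \code{sigma}, \code{df_residual}, plus the design
#'   internals used by \code{\link{loocv}}.
#' @export
fit_ols <- function(spec, data) {
  d <- .model_design(spec, data)
  n <- nrow(d$X)
  p <- ncol(d$X)
  if (n <= p + 2) stop("need more observations than terms + 2")
  fit <- stats::lm.fit(d$X, d$y)
  res <- fit$residuals
  df_res <- n - p
  sigma2 <- sum(res^2) / df_res
  XtXinv <- chol2inv(chol(crossprod(d$X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- fit$coefficients / se
  pval <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)
  ss_tot <- sum((d$y - mean(d$y))^2)
  structure(list(
    spec = spec,
    coefficients = data.frame(term = colnames(d$X),
                              estimate = unname(fit$coefficients),
                              se = unname(se), t = unname(tval),
                              p = unname(pval), stringsAsFactors = FALSE),
    r_squared = 1 - sum(res^2) / ss_tot,
    fitted = fit$fitted.values, residuals = res,
    sigma = sqrt(sigma2), df_residual = df_res,
    X = d$X, y = d$y), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit: %d obs, %d terms, R^2 = %.3f\n",
              length(x$y), nrow(x$coefficients), x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Leave-one-out cross-validation of the multilinear model
#'
#' Refits the model once per left-out observation and predicts it from the
#' remaining n - 1 rows. Reports the PRESS-based cross-validated R^2
#' (1 - PRESS/SS_tot), the squared-correlation variant, and standardized
#' prediction residuals (observed minus predicted, divided by their SD).
#'
#' @param spec a \code{\link{model_spec}}.
#' @param data data.frame of observations.
#' @param unit \code{"row"} (default: one observation left out at a time)
#'   or \code{"subject"} (both contrast rows of a subject left out
#'   together; requires a \code{subject} column).
#' @return list with \code{predictions}, \code{r2_press},
#'   \code{r2_correlation}, \code{std_residuals}, \code{press}.
#' @export
loocv <- function(spec, data, unit = c("row", "subject")) {
  unit <- match.arg(unit)
  d <- .model_design(spec, data)
  n <- nrow(d$X)
  p <- ncol(d$X)
  if (n < p + 3) stop("need n >= terms + 3 for cross-validation")
  folds <- if (unit == "row") as.list(seq_len(n)) else
    split(seq_len(n), data$subject)
  pred <- numeric(n)
  for (hold in folds) {
    fit <- stats::lm.fit(d$X[-hold, , drop = FALSE], d$y[-hold])
    pred[hold] <- d$X[hold, , drop = FALSE] %*% fit$coefficients
  }
  err <- d$y - pred
  press <- sum(err^2)
  ss_tot <- sum((d$y - mean(d$y))^2)
  sd_err <- sd(err)
  # an (all but) exact fit has no meaningful residual scale
  degenerate <- sd_err <= 1e-10 * max(sd(d$y), .Machine$double.eps)
  list(predictions = pred,
       r2_press = 1 - press / ss_tot,
       r2_correlation = suppressWarnings(cor(d$y, pred))^2,
       std_residuals = if (degenerate) err * 0 else err / sd_err,
       press = press)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; two-sided p by exact permutation for
#' n <= 9 and by the t approximation above.
#'
#' @param x,y numeric vectors (n >= 4, non-constant).
#' @return list with \code{rho} and \code{p}.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("Spearman correlation undefined for constant input")
  }
  r <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 9))
  list(rho = unname(r$estimate), p = r$p.value)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j is the coefficient of
#' determination of column j regressed on all other columns (with
#' intercept). Values near 1 indicate no multicollinearity.
#'
#' @param variables data.frame or matrix with >= 3 non-constant numeric
#'   columns.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(variables) {
  X <- as.matrix(variables)
  k <- ncol(X)
  if (k < 2) stop("need at least two columns")
  if (nrow(X) <= k + 1) stop("need n > columns + 1")
  if (any(apply(X, 2, function(c) diff(range(c)) == 0))) {
    stop("constant column")
  }
  out <- numeric(k)
  for (j in seq_len(k)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-12) {
      stop("perfect collinearity: VIF infinite for column ",
           colnames(X)[j] %||% j)
    }
    out[j] <- 1 / (1 - r2)
  }
  names(out) <- colnames(X)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spearman correlation screen with FDR
#'
#' Runs the Spearman correlation for every declared variable pair within
#' each phase contrast and adjusts p-values by Benjamini-Hochberg within
#' the declared family (all pairs x contrasts screened together).
#'
#' @param delta_table output of \code{\link{compute_deltas}}.
#' @param pairs data.frame with columns \code{x}, \code{y} naming delta
#'   variables.
#' @param contrasts contrasts to screen (default both).
#' @param family family label recorded in the output.
#' @return data.frame with columns \code{family}, \code{contrast},
#'   \code{x}, \code{y}, \code{n}, \code{rho}, \code{p}, \code{p_fdr}.
#' @export
correlation_screen <- function(delta_table, pairs,
                               contrasts = c("follicular", "luteal"),
                               family = "screen") {
  rows <- list()
  for (ctr in contrasts) {
    dt <- delta_table[delta_table$contrast == ctr, ]
    for (k in seq_len(nrow(pairs))) {
      xv <- dt[dt$variable == pairs$x[k], c("subject", "delta")]
      yv <- dt[dt$variable == pairs$y[k], c("subject", "delta")]
      m <- merge(xv, yv, by = "subject")
      sc <- spearman_cor(m$delta.x, m$delta.y)
      rows[[length(rows) + 1L]] <- data.frame(
        family = family, contrast = ctr, x = pairs$x[k], y = pairs$y[k],
        n = nrow(m), rho = sc$rho, p = sc$p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_fdr <- as.vector(bh_fdr(res$p))
  res
}
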