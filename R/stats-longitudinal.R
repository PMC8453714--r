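# Three-time-point statistical plan: Shapiro-Wilk normality gate, hormone
# one-way ANOVA with paired-t post hocs, Friedman tests on topology with
# Wilcoxon post hocs, Benjamini-Hochberg correction per declared family,
# and per-contrast delta computation.

stat_result <- function(test, statistic, df, p, ...) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p = unname(p), ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- if (length(x$df) > 1) paste(round(x$df, 2), collapse = ", ") else
    round(x$df, 2)
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n",
              x$test, x$statistic, dfs, x$p))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Normality gate logged alongside parametric tests.
#'
#' @param x numeric sample, 3 <= n <= 5000, non-constant.
#' @return \code{stat_result} with the W statistic.
#' @export
shapiro_wilk <- function(x) {
  if (diff(range(x)) == 0) stop("Shapiro-Wilk undefined for constant sample")
  r <- stats::shapiro.test(x)
  stat_result("shapiro_wilk", r$statistic, NA_real_, r$p.value)
}

#' One-way ANOVA from raw groups
#'
#' @param groups list of numeric vectors, one per group (k >= 2, each
#'   n >= 2).
#' @return \code{stat_result} with the F statistic and df = (k-1, N-k).
#' @export
anova_oneway <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  ns <- lengths(groups)
  if (any(ns < 2)) stop("every group needs n >= 2")
  anova_from_summary(vapply(groups, mean, 0), vapply(groups, sd, 0), ns)
}

#' One-way ANOVA from printed summary statistics
#'
#' Computes the classical F statistic directly from per-group means, SDs
#' and sizes: F = MSB/MSW with MSB the between-group and MSW the pooled
#' within-group mean square. Algebraically identical to the raw-data
#' one-way ANOVA, and usable on published tables.
#'
#' @param means,sds,ns per-group mean, standard deviation, and size.
#' @return \code{stat_result} with F and df = (k-1, N-k).
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  stopifnot(length(sds) == k, length(ns) == k, k >= 2, all(ns >= 2))
  if (all(sds == 0)) stop("zero within-group variance")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  msb <- sum(ns * (means - grand)^2) / (k - 1)
  msw <- sum((ns - 1) * sds^2) / (N - k)
  f <- msb / msw
  stat_result("anova_oneway", f, c(k - 1, N - k),
              pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Paired t test
#'
#' @param x,y paired samples of equal length (n >= 2), differences
#'   non-constant.
#' @return \code{stat_result} with t and df = n - 1 (two-sided p).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  if (sd(d) == 0) stop("paired t undefined: differences have zero variance")
  r <- stats::t.test(x, y, paired = TRUE)
  stat_result("paired_t", r$statistic, r$parameter, r$p.value)
}

# Friedman chi-squared statistic on a matrix of within-subject mid-ranks.
.friedman_chisq <- function(ranks) {
  n <- nrow(ranks)
  k <- ncol(ranks)
  12 / (n * k * (k + 1)) * sum(colSums(ranks)^2) - 3 * n * (k + 1)
}

# Exact permutation distribution of the k=3 Friedman statistic: dynamic
# programme over the joint column rank sums (S1, S2); each subject
# contributes one of the 3! equally likely rank rows under H0.
.friedman_exact_p <- function(n, observed) {
  rows <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  span <- 3 * n
  dist <- matrix(0, span, span)  # [S1, S2] -> number of assignments
  for (r in 1:6) {
    dist[rows[r, 1], rows[r, 2]] <- dist[rows[r, 1], rows[r, 2]] + 1
  }
  if (n > 1) {
    for (m in 2:n) {
      nxt <- matrix(0, span, span)
      nz <- which(dist > 0, arr.ind = TRUE)
      for (r in 1:6) {
        i <- nz[, 1] + rows[r, 1]
        j <- nz[, 2] + rows[r, 2]
        nxt[cbind(i, j)] <- nxt[cbind(i, j)] + dist[nz]
      }
      dist <- nxt
    }
  }
  nz <- which(dist > 0, arr.ind = TRUE)
  s1 <- nz[, 1]; s2 <- nz[, 2]; s3 <- 6 * n - s1 - s2
  stats <- 12 / (n * 3 * 4) * (s1^2 + s2^2 + s3^2) - 3 * n * 4
  sum(dist[nz][stats >= observed - 1e-9]) / 6^n
}

#' Friedman test for repeated measures
#'
#' Rank-based comparison of k conditions measured on the same n subjects:
#' chi-squared = 12/(n k (k+1)) * sum(R_j^2) - 3 n (k+1) on within-subject
#' mid-ranks, df = k - 1. For three untied conditions with n <= 12
#' subjects the p-value is exact (full permutation distribution over the
#' 6^n equally likely rank assignments); otherwise the chi-squared
#' approximation is used.
#'
#' @param values n x k numeric matrix, rows = subjects, columns =
#'   conditions (sessions).
#' @return \code{stat_result} with the chi-squared statistic; the
#'   \code{method} field records whether the p-value is exact.
#' @export
friedman_test3 <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2) stop("Friedman test needs n >= 2 subjects")
  if (k < 2) stop("Friedman test needs k >= 2 conditions")
  ranks <- t(apply(values, 1, rank))
  chisq <- .friedman_chisq(ranks)
  no_ties <- all(apply(values, 1, function(r) !anyDuplicated(r)))
  if (k == 3 && n <= 12 && no_ties) {
    p <- .friedman_exact_p(n, chisq)
    method <- "exact"
  } else {
    p <- pchisq(chisq, k - 1, lower.tail = FALSE)
    method <- "chisq_approx"
  }
  stat_result("friedman", chisq, k - 1, p, method = method)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's original rule); the two-sided
#' p-value is exact for n <= 25 remaining pairs and uses the normal
#' approximation with continuity correction above.
#'
#' @param x,y paired samples.
#' @return \code{stat_result}; the statistic is V = W+, the sum of ranks
#'   of positive differences, with \code{n_used} the pairs retained.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("all differences are zero")
  if (length(d) < 5) stop("need >= 5 nonzero differences")
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  r <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  stat_result("wilcoxon_signed_rank", r$statistic, NA_real_, r$p.value,
              n_used = length(d))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1.
#'
#' @param p vector of raw p-values in [0, 1].
#' @param family optional family label recorded with the result.
#' @return numeric vector of adjusted p-values (>= raw, same order).
#' @export
bh_fdr <- function(p, family = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p, method = "BH")
  if (!is.null(family)) attr(adj, "family") <- family
  adj
}

#' Per-contrast deltas from a long study table
#'
#' Computes the two phase contrasts for every subject x variable: the
#' follicular contrast (second minus first session) and the luteal
#' contrast (third minus second session). Subjects missing a session for a
#' variable are dropped with a warning.
#'
#' @param study_table long data.frame with columns \code{subject},
#'   \code{session}, \code{variable}, \code{value}.
#' @param sessions the three ordered session labels.
#' @return data.frame with columns \code{subject}, \code{contrast}
#'   (\code{"follicular"} = T2 - T1, \code{"luteal"} = T3 - T2),
#'   \code{variable}, \code{delta}.
#' @export
compute_deltas <- function(study_table, sessions = c("T1", "T2", "T3")) {
  stopifnot(all(c("subject", "session", "variable", "value") %in%
                  names(study_table)))
  if (length(sessions) != 3) stop("delta computation assumes three sessions")
  out <- list()
  dropped <- 0L
  for (v in unique(study_table$variable)) {
    sv <- study_table[study_table$variable == v, ]
    w <- reshape(sv[, c("subject", "session", "value")], idvar = "subject",
                 timevar = "session", direction = "wide")
    cols <- paste0("value.", sessions)
    missing_cols <- setdiff(cols, names(w))
    if (length(missing_cols)) {
      warning("variable ", v, " missing entire session(s): ",
              paste(sub("value.", "", missing_cols, fixed = TRUE),
                    collapse = ", "), "; variable skipped")
      next
    }
    complete <- stats::complete.cases(w[, cols])
    dropped <- dropped + sum(!complete)
    w <- w[complete, ]
    out[[length(out) + 1L]] <- rbind(
      data.frame(subject = w$subject, contrast = "follicular", variable = v,
                 delta = w[[cols[2]]] - w[[cols[1]]]),
      data.frame(subject = w$subject, contrast = "luteal", variable = v,
                 delta = w[[cols[3]]] - w[[cols[2]]]))
  }
  if (dropped > 0) {
    warning(dropped, " subject-variable trajectories dropped (missing session)")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Friedman + Wilcoxon session comparison for a set of variables
#'
#' Applies the Friedman test across the three sessions for every variable,
#' adjusts the Friedman p-values by Benjamini-Hochberg within the declared
#' family, and runs the three pairwise Wilcoxon post hocs (reported
#' unadjusted) for variables surviving the gate.
#'
#' @param study_table long data.frame (\code{subject}, \code{session},
#'   \code{variable}, \code{value}).
#' @param variables variables to test (default all in the table).
#' @param sessions three ordered session labels.
#' @param family family label for the FDR adjustment.
#' @param alpha significance level gating the post hocs.
#' @return data.frame with one row per variable: chi-squared statistic,
#'   df, p, p_fdr, and the three post hoc Wilcoxon p-values (NA when the
#'   Friedman test does not survive the gate).
#' @export
session_comparison <- function(study_table, variables = NULL,
                               sessions = c("T1", "T2", "T3"),
                               family = "topology", alpha = 0.05) {
  if (is.null(variables)) variables <- unique(study_table$variable)
  rows <- lapply(variables, function(v) {
    sv <- study_table[study_table$variable == v, ]
    w <- reshape(sv[, c("subject", "session", "value")], idvar = "subject",
                 timevar = "session", direction = "wide")
    mat <- as.matrix(w[, paste0("value.", sessions)])
    fr <- friedman_test3(mat)
    data.frame(family = family, variable = v, test = "friedman",
               statistic = fr$statistic, df = fr$df, p = fr$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- as.vector(bh_fdr(res$p))
  post <- matrix(NA_real_, nrow(res), 3,
                 dimnames = list(NULL, c("p_t1_t2", "p_t2_t3", "p_t1_t3")))
  for (k in seq_len(nrow(res))) {
    if (is.na(res$p_fdr[k]) || res$p_fdr[k] >= alpha) next
    sv <- study_table[study_table$variable == res$variable[k], ]
    w <- reshape(sv[, c("subject", "session", "value")], idvar = "subject",
                 timevar = "session", direction = "wide")
    v1 <- w[[paste0("value.", sessions[1])]]
    v2 <- w[[paste0("value.", sessions[2])]]
    v3 <- w[[paste0("value.", sessions[3])]]
    post[k, ] <- c(wilcoxon_signed_rank(v1, v2)$p,
                   wilcoxon_signed_rank(v2, v3)$p,
                   wilcoxon_signed_rank(v1, v3)$p)
  }
  cbind(res, as.data.frame(post))
}
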