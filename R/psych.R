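# Psychological scores and scalar latent effect-size channels.
#
# The only injected psychological effect is the luteal-phase association
# between the estradiol change and the environmental-mastery change: the
# mastery change is a monotone (normal-scores) function of the estradiol
# change plus Gaussian noise, with the Gaussian-copula conversion
# rho_Pearson = 2*sin(pi*rho_Spearman/6) so the population Spearman
# correlation equals the configured effect size. All other dimensions are
# independent noise across sessions.

# Couple a new vector to x at population Spearman rho via normal scores.
.copula_couple <- function(x, rho_s) {
  n <- length(x)
  rho_p <- 2 * sin(pi * rho_s / 6)
  z <- qnorm((rank(x, ties.method = "average") - 0.5) / n)
  rho_p * z + sqrt(max(0, 1 - rho_p^2)) * rnorm(n)
}

#' Generate synthetic psychological scores
#'
#' Produces per-subject, per-session questionnaire scores: Rosenberg
#' self-esteem, the six Ryff well-being dimensions, and depression/anxiety
#' inventories (BDI, BAI) kept below the study's inclusion cut-offs
#' (BDI < 10, BAI < 21). The luteal change (T3 - T2) of environmental
#' mastery is coupled to the luteal estradiol change at the configured
#' population Spearman correlation (\code{effect_sizes$mastery_rho}); every
#' other score is session-independent noise.
#'
#' @param panel hormone panel from \code{\link{generate_hormone_panel}}.
#' @param config the \code{\link{generator_config}} used for the panel.
#' @return long data.frame with columns \code{subject}, \code{session},
#'   \code{variable}, \code{value}.
#' @export
generate_psych_scores <- function(panel, config) {
  validate_generator_config(config)
  n <- config$n_subjects
  sessions <- config$sessions
  if (length(sessions) != 3) {
    stop("psych score generation assumes three sessions")
  }
  need <- n * length(sessions)
  if (sum(panel$hormone == "estradiol") != need) {
    stop("hormone panel incomplete: expected ", need, " estradiol rows")
  }
  rho <- config$effect_sizes$mastery_rho

  ryff_dims <- c("autonomy", "environmental_mastery", "personal_growth",
                 "positive_relations", "purpose_in_life", "self_acceptance")
  rows <- list()
  add <- function(variable, values_by_session) {
    for (s in seq_along(sessions)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        subject = seq_len(n), session = sessions[s], variable = variable,
        value = values_by_session[[s]], stringsAsFactors = FALSE)
    }
  }

  add("rosenberg", lapply(1:3, function(i) rnorm(n, 32, 4)))
  for (dim in setdiff(ryff_dims, "environmental_mastery")) {
    add(dim, lapply(1:3, function(i) rnorm(n, 60, 8)))
  }

  de <- hormone_deltas(panel, "estradiol", sessions)
  mastery_sd <- 8
  m1 <- rnorm(n, 60, mastery_sd)
  m2 <- rnorm(n, 60, mastery_sd)
  d_luteal <- .copula_couple(de$luteal, rho) * 0.5 * mastery_sd
  add("environmental_mastery", list(m1, m2, m2 + d_luteal))

  # inclusion rule satisfied by construction: BDI in 0..9, BAI in 0..20
  add("bdi", lapply(1:3, function(i) rbinom(n, 9, 0.3)))
  add("bai", lapply(1:3, function(i) rbinom(n, 20, 0.2)))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Latent hub betweenness-centrality delta panel
#'
#' Scalar stand-in for the alpha-band betweenness change of the hub node
#' (right posterior cingulate), used for effect-size recovery studies
#' without simulating oscillators: the luteal-contrast BC change is coupled
#' to the luteal estradiol change at population Spearman
#' \code{effect_sizes$bc_rho}; the follicular-contrast change is
#' independent noise.
#'
#' @param panel hormone panel.
#' @param config generator configuration.
#' @return data.frame with columns \code{subject}, \code{contrast}
#'   (\code{"follicular"}/\code{"luteal"}), \code{delta}.
#' @export
generate_bc_delta_panel <- function(panel, config) {
  validate_generator_config(config)
  de <- hormone_deltas(panel, "estradiol", config$sessions)
  n <- nrow(de)
  scale_bc <- 0.05
  rbind(
    data.frame(subject = de$subject, contrast = "follicular",
               delta = rnorm(n, 0, scale_bc)),
    data.frame(subject = de$subject, contrast = "luteal",
               delta = .copula_couple(de$luteal, config$effect_sizes$bc_rho) *
                 scale_bc)
  )
}

# Population signal fraction needed so that the expected leave-one-out
# cross-validated R^2 of a p-parameter OLS fit on n observations equals
# r2_cv. Under homogeneous leverage h_ii ~ p/n, PRESS ~ RSS/(1 - p/n)^2,
# so E[1 - PRESS/SStot] ~ 1 - (1 - R2_pop) n^2 / ((n - p)(n - 1)).
.model_r2_population <- function(r2_cv, n_obs, n_par) {
  1 - (1 - r2_cv) * (n_obs - n_par) * (n_obs - 1) / n_obs^2
}

#' Scalar delta panel for the hormone -> topology multilinear model
#'
#' Generates the regression problem of the hormone-delta model at the study
#' design size: one row per subject per contrast (follicular T2-T1, luteal
#' T3-T2) with the four hormone changes as predictors, the nuisance
#' covariates (contrast indicator, age, education, cycle length), and a
#' response carrying signal through the estradiol change only. The signal
#' fraction is calibrated so that the expected leave-one-out
#' cross-validated R^2 of the full model equals
#' \code{effect_sizes$model_r2} at this design size.
#'
#' @param config generator configuration.
#' @param panel optional pre-generated hormone panel (drawn if missing).
#' @return data.frame with columns \code{subject}, \code{contrast},
#'   \code{d_estradiol}, \code{d_progesterone}, \code{d_lh}, \code{d_fsh},
#'   \code{age}, \code{education}, \code{cycle_length}, \code{response}.
#' @export
generate_model_panel <- function(config, panel = NULL) {
  validate_generator_config(config)
  if (is.null(panel)) panel <- generate_hormone_panel(config)
  n <- config$n_subjects
  dl <- lapply(c("estradiol", "progesterone", "lh", "fsh"),
               function(h) hormone_deltas(panel, h, config$sessions))
  names(dl) <- c("estradiol", "progesterone", "lh", "fsh")
  dg <- config$demographics
  demo <- data.frame(
    subject = seq_len(n),
    age = rnorm(n, dg$age[1], dg$age[2]),
    education = rnorm(n, dg$education[1], dg$education[2]),
    cycle_length = rnorm(n, dg$cycle_length[1], dg$cycle_length[2]))

  long <- do.call(rbind, lapply(c("follicular", "luteal"), function(ctr) {
    data.frame(subject = seq_len(n), contrast = ctr,
               d_estradiol = dl$estradiol[[ctr]],
               d_progesterone = dl$progesterone[[ctr]],
               d_lh = dl$lh[[ctr]],
               d_fsh = dl$fsh[[ctr]],
               stringsAsFactors = FALSE)
  }))
  long <- merge(long, demo, by = "subject", sort = FALSE)
  long <- long[order(long$contrast, long$subject), ]

  n_obs <- nrow(long)
  n_par <- 9L  # intercept + 4 hormone deltas + 4 nuisance columns
  r2_pop <- .model_r2_population(config$effect_sizes$model_r2, n_obs, n_par)
  # degenerate smoke-scale designs (n_obs near n_par): fall back to the
  # uncorrected population fraction, capped away from 1
  if (!is.finite(r2_pop) || r2_pop >= 0.99 || n_obs <= n_par + 2) {
    r2_pop <- min(config$effect_sizes$model_r2, 0.95)
  }
  beta <- sqrt(r2_pop / (1 - r2_pop))
  z <- as.vector(scale(long$d_estradiol))
  long$response <- beta * z + rnorm(n_obs)
  rownames(long) <- NULL
  long
}
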