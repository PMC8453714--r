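# Synthetic-study generator: configuration validation, hormone marginals,
# psychological effect injection, determinism.

test_that("configuration invariants are enforced", {
  expect_error(generator_config(n_subjects = 1), "n_subjects")
  expect_error(generator_config(fs = 20, band = "gamma"), "too low")
  hp <- default_hormone_params()
  hp$sd[1] <- -1
  expect_error(generator_config(hormone_params = hp), "SDs")
  hp <- default_hormone_params()
  hp$mean[1] <- 5  # below the 11.8 pg/ml estradiol detection limit
  expect_error(generator_config(hormone_params = hp), "detection limit")
  es <- list(mastery_rho = 1.5, bc_rho = 0.5, model_r2 = 0.47)
  expect_error(generator_config(effect_sizes = es), "mastery_rho")
  expect_error(generator_config(hormone_icc = 1.2), "hormone_icc")
})

test_that("YAML configs round-trip and unknown keys are rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 6", "n_nodes: 12", "seed: 9"), path)
  cfg <- read_generator_config(path)
  expect_equal(cfg$n_subjects, 6L)
  expect_equal(cfg$n_nodes, 12L)
  writeLines(c("n_subjects: 6", "n_oscillators: 5"), path)
  expect_error(read_generator_config(path), "n_oscillators")
})

test_that("hormone marginals reproduce the configured session moments", {
  set.seed(401)
  cfg <- generator_config(n_subjects = 10000)
  panel <- generate_hormone_panel(cfg)
  e2 <- panel$value[panel$hormone == "estradiol" & panel$session == "T2"]
  expect_lt(abs(mean(e2) - 134.3) / 134.3, 0.01)
  expect_lt(abs(sd(e2) - 70.6) / 70.6, 0.03)
  # no observation below its assay detection limit
  hp <- cfg$hormone_params
  for (h in unique(hp$hormone)) {
    lim <- hp$limit[hp$hormone == h][1]
    expect_gte(min(panel$value[panel$hormone == h]), lim)
  }
  # one row per subject x session x hormone
  expect_equal(nrow(panel), 10000 * 3 * 4)
  expect_equal(anyDuplicated(panel[, c("subject", "session", "hormone")]), 0L)
})

test_that("zero-SD hormone configuration is degenerate at the session means", {
  hp <- default_hormone_params()
  hp$sd <- 0
  cfg <- generator_config(n_subjects = 5, hormone_params = hp)
  set.seed(1)
  panel <- generate_hormone_panel(cfg)
  for (r in seq_len(nrow(hp))) {
    v <- panel$value[panel$hormone == hp$hormone[r] &
                       panel$session == hp$session[r]]
    expect_equal(v, rep(hp$mean[r], 5))
  }
})

test_that("marginal matches the calibrated truncated normal (KS, icc = 0)", {
  set.seed(402)
  cfg <- generator_config(n_subjects = 10000, hormone_icc = 0)
  panel <- generate_hormone_panel(cfg)
  e1 <- panel$value[panel$hormone == "estradiol" & panel$session == "T1"]
  cal <- cyclegraph:::.calibrate_truncnorm(33.9, 12.1, 11.8, 0)
  ptrunc <- function(q) {
    p0 <- pnorm(11.8, cal["mu"], cal["sigma"])
    (pnorm(q, cal["mu"], cal["sigma"]) - p0) / (1 - p0)
  }
  ks <- suppressWarnings(ks.test(e1, ptrunc))
  expect_gt(ks$p.value, 0.01)
})

test_that("within-subject hormone repeated measures are correlated", {
  set.seed(403)
  cfg <- generator_config(n_subjects = 4000)
  panel <- generate_hormone_panel(cfg)
  fsh <- panel[panel$hormone == "fsh", ]
  w <- reshape(fsh[, c("subject", "session", "value")], idvar = "subject",
               timevar = "session", direction = "wide")
  expect_gt(cor(w$value.T1, w$value.T2), 0.2)  # icc 0.3 target
})

test_that("mastery change tracks the luteal estradiol change at the configured rho", {
  # large-sample copula check against rho_P = 2 sin(pi rho_S / 6)
  set.seed(404)
  cfg <- generator_config(n_subjects = 10000)
  panel <- generate_hormone_panel(cfg)
  psych <- generate_psych_scores(panel, cfg)
  de <- cyclegraph:::hormone_deltas(panel, "estradiol")
  m <- reshape(psych[psych$variable == "environmental_mastery",
                     c("subject", "session", "value")],
               idvar = "subject", timevar = "session", direction = "wide")
  dm <- m$value.T3 - m$value.T2
  expect_lt(abs(cor(de$luteal, dm, method = "spearman") - 0.712), 0.02)

  # null effect
  cfg0 <- generator_config(n_subjects = 10000,
                           effect_sizes = list(mastery_rho = 0, bc_rho = 0.5,
                                               model_r2 = 0.47))
  set.seed(405)
  panel0 <- generate_hormone_panel(cfg0)
  psych0 <- generate_psych_scores(panel0, cfg0)
  de0 <- cyclegraph:::hormone_deltas(panel0, "estradiol")
  m0 <- reshape(psych0[psych0$variable == "environmental_mastery",
                       c("subject", "session", "value")],
                idvar = "subject", timevar = "session", direction = "wide")
  dm0 <- m0$value.T3 - m0$value.T2
  expect_lt(abs(cor(de0$luteal, dm0, method = "spearman")), 0.03)

  # perfect monotone coupling
  cfg1 <- generator_config(n_subjects = 50,
                           effect_sizes = list(mastery_rho = 1, bc_rho = 0.5,
                                               model_r2 = 0.47))
  set.seed(406)
  panel1 <- generate_hormone_panel(cfg1)
  psych1 <- generate_psych_scores(panel1, cfg1)
  de1 <- cyclegraph:::hormone_deltas(panel1, "estradiol")
  m1 <- reshape(psych1[psych1$variable == "environmental_mastery",
                       c("subject", "session", "value")],
                idvar = "subject", timevar = "session", direction = "wide")
  dm1 <- m1$value.T3 - m1$value.T2
  expect_identical(cor(de1$luteal, dm1, method = "spearman"), 1)
})

test_that("psychological inclusion cut-offs hold by construction", {
  set.seed(407)
  cfg <- generator_config(n_subjects = 500)
  panel <- generate_hormone_panel(cfg)
  psych <- generate_psych_scores(panel, cfg)
  expect_lt(max(psych$value[psych$variable == "bdi"]), 10)
  expect_lt(max(psych$value[psych$variable == "bai"]), 21)
  dims <- c("rosenberg", "autonomy", "environmental_mastery",
            "personal_growth", "positive_relations", "purpose_in_life",
            "self_acceptance", "bdi", "bai")
  expect_setequal(unique(psych$variable), dims)
})

test_that("identical config and seed give bit-identical study bundles", {
  cfg <- fast_config(seed = 42, n_epochs = 1)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$hormones, s2$hormones)
  expect_identical(s1$psych, s2$psych)
  expect_identical(s1$model_panel, s2$model_panel)
  expect_identical(s1$recordings[["3.T2"]]$epochs,
                   s2$recordings[["3.T2"]]$epochs)
  expect_identical(s1$manifest$config_hash, s2$manifest$config_hash)
  # a different seed changes the data
  s3 <- generate_study(fast_config(seed = 43, n_epochs = 1),
                       recordings = FALSE)
  expect_false(identical(s1$hormones$value, s3$hormones$value))
})

test_that("a study bundle is complete: one recording per subject x session", {
  cfg <- generator_config(n_subjects = 3, n_nodes = 10, n_epochs = 1,
                          seed = 7)
  st <- generate_study(cfg)
  expect_length(st$recordings, 9)
  for (subj in 1:3) for (s in c("T1", "T2", "T3")) {
    rec <- st$recordings[[paste(subj, s, sep = ".")]]
    expect_s3_class(rec, "epoched_recording")
    expect_length(rec$roi_labels, 10)
    expect_length(rec$epochs, 1)
  }
  expect_equal(nrow(st$hormones), 3 * 3 * 4)
  expect_equal(nrow(st$model_panel), 6)
})

test_that("uncoupled oscillators match the independent-pair PLM baseline", {
  set.seed(408)
  pp <- plm_params(dc_policy = "include")
  cfg <- generator_config(n_subjects = 2, n_nodes = 10, base_coupling = 0,
                          n_epochs = 1, seed = 11)
  rec <- generate_coupled_oscillators(cfg, 1, "T1")
  m <- plm_matrix(rec, "alpha", pp)
  net_vals <- m$values[upper.tri(m$values)]
  # Monte-Carlo baseline from independently simulated pairs
  base <- replicate(120, {
    r2 <- generate_coupled_oscillators(cfg, 1, "T1")
    m2 <- plm_matrix(r2, "alpha", pp)
    m2$values[1, 2]
  })
  se <- sd(base) / sqrt(length(base))
  expect_lt(abs(mean(net_vals) - mean(base)),
            3 * sqrt(se^2 + var(net_vals) / length(net_vals)))
})

test_that("a hard-coupled pair is near-perfectly phase synchronized", {
  set.seed(409)
  fs <- 256
  n <- 8 * fs
  K <- matrix(c(0, 1, 1, 0), 2, 2)
  th <- cyclegraph:::kuramoto_phases(n, runif(2, -pi, pi), K,
                                     2 * pi * c(10, 10) / fs, 0.08)
  x <- cos(th) + matrix(rnorm(2 * n, 0, 0.2), n, 2)
  ph <- apply(x, 2, function(c) instantaneous_phase(bandpass(c, "alpha", fs)))
  val <- plm_pair(ph[, 1], ph[, 2], fs, plm_params(dc_policy = "include"))
  expect_gt(val, 0.9)
})

test_that("PLM increases monotonically with coupling strength", {
  set.seed(410)
  fs <- 256
  n <- 8 * fs
  levels <- seq(0, 0.06, length.out = 12)
  pp <- plm_params(dc_policy = "include")
  mean_plm <- vapply(levels, function(cpl) {
    mean(replicate(12, {
      K <- matrix(c(0, cpl, cpl, 0), 2, 2)
      om <- 2 * pi * (10 + rnorm(2, 0, 1)) / fs
      th <- cyclegraph:::kuramoto_phases(n, runif(2, -pi, pi), K, om, 0.08)
      x <- cos(th) + matrix(rnorm(2 * n, 0, 0.2), n, 2)
      ph <- apply(x, 2, function(c) instantaneous_phase(bandpass(c, "alpha", fs)))
      plm_pair(ph[, 1], ph[, 2], fs, pp)
    }))
  }, numeric(1))
  expect_gt(cor(seq_along(levels), mean_plm, method = "spearman"), 0.95)
})
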