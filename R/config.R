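#' Default hormone panel parameters
#'
#' Per-hormone, per-session target mean and SD of the observed serum
#' concentration, together with the assay detection limit. The targets are
#' the marginal moments the generator reproduces after truncation at the
#' detection limit. Units: estradiol pg/ml, progesterone ng/ml, LH and FSH
#' mIU/ml.
#'
#' @return data.frame with columns \code{hormone}, \code{session},
#'   \code{mean}, \code{sd}, \code{limit}.
#' @export
default_hormone_params <- function() {
  data.frame(
    hormone = rep(c("estradiol", "progesterone", "lh", "fsh"), each = 3),
    session = rep(c("T1", "T2", "T3"), times = 4),
    mean = c(33.9, 134.3, 97.4,
             0.3, 1.1, 5.7,
             5.4, 16.1, 6.0,
             7.3, 7.7, 3.9),
    sd = c(12.1, 70.6, 39.7,
           0.1, 0.8, 2.6,
           2.3, 11.8, 4.0,
           1.4, 3.0, 1.2),
    limit = rep(c(11.8, 0.2, 0.07, 0.3), each = 3),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-study generator configuration
#'
#' Assembles and validates the configuration of the synthetic study
#' generator. Defaults emulate the design of the source study: 24 naturally
#' cycling subjects measured at the early-follicular (T1), peri-ovulatory
#' (T2) and mid-luteal (T3) phases; 90-region source-level signals with a
#' designated hub (right posterior cingulate, \code{"Cingulum_Post_R"})
#' whose coupling is modulated across sessions; hormone panels matching the
#' published session means/SDs above assay detection limits; and well-being
#' scores whose luteal-phase change tracks the estradiol change.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param sessions ordered session labels.
#' @param n_nodes number of network nodes (90 for the full atlas; smaller
#'   values keep the designated hub via label substitution).
#' @param fs sampling rate in Hz; must exceed twice the upper edge of the
#'   simulated band.
#' @param epoch_len_s epoch length in seconds (>= 4).
#' @param n_epochs epochs per recording.
#' @param band name of the canonical frequency band the oscillators occupy.
#' @param band_targets named vector of per-band oscillator centre
#'   frequencies (Hz).
#' @param hub_label ROI label of the session-modulated hub.
#' @param hub_gain named per-session multiplier applied to the hub's
#'   coupling row/column.
#' @param base_coupling total phase-pulling strength per node (rad/sample
#'   scale), spread uniformly over its n_nodes - 1 neighbours before hub
#'   modulation.
#' @param phase_jitter SD of the per-sample phase increment noise (rad).
#' @param detune_sd SD (Hz) of the per-node natural-frequency offsets from
#'   the band centre, redrawn per recording; keeps coupled pairs short of
#'   complete zero-lag locking.
#' @param obs_noise SD of additive observation noise on the cosine signal.
#' @param hormone_params data.frame as \code{\link{default_hormone_params}}.
#' @param hormone_icc intra-class correlation of repeated hormone measures
#'   (subject random intercept share of variance), in [0, 1).
#' @param effect_sizes list with \code{mastery_rho} (population Spearman
#'   correlation between luteal estradiol change and environmental-mastery
#'   change), \code{bc_rho} (ditto for the hub betweenness change) and
#'   \code{model_r2} (target cross-validated explained variance of the
#'   hormone-delta model at the study design size).
#' @param demographics list of c(mean, sd) for \code{age}, \code{education}
#'   and \code{cycle_length}.
#' @param seed integer seed; identical config + seed gives identical output.
#'
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(n_subjects = 24,
                             sessions = c("T1", "T2", "T3"),
                             n_nodes = 90,
                             fs = 256,
                             epoch_len_s = 4,
                             n_epochs = 2,
                             band = "alpha",
                             band_targets = c(delta = 2, theta = 6, alpha = 10,
                                              beta = 21, gamma = 38),
                             hub_label = "Cingulum_Post_R",
                             hub_gain = c(T1 = 1, T2 = 2, T3 = 1),
                             base_coupling = 0.04,
                             phase_jitter = 0.08,
                             detune_sd = 1.0,
                             obs_noise = 0.2,
                             hormone_params = default_hormone_params(),
                             hormone_icc = 0.3,
                             effect_sizes = list(mastery_rho = 0.712,
                                                 bc_rho = 0.541,
                                                 model_r2 = 0.47),
                             demographics = list(age = c(26.6, 5.1),
                                                 education = c(17.3, 2.7),
                                                 cycle_length = c(28.4, 1.5)),
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), sessions = as.character(sessions),
    n_nodes = as.integer(n_nodes), fs = fs, epoch_len_s = epoch_len_s,
    n_epochs = as.integer(n_epochs), band = band, band_targets = band_targets,
    hub_label = hub_label, hub_gain = hub_gain,
    base_coupling = base_coupling, phase_jitter = phase_jitter,
    detune_sd = detune_sd, obs_noise = obs_noise,
    hormone_params = hormone_params,
    hormone_icc = hormone_icc, effect_sizes = effect_sizes,
    demographics = demographics, seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_subjects < 2) stop("config error: n_subjects must be >= 2")
  if (length(cfg$sessions) < 2) stop("config error: need >= 2 sessions")
  if (cfg$n_nodes < 2) stop("config error: n_nodes must be >= 2")
  bands <- canonical_bands()
  if (!cfg$band %in% bands$name) {
    stop("config error: unknown band '", cfg$band, "'")
  }
  f_hi <- bands$f_hi[bands$name == cfg$band]
  if (cfg$fs <= 2 * f_hi) {
    stop("config error: fs = ", cfg$fs, " Hz too low for band '", cfg$band,
         "' (upper edge ", f_hi, " Hz)")
  }
  if (cfg$epoch_len_s < 4) stop("config error: epoch_len_s must be >= 4 s")
  hp <- cfg$hormone_params
  need <- c("hormone", "session", "mean", "sd", "limit")
  if (!all(need %in% names(hp))) {
    stop("config error: hormone_params must have columns ",
         paste(need, collapse = ", "))
  }
  if (any(hp$sd < 0)) stop("config error: hormone SDs must be >= 0")
  if (any(hp$mean < hp$limit)) {
    bad <- hp$hormone[hp$mean < hp$limit][1]
    stop("config error: mean below detection limit for ", bad)
  }
  es <- cfg$effect_sizes
  for (nm in c("mastery_rho", "bc_rho")) {
    if (abs(es[[nm]]) > 1) stop("config error: |", nm, "| must be <= 1")
  }
  if (es$model_r2 < 0 || es$model_r2 >= 1) {
    stop("config error: model_r2 must be in [0, 1)")
  }
  if (cfg$hormone_icc < 0 || cfg$hormone_icc >= 1) {
    stop("config error: hormone_icc must be in [0, 1)")
  }
  if (!all(cfg$sessions %in% names(cfg$hub_gain))) {
    stop("config error: hub_gain must name every session")
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic study generator configuration\n")
  cat(sprintf("  %d subjects x sessions [%s], %d nodes @ fs=%g Hz\n",
              x$n_subjects, paste(x$sessions, collapse = ","),
              x$n_nodes, x$fs))
  cat(sprintf("  band %s, %d epochs x %g s, hub %s gain [%s]\n",
              x$band, x$n_epochs, x$epoch_len_s, x$hub_label,
              paste(x$hub_gain[x$sessions], collapse = ",")))
  cat(sprintf("  effects: mastery_rho=%g bc_rho=%g model_r2=%g, seed=%d\n",
              x$effect_sizes$mastery_rho, x$effect_sizes$bc_rho,
              x$effect_sizes$model_r2, x$seed))
  invisible(x)
}

#' Read a generator configuration from YAML
#'
#' Reads a YAML file whose keys are arguments of
#' \code{\link{generator_config}}; unknown keys are rejected. Keys absent
#' from the file keep their defaults.
#'
#' @param path YAML file path.
#' @return \code{generator_config} object.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(generator_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("config error: unknown key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$hormone_params)) {
    raw$hormone_params <- as.data.frame(raw$hormone_params,
                                        stringsAsFactors = FALSE)
  }
  for (nm in c("band_targets", "hub_gain")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(generator_config, raw)
}
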