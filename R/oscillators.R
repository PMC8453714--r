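# Coupled phase-oscillator recordings.
#
# Stand-in generative model for source-reconstructed MEG: the study's
# method has no generative model of its own, so band-limited signals are
# produced by discrete-time noisy Kuramoto-style phase dynamics, which give
# direct monotone control over exactly the quantity the connectivity
# estimator measures (phase synchronization).

#' Construct an epoched multichannel recording
#'
#' @param subject subject id.
#' @param session session label.
#' @param fs sampling rate (Hz).
#' @param roi_labels ordered channel labels.
#' @param epochs list of n_nodes x n_samples numeric matrices.
#' @return object of class \code{epoched_recording}.
#' @export
epoched_recording <- function(subject, session, fs, roi_labels, epochs) {
  n_nodes <- length(roi_labels)
  if (anyDuplicated(roi_labels)) stop("roi_labels must be unique")
  for (ep in epochs) {
    if (!is.matrix(ep) || nrow(ep) != n_nodes) {
      stop("every epoch must be an n_nodes x n_samples matrix")
    }
    if (ncol(ep) != ncol(epochs[[1]])) stop("epochs must share their shape")
    if (ncol(ep) / fs < 4) stop("every epoch must be at least 4 s long")
  }
  structure(list(subject = subject, session = session, fs = fs,
                 roi_labels = roi_labels, epochs = epochs),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf("epoched_recording: subject %s session %s, %d ROIs, %d epochs x %g s @ %g Hz\n",
              x$subject, x$session, length(x$roi_labels), length(x$epochs),
              ncol(x$epochs[[1]]) / x$fs, x$fs))
  invisible(x)
}

# Per-pair coupling matrix: base coupling spread over the n-1 neighbours,
# hub row/column scaled by the session's hub gain.
.coupling_matrix <- function(n_nodes, base_coupling, hub_index, hub_gain) {
  K <- matrix(base_coupling / (n_nodes - 1), n_nodes, n_nodes)
  diag(K) <- 0
  K[hub_index, ] <- K[hub_index, ] * hub_gain
  K[, hub_index] <- K[, hub_index] * hub_gain
  K
}

#' Simulate one subject/session recording of coupled phase oscillators
#'
#' Every node is a noisy phase oscillator near the configured band's centre
#' frequency (per-node natural frequencies are detuned by
#' \code{detune_sd} Hz, as in real source signals where no two regions
#' oscillate at exactly the same rate); pairwise coupling pulls phase
#' differences toward zero, and the hub node's coupling row/column is
#' multiplied by the session's hub gain (optionally jittered per subject
#' via \code{hub_gain_value}). Coupling drags detuned frequencies toward
#' each other, concentrating interferometric power near — but, short of
#' complete locking, not exactly at — zero frequency, which is precisely
#' what the PLM detects. The observed signal is the cosine of the phase
#' plus additive Gaussian observation noise, cut into equal epochs.
#'
#' @param config generator configuration.
#' @param subject subject id.
#' @param session session label.
#' @param hub_gain_value optional subject-specific hub gain overriding the
#'   session entry of \code{config$hub_gain}.
#' @return an \code{\link{epoched_recording}}.
#' @export
generate_coupled_oscillators <- function(config, subject, session,
                                         hub_gain_value = NULL) {
  validate_generator_config(config)
  n_nodes <- config$n_nodes
  labels <- roi_labels_for(n_nodes, config$hub_label)
  hub <- match(config$hub_label, labels)
  gain <- if (is.null(hub_gain_value)) config$hub_gain[[session]] else
    hub_gain_value
  K <- .coupling_matrix(n_nodes, config$base_coupling, hub, gain)
  f0 <- config$band_targets[[config$band]]
  freqs <- f0 + rnorm(n_nodes, 0, config$detune_sd)
  n_per_epoch <- round(config$epoch_len_s * config$fs)
  n_total <- n_per_epoch * config$n_epochs
  theta0 <- runif(n_nodes, -pi, pi)
  th <- kuramoto_phases(n_total, theta0, K, 2 * pi * freqs / config$fs,
                        config$phase_jitter)
  x <- cos(th) + matrix(rnorm(length(th), 0, config$obs_noise),
                        nrow(th), ncol(th))
  epochs <- lapply(seq_len(config$n_epochs), function(e) {
    idx <- ((e - 1) * n_per_epoch + 1):(e * n_per_epoch)
    t(x[idx, , drop = FALSE])
  })
  epoched_recording(subject, session, config$fs, labels, epochs)
}

#' Generate a complete synthetic study
#'
#' Draws the full bundle a study session produces: hormone panel,
#' psychological scores, and (optionally) one oscillator recording per
#' subject and session in the configured band. The hub coupling gain peaks
#' at the middle session and its per-subject luteal-contrast change is
#' coupled to the subject's luteal estradiol change at population Spearman
#' \code{effect_sizes$bc_rho}, so the downstream topology pipeline sees
#' both a group-level session effect and a subject-level hormone
#' association. A scalar latent hub-BC delta panel and the model panel are
#' included for analyses that do not need signal simulation.
#'
#' @param config generator configuration.
#' @param recordings if FALSE, skip the oscillator simulation and return
#'   scalar panels only.
#' @return list with elements \code{hormones}, \code{psych},
#'   \code{bc_deltas}, \code{model_panel}, \code{recordings} (list indexed
#'   \code{subject.session} or NULL), and \code{manifest} (seed and config
#'   hash).
#' @export
generate_study <- function(config, recordings = TRUE) {
  validate_generator_config(config)
  set.seed(config$seed)
  hormones <- generate_hormone_panel(config)
  psych <- generate_psych_scores(hormones, config)
  bc_deltas <- generate_bc_delta_panel(hormones, config)
  model_panel <- generate_model_panel(config, panel = hormones)

  recs <- NULL
  if (recordings) {
    de <- hormone_deltas(hormones, "estradiol", config$sessions)
    # subject-level luteal hub-gain perturbation tied to estradiol change
    gain_dev <- .copula_couple(de$luteal, config$effect_sizes$bc_rho)
    sd_gain <- 0.15 * abs(config$hub_gain[[config$sessions[2]]] -
                            config$hub_gain[[config$sessions[3]]])
    recs <- list()
    for (subj in seq_len(config$n_subjects)) {
      for (s in config$sessions) {
        gain <- config$hub_gain[[s]]
        if (s == config$sessions[3]) gain <- gain + sd_gain * gain_dev[subj]
        recs[[paste(subj, s, sep = ".")]] <-
          generate_coupled_oscillators(config, subj, s,
                                       hub_gain_value = max(gain, 0))
      }
    }
  }
  list(hormones = hormones, psych = psych, bc_deltas = bc_deltas,
       model_panel = model_panel, recordings = recs,
       manifest = list(seed = config$seed, config_hash = config_hash(config)))
}
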