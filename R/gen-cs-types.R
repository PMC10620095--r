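#' CS response-type archetype templates
#'
#' Idealized z-scored PSTH templates, one per complex-spike response type
#' observed during the delayed-response task: transients around epoch
#' transitions, a transient at trial start (before the sample epoch; in
#' real data plausibly driven by the sound of the pole motor — no
#' mechanistic claim is attached here), a buildup of activity before the
#' motor response, sustained modulation during the response epoch
#' (elevation and suppression), and sustained modulation during the sample
#' epoch. Templates are defined on the 102-bin trial time base used by
#' [zscore_psth()].
#'
#' @param n_bins number of time bins (default 102).
#' @return numeric matrix, one row per archetype (rownames label them),
#'   `n_bins` columns, in z units.
#' @export
cs_response_templates <- function(n_bins = 102L) {
  ep <- task_epochs()
  t <- seq(ep$trial[1] + 0.1, ep$trial[2] - 0.1, length.out = n_bins)
  bump <- function(center, sd = 0.12, amp = 3) amp * exp(-0.5 * ((t - center) / sd)^2)
  step <- function(win, amp = 3, soft = 0.08)
    amp * stats::plogis((t - win[1]) / soft) * stats::plogis((win[2] - t) / soft)
  ramp <- function() {
    r <- numeric(n_bins)
    in_delay <- t >= ep$delay[1] & t < ep$delay[2]
    r[in_delay] <- 3 * (t[in_delay] - ep$delay[1]) / diff(ep$delay)
    r[t >= ep$delay[2]] <- 3 * exp(-(t[t >= ep$delay[2]] - ep$delay[2]) / 0.4)
    r
  }
  templates <- rbind(
    epoch_transition    = bump(ep$sample[1]) + bump(ep$delay[1]) + bump(0),
    trial_start         = bump(ep$presample[1] + 0.25, sd = 0.15),
    pre_response_buildup = ramp(),
    response_elevation  = step(ep$response, amp = 3),
    response_suppression = -step(ep$response, amp = 2.5),
    sample_modulation   = step(ep$sample, amp = 2.5)
  )
  colnames(templates) <- NULL
  templates
}

#' Generate synthetic z-scored CS PSTHs from archetypes
#'
#' Draws a set of unit PSTHs by adding i.i.d. Gaussian noise to each
#' archetype template; the noise sd is a fraction of that template's peak
#' absolute amplitude. The clustering pipeline
#' ([cluster_response_types()]) should recover the generating number of
#' archetypes on this simulation.
#'
#' @param n_per_type units per archetype (default 40).
#' @param noise_sd_frac noise sd as a fraction of peak template amplitude
#'   (default 0.3).
#' @param seed RNG seed.
#' @param templates archetype matrix (default [cs_response_templates()]).
#' @return list with `Z` (units x bins matrix) and `labels` (generating
#'   archetype index per unit).
#' @export
gen_typed_psths <- function(n_per_type = 40, noise_sd_frac = 0.3, seed = 1L,
                            templates = cs_response_templates()) {
  set.seed(seed)
  n_arch <- nrow(templates)
  n_bins <- ncol(templates)
  Z <- matrix(0, n_arch * n_per_type, n_bins)
  labels <- rep(seq_len(n_arch), each = n_per_type)
  for (a in seq_len(n_arch)) {
    peak <- max(abs(templates[a, ]))
    rows <- which(labels == a)
    noise <- matrix(stats::rnorm(length(rows) * n_bins,
                                 sd = noise_sd_frac * peak),
                    length(rows), n_bins)
    Z[rows, ] <- matrix(templates[a, ], length(rows), n_bins, byrow = TRUE) + noise
  }
  list(Z = Z, labels = labels)
}
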