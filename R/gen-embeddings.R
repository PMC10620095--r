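#' Generate per-frame video embeddings and movement-coupled spike trains
#'
#' Emulates the output of a per-session video autoencoder: a smooth
#' 32-dimensional latent process sampled on the camera frame grid, plus
#' units whose log spike rate is linear in the embedding at a configured
#' lag. Optionally the embeddings themselves differ by trial type during
#' the delay and response epochs, creating selectivity that is fully
#' explained by movement; independently, units can carry intrinsic
#' (movement-free) trial-type selectivity added on the rate scale.
#'
#' The latent process is AR(1) per dimension, restarted at each trial, with
#' stationary unit variance. A coupled unit's rate at frame t is
#' `exp(b0 + w . E[t - lag, ])` (log link), with spike counts Poisson per
#' frame; weights are sparse (a random subset of dimensions is nonzero).
#'
#' @param config a [gen_config()]; fields `embed_dim`, `frame_step_s`
#'   (0.025 or 0.017 s), `embed_ar`, `coupling_sd`, `coupling_lag`,
#'   `baseline_hz`, plus trial-table fields.
#' @param n_trials number of trials.
#' @param n_units number of units.
#' @param coupled_frac fraction of units coupled to the embeddings.
#' @param n_active_dims number of embedding dimensions with nonzero weight
#'   in coupled units.
#' @param type_offset magnitude of the trial-type-dependent embedding
#'   offset (latent units; applied to the first four dimensions during the
#'   delay and response epochs, with opposite sign for the two types).
#'   0 disables movement-borne selectivity.
#' @param intrinsic_amp_hz mean delay-epoch rate increment added (on the
#'   rate scale) in each unit's preferred type, independent of the
#'   embeddings. 0 disables intrinsic selectivity.
#' @return object of class `embedding_session`: list with `step_s`,
#'   `frame_t` (within-trial frame times, s), `trial_id` (per frame),
#'   `E` (frames x 32 matrix), `trials` (trial table), and `units` — a list
#'   of `unit_id`, `coupled`, `w` (length-32 weights), `b0`, `lag`,
#'   `pref`, `intrinsic_amp_hz`, `counts` (spikes per frame), `rate_hz`
#'   (true rate per frame).
#' @export
gen_embeddings <- function(config, n_trials, n_units,
                           coupled_frac = 1, n_active_dims = 6,
                           type_offset = 0, intrinsic_amp_hz = 0) {
  stopifnot(inherits(config, "gen_config"),
            config$frame_step_s %in% c(0.025, 0.017),
            n_trials >= 1, n_units >= 1)
  step <- config$frame_step_s
  d <- config$embed_dim
  ep <- task_epochs()
  frame_t <- seq(ep$trial[1] + step / 2, ep$trial[2], by = step)
  n_f <- length(frame_t)

  set.seed(split_seed(config$seed, "embeddings"))
  trials <- gen_trial_table(ceiling(n_trials / 2), config$p_correct,
                            config$p_early, config$p_ignore)
  trials <- trials[seq_len(n_trials), , drop = FALSE]

  ar <- config$embed_ar
  innov_sd <- sqrt(1 - ar^2)
  E <- matrix(0, nrow = n_trials * n_f, ncol = d)
  trial_id <- rep(trials$trial_id, each = n_f)
  for (tr in seq_len(n_trials)) {
    e <- matrix(0, n_f, d)
    e[1, ] <- stats::rnorm(d)
    eps <- matrix(stats::rnorm((n_f - 1) * d, sd = innov_sd), n_f - 1, d)
    for (i in 2:n_f) e[i, ] <- ar * e[i - 1, ] + eps[i - 1, ]
    if (type_offset != 0) {
      sgn <- if (trials$type[tr] == "right") 1 else -1
      late <- frame_t >= ep$delay[1]
      e[late, 1:4] <- e[late, 1:4] + sgn * type_offset
    }
    E[((tr - 1) * n_f + 1):(tr * n_f), ] <- e
  }

  lag <- as.integer(config$coupling_lag)
  units <- vector("list", n_units)
  unit_pref <- sample(c("left", "right"), n_units, replace = TRUE)
  unit_coupled <- stats::runif(n_units) < coupled_frac
  shape_f <- selectivity_shape(frame_t, config$ramp_shape)
  for (u in seq_len(n_units)) {
    set.seed(split_seed(config$seed, "embed_units", u))
    w <- numeric(d)
    if (unit_coupled[u]) {
      # with a trial-type offset in play, coupled units read out the
      # type-carrying dimensions (1:4) so movement-borne selectivity is
      # present in every coupled unit
      idx <- if (type_offset != 0)
        c(1:4, 4 + sample.int(d - 4, max(0, n_active_dims - 4)))
      else sample.int(d, n_active_dims)
      w[idx] <- stats::rnorm(length(idx), sd = config$coupling_sd)
    }
    b0 <- log(max(config$baseline_hz, 0.1))
    rate <- numeric(n_trials * n_f)
    for (tr in seq_len(n_trials)) {
      rows <- ((tr - 1) * n_f + 1):(tr * n_f)
      Elag <- E[rows, , drop = FALSE]
      if (lag != 0) {
        # embeddings at frame t - lag drive the rate at frame t
        src <- seq_len(n_f) - lag
        src <- pmin(pmax(src, 1L), n_f)
        Elag <- Elag[src, , drop = FALSE]
      }
      r <- exp(b0 + as.numeric(Elag %*% w))
      if (intrinsic_amp_hz != 0 && trials$type[tr] == unit_pref[u])
        r <- r + intrinsic_amp_hz * shape_f
      rate[rows] <- pmin(r, 500)  # guard against latent excursions
    }
    counts <- stats::rpois(length(rate), rate * step)
    units[[u]] <- list(unit_id = sprintf("unit%04d", u),
                       coupled = unit_coupled[u], w = w, b0 = b0, lag = lag,
                       pref = unit_pref[u],
                       intrinsic_amp_hz = intrinsic_amp_hz,
                       counts = counts, rate_hz = rate)
  }

  structure(list(step_s = step, frame_t = frame_t, trial_id = trial_id,
                 E = E, trials = trials, units = units),
            class = "embedding_session")
}
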