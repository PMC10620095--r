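#' Simulate an inhomogeneous Poisson spike train by thinning
#'
#' @param rate_fn vectorized function of time (s) returning rate (Hz).
#' @param window `c(t0, t1)` in seconds.
#' @param rate_max an upper bound on `rate_fn` over the window.
#' @return sorted numeric vector of spike times.
#' @keywords internal
sim_poisson_train <- function(rate_fn, window, rate_max) {
  if (rate_max <= 0) return(numeric(0))
  n <- stats::rpois(1, rate_max * (window[2] - window[1]))
  if (n == 0) return(numeric(0))
  tt <- sort(stats::runif(n, window[1], window[2]))
  tt[stats::runif(n) < rate_fn(tt) / rate_max]
}

# selectivity modulation shape on the trial time base: 0 before the delay,
# ramps (or steps) through the delay with unit mean, and holds its end value
# through the response epoch
selectivity_shape <- function(t, ramp_shape = c("linear", "step")) {
  ramp_shape <- match.arg(ramp_shape)
  ep <- task_epochs()
  d0 <- ep$delay[1]; d1 <- ep$delay[2]
  s <- numeric(length(t))
  in_delay <- t >= d0 & t < d1
  in_resp <- t >= d1
  if (ramp_shape == "linear") {
    s[in_delay] <- 2 * (t[in_delay] - d0) / (d1 - d0)
    s[in_resp] <- 2
  } else {
    s[in_delay] <- 1
    s[in_resp] <- 1
  }
  s
}

#' Generate a behavioral trial table for one recording session
#'
#' @param n_per_type trials per instructed type.
#' @param p_correct,p_early,p_ignore outcome probabilities; early-lick and
#'   ignore trials are drawn first, the rest split correct/error.
#' @return data.frame with `trial_id`, `type` ("left"/"right"), `outcome`
#'   ("correct"/"error"/"early"/"ignore").
#' @keywords internal
gen_trial_table <- function(n_per_type, p_correct, p_early, p_ignore) {
  n <- 2L * n_per_type
  type <- sample(rep(c("left", "right"), n_per_type))
  u <- stats::runif(n)
  outcome <- ifelse(u < p_early, "early",
             ifelse(u < p_early + p_ignore, "ignore",
             ifelse(stats::runif(n) < p_correct, "correct", "error")))
  data.frame(trial_id = seq_len(n), type = type, outcome = outcome,
             stringsAsFactors = FALSE)
}

#' Generate a set of synthetic unit recordings
#'
#' Each unit is an independent recording: a trial table (instructed type,
#' outcome), a simple-spike train per trial drawn from an inhomogeneous
#' Poisson process (baseline plus, for selective units, a delay-epoch ramp of
#' the configured mean amplitude in the unit's preferred trial type), and,
#' for Purkinje-class units, a complex-spike stream with an enforced
#' simple-spike pause after every complex spike. Spike times are on the
#' common trial time base (go cue at t = 0; see [task_epochs()]).
#'
#' If the configured amplitude would drive the rate below zero it is clipped
#' at zero and the unit is flagged (`rate_clipped`).
#'
#' @param config a [gen_config()]; relevant fields `baseline_hz`,
#'   `select_amp_hz`, `frac_selective`, `ramp_shape`, `cs_rate_hz`,
#'   `pause_ms`, `purkinje_frac`, `trials_per_type`, `p_correct`, `p_early`,
#'   `p_ignore`.
#' @param n_units number of units.
#' @param region_labels optional character vector of atlas zone labels to
#'   sample unit locations from (recycled/sampled); defaults to all zones.
#' @return object of class `session_set`: list with `units` (list of unit
#'   recordings: `unit_id`, `zone`, `x_um`,`y_um`,`z_um`, `class`
#'   ("SS-only"/"Purkinje"), `pref`, `amp_hz`, `rate_clipped`, `trials`,
#'   `spikes` (data.frame `trial_id`, `t_s`), `cs` (same shape; NULL for
#'   SS-only)) and `config`.
#' @export
gen_ephys <- function(config, n_units, region_labels = NULL) {
  stopifnot(inherits(config, "gen_config"), n_units >= 1,
            config$trials_per_type >= 1)
  atlas <- config$atlas
  zones <- atlas$zones
  if (is.null(region_labels)) region_labels <- zones$zone
  stopifnot(all(region_labels %in% zones$zone))
  ep <- task_epochs()
  win <- ep$trial
  pause_s <- config$pause_ms / 1000

  set.seed(split_seed(config$seed, "ephys_units"))
  unit_zone <- sample(region_labels, n_units, replace = TRUE)
  unit_class <- ifelse(stats::runif(n_units) < config$purkinje_frac,
                       "Purkinje", "SS-only")
  unit_pref <- sample(c("left", "right"), n_units, replace = TRUE)
  unit_amp <- ifelse(stats::runif(n_units) < config$frac_selective,
                     config$select_amp_hz, 0)

  units <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    set.seed(split_seed(config$seed, "ephys_trains", u))
    zi <- match(unit_zone[u], zones$zone)
    ml <- stats::runif(1, zones$ml_min_um[zi], zones$ml_max_um[zi])
    coords <- c(x_um = ml * sample(c(-1, 1), 1),
                y_um = stats::runif(1, zones$ap_min_um[zi], zones$ap_max_um[zi]),
                z_um = stats::runif(1, zones$dv_min_um[zi], zones$dv_max_um[zi]))
    trials <- gen_trial_table(config$trials_per_type, config$p_correct,
                              config$p_early, config$p_ignore)
    base <- config$baseline_hz
    amp <- unit_amp[u]
    clipped <- base + min(0, 2 * amp) < 0
    rate_max <- max(base, base + 2 * abs(amp))
    sp <- vector("list", nrow(trials))
    cs <- vector("list", nrow(trials))
    for (tr in seq_len(nrow(trials))) {
      pref_trial <- trials$type[tr] == unit_pref[u]
      rate_fn <- if (pref_trial && amp != 0) {
        function(t) pmax(0, base + amp * selectivity_shape(t, config$ramp_shape))
      } else {
        function(t) rep(base, length(t))
      }
      ss <- sim_poisson_train(rate_fn, win, rate_max)
      if (unit_class[u] == "Purkinje") {
        cst <- sim_poisson_train(function(t) rep(config$cs_rate_hz, length(t)),
                                 win, config$cs_rate_hz)
        if (length(cst) && length(ss) && pause_s > 0) {
          drop <- rep(FALSE, length(ss))
          for (ct in cst) drop <- drop | (ss > ct & ss <= ct + pause_s)
          ss <- ss[!drop]
        }
        cs[[tr]] <- if (length(cst))
          data.frame(trial_id = tr, t_s = cst) else NULL
      }
      sp[[tr]] <- if (length(ss)) data.frame(trial_id = tr, t_s = ss) else NULL
    }
    if (clipped)
      message("unit ", u, ": configured amplitude drives rate below 0; clipped")
    units[[u]] <- list(
      unit_id = sprintf("unit%04d", u),
      zone = unit_zone[u],
      x_um = unname(coords["x_um"]), y_um = unname(coords["y_um"]),
      z_um = unname(coords["z_um"]),
      class = unit_class[u],
      pref = unit_pref[u],
      amp_hz = amp,
      rate_clipped = clipped,
      trials = trials,
      spikes = if (is.null(sp1 <- do.call(rbind, sp)))
        data.frame(trial_id = integer(), t_s = numeric()) else sp1,
      cs = if (unit_class[u] == "Purkinje") {
        if (is.null(cs1 <- do.call(rbind, cs)))
          data.frame(trial_id = integer(), t_s = numeric()) else cs1
      } else NULL
    )
  }
  structure(list(units = units, config = config), class = "session_set")
}
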