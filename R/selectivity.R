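#' Peri-stimulus time histogram of one unit
#'
#' Spike-count histogram on the common trial time base, divided by bin
#' width and trial count, optionally smoothed with a centered moving
#' average (partial windows at the edges).
#'
#' @param unit a unit recording (list with `spikes`, `trials`; see
#'   [gen_ephys()]).
#' @param trials trial table; defaults to the unit's own.
#' @param types trial types to compute (default both).
#' @param outcomes outcomes to include (default `"correct"`).
#' @param bin_s bin width (s), default 0.1.
#' @param smooth_s smoothing (averaging) window (s), default 0.2; 0
#'   disables smoothing.
#' @return list with `time` (bin centers, s), `rates` (named list of
#'   numeric traces, Hz, one per type), `n_trials` (named count).
#' @export
psth <- function(unit, trials = unit$trials, types = c("left", "right"),
                 outcomes = "correct", bin_s = 0.1, smooth_s = 0.2) {
  win <- task_epochs()$trial
  n_bins <- round((win[2] - win[1]) / bin_s)
  centers <- win[1] + (seq_len(n_bins) - 0.5) * bin_s
  rates <- list(); n_trials <- integer(0)
  for (ty in types) {
    ids <- trials$trial_id[trials$type == ty & trials$outcome %in% outcomes]
    if (!length(ids)) stop("no trials of type '", ty, "' with outcome(s) ",
                           paste(outcomes, collapse = "/"))
    sp <- unit$spikes$t_s[unit$spikes$trial_id %in% ids]
    sp <- sp[sp >= win[1] & sp < win[2]]
    h <- tabulate(floor((sp - win[1]) / bin_s) + 1L, nbins = n_bins)
    r <- h / bin_s / length(ids)
    if (smooth_s > 0) r <- moving_average(r, max(1L, round(smooth_s / bin_s)))
    rates[[ty]] <- r
    n_trials[ty] <- length(ids)
  }
  list(time = centers, rates = rates, n_trials = n_trials)
}

# centered moving average with partial windows at the edges
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  half <- floor(k / 2)
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Held-out trial-type preference and selectivity from per-trial values
#'
#' The split-trial estimator at the core of the selectivity analysis: the
#' preferred trial type is determined from a held-out subset of trials
#' (default the first 15 of each type, chronologically), and the
#' selectivity amplitude is the mean difference (preferred minus
#' non-preferred) over the remaining trials only, making the estimator
#' unbiased under the null. Significance is a two-tailed Welch t-test over
#' all supplied trials.
#'
#' @param values per-trial statistic (e.g. epoch spike rate, Hz).
#' @param type per-trial type ("left"/"right"), same length.
#' @param n_pref_trials held-out trials per type used to fix the
#'   preference (default 15).
#' @param alpha significance level (default 0.01).
#' @param pref_subset `"first"` (chronological, default) or `"random"`
#'   (seeded).
#' @param seed seed for `pref_subset = "random"`.
#' @return list: `usable`, `preferred`, `p_value`, `significant`,
#'   `amplitude` (mean value difference, preferred minus non-preferred,
#'   estimation trials only), `est_idx` (indices of estimation trials).
#' @export
held_out_selectivity <- function(values, type, n_pref_trials = 15,
                                 alpha = 0.01,
                                 pref_subset = c("first", "random"),
                                 seed = 1L) {
  pref_subset <- match.arg(pref_subset)
  stopifnot(length(values) == length(type))
  iL <- which(type == "left"); iR <- which(type == "right")
  if (length(iL) < n_pref_trials + 1 || length(iR) < n_pref_trials + 1)
    return(list(usable = FALSE, preferred = NA_character_,
                p_value = NA_real_, significant = NA,
                amplitude = NA_real_, est_idx = integer(0)))
  p <- tryCatch(stats::t.test(values[iR], values[iL])$p.value,
                error = function(e) NA_real_)
  take <- function(idx) {
    if (pref_subset == "first") idx[seq_len(n_pref_trials)]
    else { set.seed(seed); sample(idx, n_pref_trials) }
  }
  hL <- take(iL); hR <- take(iR)
  preferred <- if (mean(values[hR]) >= mean(values[hL])) "right" else "left"
  eL <- setdiff(iL, hL); eR <- setdiff(iR, hR)
  amp <- if (preferred == "right")
    mean(values[eR]) - mean(values[eL])
  else
    mean(values[eL]) - mean(values[eR])
  list(usable = TRUE, preferred = preferred, p_value = p,
       significant = is.finite(p) && p < alpha, amplitude = amp,
       est_idx = sort(c(eL, eR)))
}

#' Epoch trial-type selectivity of one unit
#'
#' Tests whether a unit's spike counts in a task epoch differentiate
#' 'lick left' from 'lick right' trials (two-tailed t-test, significant at
#' `alpha`), fixes the preferred type on a held-out subset of trials, and
#' computes the selectivity amplitude and trace from the remaining trials
#' (preferred minus non-preferred spike rate).
#'
#' By default only correct trials are used. With
#' `correct_only = FALSE` (the convention for photostimulation analyses)
#' correct and error trials are pooled, grouped by the instructed type.
#'
#' @param unit a unit recording ([gen_ephys()]).
#' @param trials trial table; defaults to the unit's own.
#' @param epoch `"sample"`, `"delay"` or `"response"`.
#' @param n_pref_trials held-out trials per type (default 15).
#' @param correct_only logical (default TRUE).
#' @param alpha significance level (default 0.01).
#' @param bin_s,smooth_s trace binning, passed to [psth()].
#' @param trace compute the selectivity trace (default TRUE; turn off in
#'   large simulations).
#' @param pref_subset,seed see [held_out_selectivity()].
#' @return object of class `selectivity_result`: list with `usable`,
#'   `epoch`, `preferred`, `p_value`, `significant`, `amplitude_hz`,
#'   `time`, `trace` (S(t), Hz; NULL if `trace = FALSE`), `n_trials`.
#' @export
epoch_selectivity <- function(unit, trials = unit$trials, epoch = "delay",
                              n_pref_trials = 15, correct_only = TRUE,
                              alpha = 0.01, bin_s = 0.1, smooth_s = 0.2,
                              trace = TRUE,
                              pref_subset = c("first", "random"), seed = 1L) {
  stopifnot(epoch %in% c("sample", "delay", "response"))
  win <- task_epochs()[[epoch]]
  keep <- if (correct_only) trials$outcome == "correct"
          else trials$outcome %in% c("correct", "error")
  tt <- trials[keep, , drop = FALSE]
  rate <- epoch_rates(unit, tt$trial_id, win)
  hs <- held_out_selectivity(rate, tt$type, n_pref_trials, alpha,
                             pref_subset, seed)
  res <- list(usable = hs$usable, epoch = epoch, preferred = hs$preferred,
              p_value = hs$p_value, significant = hs$significant,
              amplitude_hz = hs$amplitude, time = NULL, trace = NULL,
              n_trials = nrow(tt))
  if (hs$usable && trace) {
    est <- tt[hs$est_idx, , drop = FALSE]
    ps <- psth(unit, est, outcomes = unique(est$outcome),
               bin_s = bin_s, smooth_s = smooth_s)
    pref <- hs$preferred
    nonpref <- setdiff(c("left", "right"), pref)
    res$time <- ps$time
    res$trace <- ps$rates[[pref]] - ps$rates[[nonpref]]
  }
  class(res) <- "selectivity_result"
  res
}

# internal: per-trial spike rate (Hz) in a time window
epoch_rates <- function(unit, trial_ids, win) {
  sp <- unit$spikes
  sp <- sp[sp$t_s >= win[1] & sp$t_s < win[2], , drop = FALSE]
  cnt <- table(factor(sp$trial_id, levels = trial_ids))
  as.numeric(cnt) / (win[2] - win[1])
}

#' Population selectivity trace
#'
#' Pointwise mean and s.e.m. across units' selectivity traces (denominator
#' is the number of units).
#'
#' @param results list of `selectivity_result` objects with traces on a
#'   common time base.
#' @return list with `time`, `mean`, `sem`, `n_units`.
#' @export
population_selectivity <- function(results) {
  results <- Filter(function(r) !is.null(r$trace), results)
  if (!length(results)) stop("no selectivity traces supplied")
  M <- do.call(rbind, lapply(results, function(r) r$trace))
  n <- nrow(M)
  list(time = results[[1]]$time,
       mean = colMeans(M),
       sem = if (n > 1) apply(M, 2, stats::sd) / sqrt(n) else rep(0, ncol(M)),
       n_units = n)
}

#' Classify ramping activity of one unit
#'
#' Delay activity is the per-trial difference in spike rate between the
#' delay epoch and the baseline window (the 500 ms before sample onset),
#' computed separately per trial type. A unit is classified when delay
#' activity in at least one type differs significantly from zero (Wilcoxon
#' signed-rank on the per-trial differences, P < 0.05); for the type with
#' the largest rate change, the unit ramps up (down) if the spike rate in
#' the last 500 ms of the delay exceeds (falls below) baseline. Units with
#' nonsignificant delay activity are excluded.
#'
#' @param unit a unit recording.
#' @param trials trial table (default the unit's own); correct trials only.
#' @param alpha significance level (default 0.05).
#' @return list with `label` ("up"/"down"/"excluded"), `delay_activity_hz`
#'   (named per type), `p_values` (named per type).
#' @export
classify_ramping <- function(unit, trials = unit$trials, alpha = 0.05) {
  ep <- task_epochs()
  tt <- trials[trials$outcome == "correct", , drop = FALSE]
  base_win <- ep$presample
  late_win <- c(ep$delay[2] - 0.5, ep$delay[2])
  types <- c("left", "right")
  d_mean <- stats::setNames(rep(NA_real_, 2), types)
  pv <- stats::setNames(rep(NA_real_, 2), types)
  late_mean <- stats::setNames(rep(NA_real_, 2), types)
  base_mean <- stats::setNames(rep(NA_real_, 2), types)
  for (ty in types) {
    ids <- tt$trial_id[tt$type == ty]
    if (length(ids) < 2) next
    d <- epoch_rates(unit, ids, ep$delay) - epoch_rates(unit, ids, base_win)
    if (all(d == 0)) { d_mean[ty] <- 0; pv[ty] <- 1 }
    else {
      d_mean[ty] <- mean(d)
      pv[ty] <- suppressWarnings(stats::wilcox.test(d, mu = 0)$p.value)
    }
    late_mean[ty] <- mean(epoch_rates(unit, ids, late_win))
    base_mean[ty] <- mean(epoch_rates(unit, ids, base_win))
  }
  if (!any(is.finite(pv)) || min(pv, na.rm = TRUE) >= alpha)
    return(list(label = "excluded", delay_activity_hz = d_mean,
                p_values = pv))
  ty <- types[which.max(abs(d_mean))]
  diff_late <- late_mean[ty] - base_mean[ty]
  label <- if (isTRUE(diff_late > 0)) "up"
           else if (isTRUE(diff_late < 0)) "down" else "excluded"
  list(label = label, delay_activity_hz = d_mean, p_values = pv)
}

#' Assign a unit to a connectivity-defined region group
#'
#' Maps the unit's reference coordinates to an atlas zone (lobule or
#' sub-lobule via the split thresholds) and then to its region group from
#' a [classify_regions()] result.
#'
#' @param unit a unit recording (fields `x_um`, `y_um`, `z_um`).
#' @param classification a [classify_regions()] result.
#' @param atlas a [cb_atlas()].
#' @return list with `zone` and `region` (both `"unassigned"` when the
#'   coordinates fall outside every atlas zone).
#' @export
assign_region <- function(unit, classification, atlas = cb_atlas()) {
  zone <- atlas_zone_at(atlas, unit$x_um, unit$y_um, unit$z_um)
  if (is.na(zone)) return(list(zone = "unassigned", region = "unassigned"))
  i <- match(zone, classification$zone)
  if (is.na(i)) return(list(zone = zone, region = "unassigned"))
  list(zone = zone, region = as.character(classification$region[i]))
}
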