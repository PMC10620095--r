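#' Validate Purkinje identity by the CS-triggered SS pause
#'
#' Computes the cross-correlogram of simple-spike (SS) activity around
#' complex-spike (CS) times and tests for the characteristic pause of SS
#' firing just after a CS, which confirms that the two spike streams
#' originate from the same Purkinje cell. The pause statistic is the SS
#' rate in the post-CS window divided by the baseline SS rate (estimated
#' from negative lags); the unit is accepted when the statistic falls below
#' the ratio threshold. An automated surrogate for manual correlogram
#' inspection.
#'
#' @param ss_times,cs_times data.frames with `trial_id`, `t_s` (as in
#'   [gen_ephys()] units), or plain numeric vectors of event times on a
#'   single continuous time base.
#' @param pause_window_ms post-CS window tested for the pause (default 10).
#' @param ratio_threshold accept when pause statistic < this (default 0.5).
#' @param bin_ms correlogram bin (default 1), `max_lag_ms` its span
#'   (default 50).
#' @param max_lag_ms maximum lag of the correlogram (default 50).
#' @return list with `decision` ("accept"/"reject"/"indeterminate"),
#'   `pause_statistic`, `n_cs`, and `correlogram` (data.frame `lag_ms`,
#'   `rate_hz`) for audit.
#' @export
validate_cs_pause <- function(ss_times, cs_times, pause_window_ms = 10,
                              ratio_threshold = 0.5, bin_ms = 1,
                              max_lag_ms = 50) {
  as_events <- function(x) {
    if (is.data.frame(x)) x
    else data.frame(trial_id = 1L, t_s = as.numeric(x))
  }
  ss <- as_events(ss_times); cs <- as_events(cs_times)
  n_cs <- nrow(cs)
  lag_max <- max_lag_ms / 1000
  lags <- numeric(0)
  for (tr in unique(cs$trial_id)) {
    s <- ss$t_s[ss$trial_id == tr]
    if (!length(s)) next
    for (ct in cs$t_s[cs$trial_id == tr]) {
      d <- s - ct
      lags <- c(lags, d[abs(d) <= lag_max & d != 0])
    }
  }
  n_bins <- 2L * as.integer(max_lag_ms / bin_ms)
  edges <- seq(-lag_max, lag_max, length.out = n_bins + 1)
  cnt <- tabulate(findInterval(lags, edges, rightmost.closed = TRUE),
                  nbins = n_bins)
  rate <- cnt / (n_cs * bin_ms / 1000)
  centers <- (edges[-1] + edges[-length(edges)]) / 2 * 1000
  correlogram <- data.frame(lag_ms = centers, rate_hz = rate)
  if (n_cs < 20)
    return(list(decision = "indeterminate", pause_statistic = NA_real_,
                n_cs = n_cs, correlogram = correlogram))
  baseline <- mean(rate[centers < 0])
  pause_rate <- mean(rate[centers > 0 & centers <= pause_window_ms])
  stat <- if (baseline > 0) pause_rate / baseline else NA_real_
  decision <- if (!is.finite(stat)) "indeterminate"
              else if (stat < ratio_threshold) "accept" else "reject"
  list(decision = decision, pause_statistic = stat, n_cs = n_cs,
       correlogram = correlogram)
}

#' Z-scored PSTH over 102 bins
#'
#' Computes a unit's PSTH in 200-ms bins over the trial ('lick left' and
#' 'lick right' trials pooled, one outcome condition), z-scores it against
#' the baseline spike rate before the sample epoch, and downsamples the
#' trace to exactly 102 evenly spaced bins by linear interpolation.
#'
#' @param unit a unit recording; by default its CS stream is used when
#'   present (`stream = "cs"`), otherwise SS.
#' @param trials trial table (default the unit's own).
#' @param condition `"correct"` (default) or `"error"`.
#' @param stream `"cs"` or `"ss"`; default uses CS if the unit has one.
#' @param n_out output length (default 102).
#' @param sd_floor_hz baseline-sd floor below which the unit is excluded
#'   (default 1e-6).
#' @return list with `unit_id`, `z` (length `n_out`), `time`, `condition`,
#'   `n_trials`, `excluded`, `reason`.
#' @export
zscore_psth <- function(unit, trials = unit$trials, condition = "correct",
                        stream = NULL, n_out = 102L, sd_floor_hz = 1e-6) {
  if (is.null(stream)) stream <- if (!is.null(unit$cs)) "cs" else "ss"
  events <- if (stream == "cs") unit$cs else unit$spikes
  win <- task_epochs()$trial
  bin <- 0.2
  n_bins <- round((win[2] - win[1]) / bin)
  ids <- trials$trial_id[trials$outcome == condition]
  if (!length(ids))
    return(list(unit_id = unit$unit_id, z = NULL, time = NULL,
                condition = condition, n_trials = 0L, excluded = TRUE,
                reason = "no trials in condition"))
  # per-trial count matrix (trials x bins)
  C <- matrix(0, length(ids), n_bins)
  ev <- events[events$trial_id %in% ids & events$t_s >= win[1] &
                 events$t_s < win[2], , drop = FALSE]
  if (nrow(ev)) {
    bi <- floor((ev$t_s - win[1]) / bin) + 1L
    ti <- match(ev$trial_id, ids)
    for (k in seq_along(bi)) C[ti[k], bi[k]] <- C[ti[k], bi[k]] + 1
  }
  R <- C / bin
  centers <- win[1] + (seq_len(n_bins) - 0.5) * bin
  base_bins <- which(win[1] + (seq_len(n_bins) - 1) * bin >= task_epochs()$presample[1] &
                     win[1] + seq_len(n_bins) * bin <= task_epochs()$presample[2])
  base_vals <- as.numeric(R[, base_bins])
  mu <- mean(base_vals); s <- stats::sd(base_vals)
  if (!is.finite(s) || s < sd_floor_hz)
    return(list(unit_id = unit$unit_id, z = NULL, time = NULL,
                condition = condition, n_trials = length(ids),
                excluded = TRUE, reason = "baseline sd below floor"))
  z23 <- (colMeans(R) - mu) / s
  out_t <- seq(centers[1], centers[n_bins], length.out = n_out)
  z <- stats::approx(centers, z23, xout = out_t)$y
  list(unit_id = unit$unit_id, z = z, time = out_t, condition = condition,
       n_trials = length(ids), excluded = FALSE, reason = NA_character_)
}

# internal: mean silhouette width of a k-means labelling in score space
mean_silhouette <- function(labels, d) {
  mean(cluster::silhouette(labels, d)[, "sil_width"])
}

#' Cluster CS response types
#'
#' Clusters z-scored PSTHs into response types: the mean-centered PSTH
#' matrix is reduced to its top principal-component scores, k-means (with
#' seeded multiple restarts) is run for each candidate cluster number, and
#' the number of clusters maximizing the mean silhouette width (Euclidean
#' distance) is selected. Silhouette is undefined at k = 1; a candidate
#' k = 1 is reported as "no structure" only when every k >= 2 silhouette
#' falls below `noise_sil` (default 0.25, above the ~0.2 silhouettes that
#' k-means extracts from pure isotropic noise at these problem sizes).
#'
#' @param psths numeric matrix, units x bins (typically 102 columns of
#'   z-scored rate), or a list of [zscore_psth()] results.
#' @param n_pcs number of principal-component scores used (default 6).
#' @param k_range candidate cluster numbers (default 1:20).
#' @param nstart k-means restarts (default 50).
#' @param seed RNG seed for the restarts.
#' @param noise_sil silhouette level below which apparent clusters are
#'   treated as noise (default 0.25).
#' @return list with `k` (selected number of clusters; NA when degenerate),
#'   `labels`, `silhouette` (data.frame `k`, `mean_sil`), `scores`,
#'   `degenerate`, `no_structure`.
#' @export
cluster_response_types <- function(psths, n_pcs = 6, k_range = 1:20,
                                   nstart = 50, seed = 1L,
                                   noise_sil = 0.25) {
  Z <- if (is.list(psths) && !is.matrix(psths))
    do.call(rbind, lapply(psths, `[[`, "z")) else as.matrix(psths)
  n <- nrow(Z)
  if (n < 2) stop("need at least two units to cluster")
  if (max(stats::dist(Z)) == 0)
    return(list(k = NA_integer_, labels = rep(1L, n),
                silhouette = data.frame(k = integer(), mean_sil = numeric()),
                scores = NULL, degenerate = TRUE, no_structure = TRUE))
  n_pcs <- min(n_pcs, n - 1, ncol(Z))
  pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  d <- stats::dist(scores)
  ks <- sort(unique(k_range[k_range >= 2 & k_range <= n - 1]))
  sil <- numeric(length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    set.seed(seed + ks[i])
    fits[[i]] <- stats::kmeans(scores, centers = ks[i], nstart = nstart,
                               iter.max = 100)
    sil[i] <- mean_silhouette(fits[[i]]$cluster, d)
  }
  sil_tab <- data.frame(k = ks, mean_sil = sil)
  no_structure <- (1 %in% k_range) && all(sil < noise_sil)
  if (no_structure)
    return(list(k = 1L, labels = rep(1L, n), silhouette = sil_tab,
                scores = scores, degenerate = FALSE, no_structure = TRUE))
  best <- which.max(sil)
  list(k = ks[best], labels = fits[[best]]$cluster, silhouette = sil_tab,
       scores = scores, degenerate = FALSE, no_structure = FALSE)
}
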