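#' Task performance summary
#'
#' Performance is the fraction of correct choices among scoreable trials:
#' early-lick and ignore trials are excluded from the denominator. Computed
#' per condition, both pooled over trial types and separately for 'lick
#' left' and 'lick right' trials; early-lick and ignore fractions are
#' computed over all trials of the cell.
#'
#' @param trials behavior data.frame ([gen_behavior()] schema: `type`,
#'   `condition`, `outcome`).
#' @param by_type also report per-trial-type rows (default TRUE).
#' @return data.frame with `condition`, `type` ("all"/"left"/"right"),
#'   `n_trials`, `n_scoreable`, `performance` (NA with zero scoreable
#'   trials), `early_frac`, `ignore_frac`.
#' @export
performance <- function(trials, by_type = TRUE) {
  cell <- function(df, condition, type) {
    scoreable <- df$outcome %in% c("correct", "error")
    n_sc <- sum(scoreable)
    data.frame(
      condition = condition, type = type,
      n_trials = nrow(df), n_scoreable = n_sc,
      performance = if (n_sc > 0) sum(df$outcome == "correct") / n_sc
                    else NA_real_,
      early_frac = mean(df$outcome == "early"),
      ignore_frac = mean(df$outcome == "ignore"),
      stringsAsFactors = FALSE)
  }
  out <- list()
  for (cond in unique(trials$condition)) {
    dc <- trials[trials$condition == cond, , drop = FALSE]
    out[[length(out) + 1]] <- cell(dc, cond, "all")
    if (by_type) for (ty in c("left", "right"))
      out[[length(out) + 1]] <-
        cell(dc[dc$type == ty, , drop = FALSE], cond, ty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# internal: per-session scoreable counts for one condition vs control,
# optionally restricted to one instructed trial type
session_counts <- function(trials, condition, type = "all") {
  if (!condition %in% trials$condition)
    stop("condition '", condition, "' absent from dataset")
  keep <- trials$condition %in% c("control", condition) &
    trials$outcome %in% c("correct", "error")
  if (type != "all") keep <- keep & trials$type == type
  tt <- trials[keep, , drop = FALSE]
  tt$arm <- ifelse(tt$condition == "control", "ctrl", "stim")
  sessions <- sort(unique(tt$session_id))
  mouse_of <- tapply(tt$mouse_id, tt$session_id, `[`, 1)[sessions]
  get <- function(arm) {
    x <- tt[tt$arm == arm, ]
    n <- tapply(rep(1, nrow(x)), factor(x$session_id, levels = sessions), sum)
    k <- tapply(x$outcome == "correct", factor(x$session_id, levels = sessions), sum)
    n[is.na(n)] <- 0; k[is.na(k)] <- 0
    list(n = as.numeric(n), k = as.numeric(k))
  }
  ctrl <- get("ctrl"); stim <- get("stim")
  data.frame(session_id = sessions, mouse_id = as.character(mouse_of),
             n_ctrl = ctrl$n, k_ctrl = ctrl$k,
             n_stim = stim$n, k_stim = stim$k,
             stringsAsFactors = FALSE)
}

# internal: pooled stim-minus-control performance change from session counts
delta_from_counts <- function(sc) {
  if (sum(sc$n_stim) == 0 || sum(sc$n_ctrl) == 0) return(NA_real_)
  sum(sc$k_stim) / sum(sc$n_stim) - sum(sc$k_ctrl) / sum(sc$n_ctrl)
}

#' Photostimulation-induced performance change
#'
#' Observed change in fraction-correct between one photostimulation
#' condition and control trials (stim minus control), pooled over sessions
#' and mice, excluding early-lick and ignore trials.
#'
#' @param trials behavior data.frame.
#' @param condition condition label (e.g. `"spot05:delay"`).
#' @param type `"all"` (default), `"left"` or `"right"`.
#' @return numeric Δperformance (probability units).
#' @export
delta_performance <- function(trials, condition, type = "all") {
  delta_from_counts(session_counts(trials, condition, type))
}

#' Hierarchical bootstrap test of a performance change
#'
#' Tests an observed photostimulation-induced performance change against
#' behavioral variability by nested resampling with replacement from
#' (1) mice, (2) the sessions performed by each resampled mouse and
#' (3) the trials within each resampled session (stimulation and control
#' trials resampled within their own stratum so both arms stay
#' represented). Each replicate recomputes the performance change; the
#' one-sided p-value is the fraction of replicates whose change has the
#' sign opposite to the observed change (replicates with exactly zero
#' change count one half). A p-value of zero is reported as `1/n_reps`.
#'
#' `method = "binomial"` draws each session's resampled correct count as
#' Binomial(n, k/n), which is distributionally identical to index-level
#' trial resampling for a fraction-correct statistic and much faster;
#' `method = "index"` resamples literal trial indices.
#'
#' @param trials behavior data.frame ([gen_behavior()] schema).
#' @param condition photostimulation condition label.
#' @param n_reps bootstrap replicates (default 10000; at least 1000).
#' @param seed RNG seed.
#' @param type `"all"`, `"left"` or `"right"`.
#' @param method `"binomial"` (default) or `"index"`.
#' @param audit with `method = "index"`, also return per-replicate
#'   resampling structure for the first `audit` replicates (default 0).
#' @return object of class `bootstrap_report`: list with `condition`,
#'   `type`, `observed_delta`, `p_value`, `p_floored`, `n_reps`,
#'   `replicates` (the replicate deltas), and `audit` (NULL unless
#'   requested).
#' @export
hierarchical_bootstrap <- function(trials, condition, n_reps = 10000,
                                   seed = 1L, type = "all",
                                   method = c("binomial", "index"),
                                   audit = 0L) {
  method <- match.arg(method)
  if (n_reps < 1000) stop("n_reps must be at least 1000")
  sc <- session_counts(trials, condition, type)
  observed <- delta_from_counts(sc)
  mice <- unique(sc$mouse_id)
  if (length(mice) < 2)
    warning("hierarchical bootstrap over a single mouse: ",
            "mouse-level variability cannot be resampled")
  sess_by_mouse <- split(seq_len(nrow(sc)), sc$mouse_id)
  p_ctrl <- ifelse(sc$n_ctrl > 0, sc$k_ctrl / sc$n_ctrl, 0)
  p_stim <- ifelse(sc$n_stim > 0, sc$k_stim / sc$n_stim, 0)

  trial_pool <- NULL
  if (method == "index") {
    keep <- trials$condition %in% c("control", condition) &
      trials$outcome %in% c("correct", "error")
    if (type != "all") keep <- keep & trials$type == type
    tp <- trials[keep, , drop = FALSE]
    tp$arm <- ifelse(tp$condition == "control", "ctrl", "stim")
    trial_pool <- split(tp, tp$session_id)
  }

  set.seed(seed)
  reps <- numeric(n_reps)
  audit_log <- if (audit > 0) vector("list", min(audit, n_reps)) else NULL
  n_mice <- length(mice)
  for (r in seq_len(n_reps)) {
    m_idx <- sample.int(n_mice, n_mice, replace = TRUE)
    sess <- unlist(lapply(m_idx, function(mi) {
      s <- sess_by_mouse[[mice[mi]]]
      s[sample.int(length(s), length(s), replace = TRUE)]
    }), use.names = FALSE)
    if (method == "binomial") {
      ks <- stats::rbinom(length(sess), sc$n_stim[sess], p_stim[sess])
      kc <- stats::rbinom(length(sess), sc$n_ctrl[sess], p_ctrl[sess])
      ns <- sum(sc$n_stim[sess]); nc <- sum(sc$n_ctrl[sess])
      reps[r] <- if (ns > 0 && nc > 0) sum(ks) / ns - sum(kc) / nc else NA
    } else {
      ks <- kc <- ns <- nc <- 0
      rows <- if (!is.null(audit_log) && r <= length(audit_log)) list() else NULL
      for (si in sess) {
        pool <- trial_pool[[sc$session_id[si]]]
        for (arm in c("stim", "ctrl")) {
          px <- pool[pool$arm == arm, , drop = FALSE]
          if (!nrow(px)) next
          pick <- sample.int(nrow(px), nrow(px), replace = TRUE)
          ok <- sum(px$outcome[pick] == "correct")
          if (arm == "stim") { ks <- ks + ok; ns <- ns + nrow(px) }
          else { kc <- kc + ok; nc <- nc + nrow(px) }
          if (!is.null(rows))
            rows[[length(rows) + 1]] <- data.frame(
              mouse_id = px$mouse_id[1], session_id = px$session_id[1],
              arm = arm, trial_id = px$trial_id[pick],
              stringsAsFactors = FALSE)
        }
      }
      reps[r] <- if (ns > 0 && nc > 0) ks / ns - kc / nc else NA
      if (!is.null(rows) && r <= length(audit_log))
        audit_log[[r]] <- do.call(rbind, rows)
    }
  }
  reps_ok <- reps[is.finite(reps)]
  if (!is.finite(observed) || observed == 0) {
    p <- 0.5
  } else {
    opp <- if (observed > 0) reps_ok < 0 else reps_ok > 0
    p <- (sum(opp) + 0.5 * sum(reps_ok == 0)) / length(reps_ok)
  }
  floored <- p < 1 / n_reps
  structure(list(condition = condition, type = type,
                 observed_delta = observed,
                 p_value = max(p, 1 / n_reps), p_floored = floored,
                 n_reps = n_reps, replicates = reps, audit = audit_log),
            class = "bootstrap_report")
}

#' Benjamini-Hochberg step-up correction
#'
#' Flags the significant members of a family of one-sided p-values by the
#' step-up rule: sort the p-values ascending, find the largest rank i with
#' P(i) <= alpha * i / m, and score ranks 1..i as significant, mapped back
#' to the original order. Implemented through [stats::p.adjust()]
#' (`method = "BH"`), which is equivalent.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param alpha family threshold (default 0.025).
#' @param m number of comparisons (default `length(pvals)`; 16 for the
#'   photostimulation grid).
#' @return logical vector of significance flags, same order as `pvals`.
#' @export
bh_correct <- function(pvals, alpha = 0.025, m = length(pvals)) {
  if (!length(pvals)) return(logical(0))
  stopifnot(all(pvals >= 0 & pvals <= 1), m >= length(pvals))
  stats::p.adjust(pvals, method = "BH", n = m) <= alpha
}
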