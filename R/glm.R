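#' Variance accounted for
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` over the
#' trial-concatenated series; can be negative on held-out data.
#'
#' @param y observed series (non-constant).
#' @param yhat predicted series, same length.
#' @return numeric R^2; `NA` (with a warning) when `y` is constant.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant observed series: R^2 undefined")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

# internal: per-trial lag shift of the embedding matrix; frame t is paired
# with the embedding at frame t - lag, clamped at trial edges (the same
# convention the generator uses)
shift_embeddings <- function(E, trial_id, lag) {
  if (lag == 0) return(E)
  out <- E
  for (tr in unique(trial_id)) {
    rows <- which(trial_id == tr)
    src <- seq_along(rows) - lag
    src <- pmin(pmax(src, 1L), length(rows))
    out[rows, ] <- E[rows[src], , drop = FALSE]
  }
  out
}

#' Fit a lagged, L1-penalized Poisson GLM of spiking on video embeddings
#'
#' Predicts a unit's binned spike counts from the 32-dimensional per-frame
#' video embeddings with a log-link Poisson GLM and L1-regularized weights.
#' A separate model is fitted with the spike train shifted by each lag in
#' `lags` (multiples of the frame step, both directions); parameters are
#' fitted on 80% of trials, the penalty strength is chosen on a validation
#' split of the training trials, and the model with the largest R^2 on the
#' held-out 20% of trials is retained.
#'
#' @param session an `embedding_session` ([gen_embeddings()]), or any list
#'   with `E`, `trial_id`, `step_s`.
#' @param counts per-frame spike counts of the unit.
#' @param lags integer lags to scan (default -5:5).
#' @param split fraction of trials used for training (default 0.8).
#' @param seed RNG seed for the trial split.
#' @param nlambda length of the L1 penalty path searched (default 20).
#' @param relax if TRUE, after the lag and penalty are chosen the weights
#'   on the L1-selected support are refit by an unpenalized Poisson GLM on
#'   the training trials (relaxed lasso). This removes the shrinkage bias
#'   of the penalized weights, which otherwise leaves a small systematic
#'   fraction of any movement-borne rate modulation in the subtraction
#'   residual; recommended when the fit feeds [residual_selectivity()].
#'   Default FALSE.
#' @return object of class `glm_fit`: list with `lag` (chosen), `weights`
#'   (length-32), `intercept`, `lambda`, `test_r2` (at the chosen lag),
#'   `per_lag` (data.frame `lag`, `test_r2`, `lambda`), `pred_rate_hz`
#'   (predicted rate for every frame at the chosen lag), `test_trials`,
#'   `zero_unit`.
#' @export
fit_lagged_glm <- function(session, counts, lags = -5:5, split = 0.8,
                           seed = 1L, nlambda = 20, relax = FALSE) {
  E <- session$E; trial_id <- session$trial_id; step <- session$step_s
  stopifnot(length(counts) == nrow(E))
  trials <- unique(trial_id)
  if (length(trials) < 10) stop("need at least 10 trials")
  set.seed(seed)
  n_train <- max(2L, round(split * length(trials)))
  train_trials <- sample(trials, n_train)
  test_trials <- setdiff(trials, train_trials)
  n_val <- max(1L, round(0.25 * n_train))
  val_trials <- sample(train_trials, n_val)
  fit_rows <- trial_id %in% setdiff(train_trials, val_trials)
  val_rows <- trial_id %in% val_trials
  train_rows <- trial_id %in% train_trials
  test_rows <- trial_id %in% test_trials

  if (sum(counts) == 0) {
    return(structure(list(lag = 0L, weights = numeric(ncol(E)),
                          intercept = -Inf, lambda = NA_real_, test_r2 = 0,
                          per_lag = data.frame(lag = 0L, test_r2 = 0,
                                               lambda = NA_real_),
                          pred_rate_hz = numeric(nrow(E)),
                          test_trials = test_trials, zero_unit = TRUE),
                     class = "glm_fit"))
  }

  if (all(apply(E, 2, stats::var) == 0)) {
    # degenerate embeddings: intercept-only model, prediction is the mean
    mu <- mean(counts[train_rows])
    return(structure(list(lag = 0L, weights = numeric(ncol(E)),
                          intercept = log(mu), lambda = NA_real_,
                          test_r2 = r_squared(counts[test_rows],
                                              rep(mu, sum(test_rows))),
                          per_lag = data.frame(lag = 0L,
                                               test_r2 = NA_real_,
                                               lambda = NA_real_),
                          pred_rate_hz = rep(mu / step, nrow(E)),
                          test_trials = test_trials, zero_unit = FALSE),
                     class = "glm_fit"))
  }

  per_lag <- data.frame(lag = lags, test_r2 = NA_real_, lambda = NA_real_)
  best <- NULL
  for (i in seq_along(lags)) {
    X <- shift_embeddings(E, trial_id, lags[i])
    # penalty strength: path fitted on the inner-train rows, scored on the
    # validation rows
    path <- glmnet::glmnet(X[fit_rows, , drop = FALSE], counts[fit_rows],
                           family = "poisson", alpha = 1, nlambda = nlambda)
    mu_val <- stats::predict(path, X[val_rows, , drop = FALSE],
                             type = "response")
    val_r2 <- apply(mu_val, 2, function(m) r_squared(counts[val_rows], m))
    lam <- path$lambda[which.max(val_r2)]
    # refit at the chosen penalty on all training trials
    refit <- glmnet::glmnet(X[train_rows, , drop = FALSE], counts[train_rows],
                            family = "poisson", alpha = 1,
                            lambda = c(lam * 2, lam))
    mu_test <- stats::predict(refit, X[test_rows, , drop = FALSE],
                              type = "response", s = lam)[, 1]
    r2 <- r_squared(counts[test_rows], mu_test)
    per_lag$test_r2[i] <- r2
    per_lag$lambda[i] <- lam
    if (is.null(best) || (is.finite(r2) && r2 > best$r2)) {
      mu_all <- stats::predict(refit, X, type = "response", s = lam)[, 1]
      cf <- as.numeric(stats::coef(refit, s = lam))
      best <- list(lag = lags[i], r2 = r2, lambda = lam,
                   intercept = cf[1], weights = cf[-1],
                   pred_rate_hz = mu_all / step)
    }
  }
  if (relax && any(best$weights != 0)) {
    supp <- which(best$weights != 0)
    Xb <- shift_embeddings(E, trial_id, best$lag)
    refit <- tryCatch(
      stats::glm.fit(cbind(1, Xb[train_rows, supp, drop = FALSE]),
                     counts[train_rows], family = stats::poisson()),
      error = function(e) NULL)
    if (!is.null(refit) && refit$converged) {
      cf <- refit$coefficients
      best$intercept <- cf[1]
      best$weights <- numeric(ncol(E))
      best$weights[supp] <- cf[-1]
      mu_all <- as.numeric(exp(cbind(1, Xb[, supp, drop = FALSE]) %*% cf))
      best$pred_rate_hz <- mu_all / step
      best$r2 <- r_squared(counts[test_rows], mu_all[test_rows])
    }
  }
  structure(list(lag = best$lag, weights = best$weights,
                 intercept = best$intercept, lambda = best$lambda,
                 test_r2 = best$r2, per_lag = per_lag,
                 pred_rate_hz = best$pred_rate_hz,
                 test_trials = test_trials, zero_unit = FALSE),
            class = "glm_fit")
}

#' Residual trial-type selectivity after movement prediction
#'
#' The movement control: the GLM-predicted spike rate is subtracted from
#' the observed spike rate (first smoothed with a centered boxcar of
#' 425 ms at 25-ms frame steps, 340 ms at 17-ms steps), and trial-type
#' selectivity is recomputed on the residuals with the same held-out
#' preference scheme as the spike-count analysis. If the unit's
#' selectivity is carried by its movements, the residual selectivity
#' collapses toward zero; if it is movement-independent, it survives.
#'
#' @param session an `embedding_session`.
#' @param counts per-frame spike counts of the unit.
#' @param fit the unit's [fit_lagged_glm()] result.
#' @param epoch epoch for the per-trial statistic (default `"delay"`).
#' @param n_pref_trials,alpha see [held_out_selectivity()].
#' @return list with `residual` and `original` (each a
#'   [held_out_selectivity()] result; amplitudes in Hz), and
#'   `smooth_bins` used.
#' @export
residual_selectivity <- function(session, counts, fit, epoch = "delay",
                                 n_pref_trials = 15, alpha = 0.01) {
  step <- session$step_s
  smooth_s <- if (abs(step - 0.025) < 1e-9) 0.425 else 0.340
  k <- max(1L, round(smooth_s / step))
  win <- task_epochs()[[epoch]]
  in_epoch <- session$frame_t >= win[1] & session$frame_t < win[2]
  trials <- session$trials
  n_f <- length(session$frame_t)
  rate_obs <- counts / step
  res_mean <- orig_mean <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    rows <- which(session$trial_id == trials$trial_id[i])
    stopifnot(length(rows) == n_f)
    y_sm <- moving_average(rate_obs[rows], k)
    # prediction smoothed with the same window, so epoch-onset transients
    # enter both series identically and cancel in the residual
    resid <- y_sm - moving_average(fit$pred_rate_hz[rows], k)
    res_mean[i] <- mean(resid[in_epoch])
    orig_mean[i] <- mean(y_sm[in_epoch])
  }
  list(residual = held_out_selectivity(res_mean, trials$type,
                                       n_pref_trials, alpha),
       original = held_out_selectivity(orig_mean, trials$type,
                                       n_pref_trials, alpha),
       smooth_bins = k)
}
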