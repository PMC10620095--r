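#' Photostimulation condition grid
#'
#' The default perturbation design: a 4 x 4 grid of photostimulation spots
#' (1-mm spacing) crossed with the three task epochs, plus a control
#' (no-stimulation) condition.
#'
#' @return data.frame with `spot` ("spot01".."spot16"), `epoch`, and the
#'   spot's grid coordinates `grid_x_mm`, `grid_y_mm`.
#' @export
stim_grid <- function() {
  g <- expand.grid(col = 1:4, row = 1:4)
  spots <- data.frame(spot = sprintf("spot%02d", 1:16),
                      grid_x_mm = g$col - 1, grid_y_mm = g$row - 1,
                      stringsAsFactors = FALSE)
  out <- merge(spots,
               data.frame(epoch = c("sample", "delay", "response"),
                          stringsAsFactors = FALSE))
  out[order(out$spot, out$epoch),
      c("spot", "epoch", "grid_x_mm", "grid_y_mm")]
}

#' Generate a behavioral perturbation dataset
#'
#' Emulates the photostimulation mapping experiment: mice run sessions of
#' the delayed-response task in which a fraction of trials receive
#' photostimulation in one of 16 grid spots during one of the three epochs.
#' Outcomes are Bernoulli draws from the control performance, shifted by the
#' configured per-(spot, epoch) bias on stimulation trials; early-lick and
#' ignore trials occur at configured rates and are not scoreable.
#'
#' @param config a [gen_config()]; fields `perf_control` (per trial type),
#'   `stim_bias` (16 x 3 matrix, probability units), `stim_fraction`,
#'   `p_early`, `p_ignore`.
#' @param n_mice,sessions_per_mouse,trials_per_session design counts
#'   (all >= 1).
#' @return data.frame with one row per trial: `mouse_id`, `session_id`,
#'   `trial_id`, `type`, `condition` ("control" or "spotNN:epoch"), `spot`,
#'   `epoch` (NA for control), `outcome`.
#' @export
gen_behavior <- function(config, n_mice, sessions_per_mouse,
                         trials_per_session) {
  stopifnot(inherits(config, "gen_config"), n_mice >= 1,
            sessions_per_mouse >= 1, trials_per_session >= 1)
  perf <- config$perf_control
  if (any(perf < 0 | perf > 1)) stop("perf_control outside [0, 1]")
  bias <- config$stim_bias
  stopifnot(is.matrix(bias), nrow(bias) == 16, ncol(bias) == 3)
  if (any(perf["left"] + bias < -1e-9 | perf["left"] + bias > 1 + 1e-9) ||
      any(perf["right"] + bias < -1e-9 | perf["right"] + bias > 1 + 1e-9))
    stop("stim_bias pushes performance outside [0, 1]")
  grid <- stim_grid()
  if (!is.null(config$stim_conditions)) {
    lab <- paste0(grid$spot, ":", grid$epoch)
    bad <- setdiff(config$stim_conditions, lab)
    if (length(bad)) stop("unknown stim condition(s): ",
                          paste(bad, collapse = ", "))
    grid <- grid[lab %in% config$stim_conditions, , drop = FALSE]
  }

  set.seed(split_seed(config$seed, "behavior"))
  res <- list(); k <- 0L
  for (m in seq_len(n_mice)) {
    for (s in seq_len(sessions_per_mouse)) {
      n <- trials_per_session
      type <- sample(c("left", "right"), n, replace = TRUE)
      is_stim <- stats::runif(n) < config$stim_fraction
      cond_idx <- ifelse(is_stim, sample.int(nrow(grid), n, replace = TRUE), NA)
      spot <- ifelse(is_stim, grid$spot[cond_idx], NA)
      epoch <- ifelse(is_stim, grid$epoch[cond_idx], NA)
      p <- unname(perf[type])
      b <- ifelse(is_stim, bias[cbind(match(spot, rownames(bias)),
                                      match(epoch, colnames(bias)))], 0)
      p <- pmin(1, pmax(0, p + b))
      u <- stats::runif(n)
      outcome <- ifelse(u < config$p_early, "early",
                 ifelse(u < config$p_early + config$p_ignore, "ignore",
                 ifelse(stats::runif(n) < p, "correct", "error")))
      k <- k + 1L
      res[[k]] <- data.frame(
        mouse_id = sprintf("mouse%02d", m),
        session_id = sprintf("mouse%02d_s%02d", m, s),
        trial_id = seq_len(n), type = type,
        condition = ifelse(is_stim, paste0(spot, ":", epoch), "control"),
        spot = spot, epoch = epoch, outcome = outcome,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
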