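# Independent oracles and fixture builders used across the suite.

# Brute-force Benjamini-Hochberg step-up: evaluate every rank explicitly.
bh_bruteforce <- function(p, alpha, m = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  i_max <- 0L
  for (i in seq_along(ps)) if (ps[i] <= alpha * i / m) i_max <- i
  flags <- rep(FALSE, length(p))
  if (i_max > 0) flags[ord[seq_len(i_max)]] <- TRUE
  flags
}

# Brute-force 3-D Gaussian-product KDE: explicit double loop, per mouse,
# averaged across mice.
kde_bruteforce <- function(points, h) {
  X <- as.matrix(points[, c("x_um", "y_um", "z_um")])
  mice <- unique(points$mouse_id)
  out <- matrix(0, nrow(X), length(mice))
  for (j in seq_along(mice)) {
    S <- X[points$mouse_id == mice[j], , drop = FALSE]
    for (i in seq_len(nrow(X))) {
      acc <- 0
      for (q in seq_len(nrow(S))) {
        k <- 1
        for (ax in 1:3)
          k <- k * stats::dnorm(X[i, ax] - S[q, ax], sd = h[ax])
        acc <- acc + k
      }
      out[i, j] <- acc / nrow(S)
    }
  }
  rowMeans(out)
}

# Piecewise-constant Poisson unit: rates given per epoch and trial type.
# rates: list(left = c(presample=, sample=, delay=, response=), right = ...)
make_rate_unit <- function(rates, n_per_type = 30, seed = 1) {
  set.seed(seed)
  ep <- task_epochs()
  wins <- ep[c("presample", "sample", "delay", "response")]
  trials <- data.frame(
    trial_id = seq_len(2 * n_per_type),
    type = rep(c("left", "right"), n_per_type),
    outcome = "correct", stringsAsFactors = FALSE)
  sp <- list()
  for (i in seq_len(nrow(trials))) {
    r <- rates[[trials$type[i]]]
    tt <- unlist(lapply(names(wins), function(w) {
      lam <- r[[w]] * (wins[[w]][2] - wins[[w]][1])
      n <- stats::rpois(1, lam)
      if (n == 0) return(numeric(0))
      sort(stats::runif(n, wins[[w]][1], wins[[w]][2]))
    }))
    if (length(tt)) sp[[length(sp) + 1]] <- data.frame(trial_id = i, t_s = tt)
  }
  list(unit_id = "synthetic", x_um = 0, y_um = 0, z_um = 0,
       class = "SS-only", trials = trials,
       spikes = if (length(sp)) do.call(rbind, sp)
                else data.frame(trial_id = integer(), t_s = numeric()),
       cs = NULL)
}

# A minimal atlas object with hand-chosen volumes, for arithmetic tests.
toy_atlas <- function(volumes, extent_um = 1000) {
  n <- length(volumes)
  zones <- data.frame(
    zone = names(volumes), lobule = names(volumes),
    volume_voxels = as.numeric(volumes),
    ml_min_um = 0, ml_max_um = extent_um,
    ap_min_um = (seq_len(n) - 1) * extent_um,
    ap_max_um = seq_len(n) * extent_um,
    dv_min_um = 0, dv_max_um = extent_um,
    vermal = TRUE, stringsAsFactors = FALSE)
  structure(list(zones = zones, splits = numeric(0), pathway = "fastigial"),
            class = "cb_atlas")
}

# Points data.frame helper
make_points <- function(lobule, mouse_id = "m1", x_um = 100) {
  n <- length(lobule)
  data.frame(x_um = rep_len(x_um, n), y_um = 50, z_um = 50,
             hemisphere = "R", lobule = lobule,
             mouse_id = rep_len(mouse_id, n), stringsAsFactors = FALSE)
}
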