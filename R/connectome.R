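#' Split lobules into medial and lateral sub-lobules
#'
#' Relabels points in splittable lobules as `med-X` or `lat-X` according to
#' the absolute mediolateral distance of the point from the midline versus
#' the lobule's split threshold. A distance greater than or equal to the
#' threshold is lateral (tie goes lateral). Points in non-splittable
#' lobules keep their lobule label.
#'
#' @param points data.frame with at least `x_um` (signed mediolateral, um)
#'   and `lobule`.
#' @param atlas a [cb_atlas()]; its `splits` supply the thresholds (um).
#' @param thresholds optional named numeric overriding `atlas$splits`.
#' @return `points` with a `zone` column added (or replaced).
#' @export
split_sublobules <- function(points, atlas = cb_atlas(), thresholds = NULL) {
  thr <- if (is.null(thresholds)) atlas$splits else thresholds
  zone <- points$lobule
  for (lb in names(thr)) {
    sel <- points$lobule == lb
    if (!any(sel)) next
    lat <- abs(points$x_um[sel]) >= thr[lb]
    zone[sel] <- paste0(ifelse(lat, "lat-", "med-"), lb)
  }
  points$zone <- zone
  points
}

#' Normalized connectivity density per lobule or sub-lobule
#'
#' For each mouse, counts points per zone, converts counts to fractions of
#' that mouse's total (so fractions sum to 1 over included zones,
#' compensating for infection-rate variability), and divides each fraction
#' by the zone volume (in 10-um reference voxels) to obtain the normalized
#' density. Zone means and s.e.m. are computed across mice, never by
#' pooling points.
#'
#' @param points data.frame with `x_um`, `hemisphere`, `lobule`,
#'   `mouse_id` (a `zone` column is recomputed from the atlas splits).
#' @param atlas a [cb_atlas()].
#' @param hemisphere `"combine"` (default; pool both hemispheres — the
#'   convention for the mossy-fiber input map) or `"L"`/`"R"` (restrict to
#'   one hemisphere and use half the zone volume — the convention for the
#'   Purkinje-cell output map).
#' @param level `"zone"` (sub-lobule-resolved, default) or `"lobule"`.
#' @return object of class `connectivity_profile`: list with
#'   `per_mouse` (data.frame `mouse_id`, `zone`, `count`, `fraction`,
#'   `density`), `summary` (data.frame `zone`, `volume_voxels`,
#'   `mean_density`, `sem_density`, `mean_fraction`), `hemisphere`, `level`.
#' @export
normalized_density <- function(points, atlas = cb_atlas(),
                               hemisphere = c("combine", "L", "R"),
                               level = c("zone", "lobule")) {
  hemisphere <- match.arg(hemisphere)
  level <- match.arg(level)
  zones <- atlas$zones
  unknown <- setdiff(unique(points$lobule), zones$lobule)
  if (length(unknown))
    stop("points carry lobule labels not in the atlas: ",
         paste(unknown, collapse = ", "))
  if (hemisphere != "combine")
    points <- points[points$hemisphere == hemisphere, , drop = FALSE]
  points <- split_sublobules(points, atlas)

  if (level == "zone") {
    labels <- zones$zone
    vols <- stats::setNames(zones$volume_voxels, zones$zone)
  } else {
    labels <- unique(zones$lobule)
    vols <- tapply(zones$volume_voxels, zones$lobule, sum)[labels]
    points$zone <- points$lobule
  }
  if (hemisphere != "combine") vols <- vols / 2

  mice <- sort(unique(points$mouse_id))
  empty <- setdiff(mice, unique(points$mouse_id[!is.na(points$zone)]))
  per_mouse <- list()
  for (m in mice) {
    cnt <- table(factor(points$zone[points$mouse_id == m], levels = labels))
    tot <- sum(cnt)
    if (tot == 0) {
      warning("mouse ", m, " has zero points; excluded from the profile")
      next
    }
    f <- as.numeric(cnt) / tot
    per_mouse[[m]] <- data.frame(
      mouse_id = m, zone = labels, count = as.numeric(cnt),
      fraction = f, density = f / as.numeric(vols[labels]),
      stringsAsFactors = FALSE)
  }
  if (!length(per_mouse)) stop("no mouse with at least one point")
  pm <- do.call(rbind, per_mouse)
  rownames(pm) <- NULL
  dmat <- matrix(pm$density, nrow = length(labels),
                 dimnames = list(labels, NULL))
  fmat <- matrix(pm$fraction, nrow = length(labels))
  n_mice <- ncol(dmat)
  summary <- data.frame(
    zone = labels,
    volume_voxels = as.numeric(vols[labels]),
    mean_density = rowMeans(dmat),
    sem_density = if (n_mice > 1) apply(dmat, 1, stats::sd) / sqrt(n_mice)
                  else rep(0, length(labels)),
    mean_fraction = rowMeans(fmat),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(per_mouse = pm, summary = summary,
                 hemisphere = hemisphere, level = level, n_mice = n_mice),
            class = "connectivity_profile")
}

#' Kernel density estimate at annotated points
#'
#' Gaussian-product kernel density estimation in three dimensions,
#' evaluated at every annotated point: the density is computed separately
#' for each mouse (injection case) from that mouse's points, then averaged
#' across mice. Used for display binning of point clouds.
#'
#' @param points data.frame with `x_um`, `y_um`, `z_um`, `mouse_id`.
#' @param kernel_widths_um numeric length-3, Gaussian sigma per axis (um);
#'   default `c(20, 20, 20)`.
#' @return numeric vector: averaged density at each row of `points`
#'   (per um^3).
#' @export
kde_map <- function(points, kernel_widths_um = c(20, 20, 20)) {
  stopifnot(length(kernel_widths_um) == 3, all(kernel_widths_um > 0))
  n <- nrow(points)
  if (n == 0) return(numeric(0))
  X <- as.matrix(points[, c("x_um", "y_um", "z_um")])
  h <- kernel_widths_um
  mice <- unique(points$mouse_id)
  acc <- matrix(0, n, length(mice))
  for (j in seq_along(mice)) {
    S <- X[points$mouse_id == mice[j], , drop = FALSE]
    m <- nrow(S)
    # product of per-axis Gaussian kernels, averaged over the mouse's points
    dens <- numeric(n)
    for (ax in 1:3) {
      d <- outer(X[, ax], S[, ax], "-") / h[ax]
      k <- exp(-0.5 * d^2) / (sqrt(2 * pi) * h[ax])
      if (ax == 1) K <- k else K <- K * k
    }
    acc[, j] <- rowSums(K) / m
  }
  rowMeans(acc)
}

#' Classify regions by conjunctive input-output connectivity
#'
#' Applies a threshold to the cross-mouse mean normalized densities of an
#' input (mossy-fiber) and an output (Purkinje-cell) profile: zones above
#' both thresholds are conjunction regions, above only the input threshold
#' input-dominant, above only the output threshold output-dominant, and
#' above neither excluded.
#'
#' @param input_profile,output_profile [normalized_density()] results over
#'   the same zone set.
#' @param theta density threshold (default 1e-11, on the
#'   fraction-per-10-um-voxel scale).
#' @return data.frame `zone`, `input_density`, `output_density`, `region`
#'   (factor: conjunction / input-dominant / output-dominant / excluded),
#'   with attribute `theta`.
#' @export
classify_regions <- function(input_profile, output_profile, theta = 1e-11) {
  stopifnot(theta > 0)
  zi <- input_profile$summary
  zo <- output_profile$summary
  if (!setequal(zi$zone, zo$zone))
    stop("input and output profiles cover different zone sets")
  zo <- zo[match(zi$zone, zo$zone), ]
  inp <- zi$mean_density > theta
  out <- zo$mean_density > theta
  region <- ifelse(inp & out, "conjunction",
            ifelse(inp, "input-dominant",
            ifelse(out, "output-dominant", "excluded")))
  res <- data.frame(zone = zi$zone,
                    input_density = zi$mean_density,
                    output_density = zo$mean_density,
                    region = factor(region, levels = c(
                      "conjunction", "input-dominant",
                      "output-dominant", "excluded")),
                    stringsAsFactors = FALSE)
  attr(res, "theta") <- theta
  res
}

#' Tessellate point clouds and unit activity into voxels
#'
#' Bins input and output point clouds into cubic voxels
#' (`floor(coordinate / edge)` indexing, so voxels tile space evenly and may
#' span lobule boundaries), normalizes each count to its cloud total, and
#' attaches unit-level activity per voxel: number of recorded units,
#' fraction with significant delay selectivity, and mean selectivity
#' amplitude among the selective units.
#'
#' @param inputs,outputs data.frames with `x_um`, `y_um`, `z_um`.
#' @param units optional data.frame with `x_um`, `y_um`, `z_um`,
#'   `delay_selective` (logical), `amplitude_hz`.
#' @param edge_um voxel edge length (default 100).
#' @return data.frame, one row per non-empty voxel: `ix`, `iy`, `iz`,
#'   `input_n`, `output_n`, `input_strength`, `output_strength`,
#'   `n_units`, `frac_selective`, `mean_amp` (NA where `n_units` = 0).
#' @export
voxelize <- function(inputs, outputs, units = NULL, edge_um = 100) {
  stopifnot(edge_um > 0)
  key <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(character(0))
    paste(floor(df$x_um / edge_um), floor(df$y_um / edge_um),
          floor(df$z_um / edge_um), sep = "_")
  }
  ki <- key(inputs); ko <- key(outputs)
  ku <- if (!is.null(units)) key(units) else character(0)
  all_keys <- unique(c(ki, ko, ku))
  if (!length(all_keys))
    return(data.frame(ix = integer(), iy = integer(), iz = integer(),
                      input_n = numeric(), output_n = numeric(),
                      input_strength = numeric(), output_strength = numeric(),
                      n_units = integer(), frac_selective = numeric(),
                      mean_amp = numeric()))
  cnt <- function(k) as.numeric(table(factor(k, levels = all_keys)))
  input_n <- cnt(ki); output_n <- cnt(ko)
  idx <- do.call(rbind, strsplit(all_keys, "_", fixed = TRUE))
  grid <- data.frame(ix = as.integer(idx[, 1]), iy = as.integer(idx[, 2]),
                     iz = as.integer(idx[, 3]),
                     input_n = input_n, output_n = output_n,
                     input_strength = if (sum(input_n) > 0)
                       input_n / sum(input_n) else 0,
                     output_strength = if (sum(output_n) > 0)
                       output_n / sum(output_n) else 0)
  grid$n_units <- 0L
  grid$frac_selective <- NA_real_
  grid$mean_amp <- NA_real_
  if (!is.null(units) && nrow(units) > 0) {
    f <- factor(ku, levels = all_keys)
    grid$n_units <- as.integer(table(f))
    sel <- tapply(units$delay_selective, f, mean)
    grid$frac_selective[grid$n_units > 0] <- sel[grid$n_units > 0]
    amp <- tapply(ifelse(units$delay_selective, units$amplitude_hz, NA),
                  f, mean, na.rm = TRUE)
    amp[is.nan(amp)] <- NA
    grid$mean_amp[grid$n_units > 0] <- amp[grid$n_units > 0]
  }
  grid
}

# internal: cross-validated R^2 of a linear model y ~ x over rows
cv_r2_lm <- function(y, x, folds = 5, seed = 1) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (stats::var(x) == 0) return(NA_real_)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- stats::lm.fit(cbind(1, x[tr]), y[tr])
    pred[!tr] <- cbind(1, x[!tr]) %*% fit$coefficients
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Voxel-level connectivity-to-activity model comparison
#'
#' Asks whether preparatory activity in a voxel grid is better predicted by
#' input connectivity, output connectivity, or their product. For each
#' activity measure (fraction of delay-selective units; mean selectivity
#' amplitude) fits three single-predictor linear models on voxels with
#' recorded units and reports the cross-validated R-squared of each, plus
#' the winning predictor.
#'
#' @param grid a [voxelize()] result.
#' @param folds cross-validation folds over voxels (default 5).
#' @param seed fold-assignment seed.
#' @return data.frame with `activity` ("frac_selective", "mean_amp"),
#'   `predictor` ("input", "output", "product"), `cv_r2`, `winner`
#'   (logical; highest cv R^2 within the activity measure).
#' @export
connectivity_activity_model <- function(grid, folds = 5, seed = 1) {
  g <- grid[grid$n_units > 0, , drop = FALSE]
  if (nrow(g) < 10)
    stop("need at least 10 voxels with recorded units")
  preds <- list(input = g$input_strength,
                output = g$output_strength,
                product = g$input_strength * g$output_strength)
  rows <- list()
  for (act in c("frac_selective", "mean_amp")) {
    y <- g[[act]]
    r2 <- vapply(preds, function(x) cv_r2_lm(y, x, folds, seed), numeric(1))
    win <- rep(FALSE, 3)
    if (any(is.finite(r2))) win[which.max(r2)] <- TRUE
    rows[[act]] <- data.frame(activity = act, predictor = names(preds),
                              cv_r2 = as.numeric(r2), winner = win,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
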