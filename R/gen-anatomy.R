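#' Default anatomical generation intensities
#'
#' Expected annotation densities (points per mm^3) per atlas zone for the
#' mossy-fiber input map and the Purkinje-cell output map. The defaults
#' encode the connectivity structure of the ALM cortico-cerebellar loop via
#' the fastigial nucleus: input projections target the simplex, Crus 1/2,
#' PRM and vermal lobule VII; output (ALM-projecting) Purkinje cells sit in
#' the medial simplex/Crus and the vermis, so the medial sub-lobules and
#' Lob VII carry both (conjunction), the lateral sub-lobules and PRM carry
#' input only, the remaining vermal lobules and COPY carry output only, and
#' Lob I, PFL and FL carry neither. Zones without a projection are given
#' intensity zero: sparse background mis-annotation is not modeled.
#'
#' @param atlas a [cb_atlas()] object.
#' @return list with named numeric vectors `input` and `output` (points per
#'   mm^3 per zone).
#' @export
default_anatomy_intensity <- function(atlas = cb_atlas()) {
  zones <- atlas$zones$zone
  inp <- stats::setNames(numeric(length(zones)), zones)
  out <- inp
  input_zones <- c("med-SIM", "lat-SIM", "med-Crus 1", "lat-Crus 1",
                   "med-Crus 2", "lat-Crus 2", "PRM", "Lob VII")
  output_zones <- c("med-SIM", "med-Crus 1", "med-Crus 2", "Lob VII",
                    "COPY", "Lob II", "Lob III", "Lob IV-V", "Lob VI",
                    "Lob VIII", "Lob IX", "Lob X")
  inp[intersect(input_zones, zones)] <- 2000
  out[intersect(output_zones, zones)] <- 800
  list(input = inp, output = out)
}

#' Generation configuration
#'
#' Bundles every tunable of the synthetic-data generators with a root seed.
#' Any field can be overridden through `...`; unknown fields are an error.
#'
#' @param seed integer root seed; all stage seeds derive from it via
#'   [split_seed()].
#' @param atlas a [cb_atlas()] object (defines the zone vocabulary).
#' @param ... overrides for fields of the default configuration, see
#'   Details.
#' @details Fields (defaults in parentheses):
#' \describe{
#'   \item{input_intensity, output_intensity}{named per-zone expected points
#'     per mm^3 ([default_anatomy_intensity()]).}
#'   \item{infection_sdlog}{sd of the log-normal per-mouse infection-rate
#'     multiplier (0.4); multiplier has median 1.}
#'   \item{collapse_posterior}{if TRUE, points beyond the posterior edge of
#'     the reference template are collapsed onto its boundary plane,
#'     mimicking registration to the last template section (FALSE).}
#'   \item{baseline_hz}{baseline spike rate (15 Hz).}
#'   \item{select_amp_hz}{trial-type selectivity amplitude: mean extra rate
#'     in the delay epoch for the preferred type (6 Hz).}
#'   \item{frac_selective}{fraction of units given a nonzero amplitude (0.6).}
#'   \item{ramp_shape}{`"linear"` (rate climbs through the delay, mean
#'     amplitude as configured) or `"step"` (constant through the delay).}
#'   \item{cs_rate_hz}{complex-spike rate of Purkinje units (1 Hz).}
#'   \item{pause_ms}{duration of the enforced simple-spike pause after each
#'     complex spike (10 ms).}
#'   \item{purkinje_frac}{fraction of generated units carrying a CS stream
#'     (0.3).}
#'   \item{trials_per_type}{trials per trial type per unit/session (40).}
#'   \item{p_correct}{probability a trial is performed correctly (0.85).}
#'   \item{p_early, p_ignore}{early-lick and ignore rates (0.05, 0.02).}
#'   \item{perf_control}{control fraction-correct per trial type
#'     (c(left = 0.80, right = 0.80)).}
#'   \item{stim_bias}{16 x 3 matrix of performance changes (stim minus
#'     control, probability units) per photostimulation spot x epoch
#'     (all zero).}
#'   \item{stim_fraction}{fraction of trials that are photostimulation
#'     trials (0.5), spread uniformly over the spot x epoch grid.}
#'   \item{stim_conditions}{optional character vector of "spot:epoch"
#'     labels restricting which grid conditions are stimulated (NULL =
#'     full 16 x 3 grid); emulates sessions that test a subset of spots.}
#'   \item{embed_dim}{embedding dimension (32, mirroring the video
#'     autoencoder embedding).}
#'   \item{frame_step_s}{embedding frame step (0.025 s; 0.017 s also
#'     supported).}
#'   \item{embed_ar}{AR(1) coefficient of the latent embedding process
#'     (0.8; ~110-ms decorrelation at 25-ms frames, the timescale of
#'     orofacial movement video).}
#'   \item{coupling_sd}{sd of the log-rate coupling weights of
#'     movement-coupled units (0.4).}
#'   \item{coupling_lag}{lag, in frame steps, at which embeddings drive
#'     the log rate (0).}
#' }
#' @return an object of class `gen_config` (a list).
#' @export
gen_config <- function(seed = 1L, atlas = cb_atlas(), ...) {
  inten <- default_anatomy_intensity(atlas)
  cfg <- list(
    seed = as.integer(seed),
    atlas = atlas,
    input_intensity = inten$input,
    output_intensity = inten$output,
    infection_sdlog = 0.4,
    collapse_posterior = FALSE,
    baseline_hz = 15,
    select_amp_hz = 6,
    frac_selective = 0.6,
    ramp_shape = "linear",
    cs_rate_hz = 1,
    pause_ms = 10,
    purkinje_frac = 0.3,
    trials_per_type = 40,
    p_correct = 0.85,
    p_early = 0.05,
    p_ignore = 0.02,
    perf_control = c(left = 0.80, right = 0.80),
    stim_bias = matrix(0, nrow = 16, ncol = 3,
                       dimnames = list(sprintf("spot%02d", 1:16),
                                       c("sample", "delay", "response"))),
    stim_fraction = 0.5,
    stim_conditions = NULL,
    embed_dim = 32L,
    frame_step_s = 0.025,
    embed_ar = 0.8,
    coupling_sd = 0.4,
    coupling_lag = 0L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown gen_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$baseline_hz >= 0, cfg$cs_rate_hz >= 0, cfg$pause_ms >= 0,
            cfg$trials_per_type >= 1, cfg$embed_dim == 32L,
            all(cfg$perf_control >= 0 & cfg$perf_control <= 1))
  class(cfg) <- "gen_config"
  cfg
}

#' Generate anatomical point clouds
#'
#' Draws annotated mossy-fiber-terminal (input) and Purkinje-cell-soma
#' (output) point clouds from a seeded configuration. Per mouse and zone the
#' point count is Poisson with mean intensity x zone volume x a log-normal
#' per-mouse infection-rate multiplier; point locations are uniform inside
#' the zone's box, assigned to a hemisphere at random (vermal zones span the
#' midline and keep hemisphere labels by the sign of the drawn mediolateral
#' position).
#'
#' @param config a [gen_config()].
#' @param atlas a [cb_atlas()]; defaults to the config's atlas.
#' @param n_mice number of mice per cloud (one "injection case" each).
#' @return list with data.frames `inputs` and `outputs`, columns `x_um`,
#'   `y_um`, `z_um`, `hemisphere` ("L"/"R"), `lobule` (base lobule label),
#'   `zone` (sub-lobule-resolved label), `mouse_id`, `marker`
#'   ("mossy_fiber_terminal" / "purkinje_soma").
#' @export
gen_anatomy <- function(config, atlas = config$atlas, n_mice = 7L) {
  stopifnot(inherits(config, "gen_config"), n_mice >= 1)
  zones <- atlas$zones
  for (nm in c("input_intensity", "output_intensity")) {
    unknown <- setdiff(names(config[[nm]]), zones$zone)
    if (length(unknown))
      stop("intensity specified for unknown zone(s): ",
           paste(unknown, collapse = ", "))
  }

  draw_cloud <- function(intensity, marker, stream) {
    set.seed(split_seed(config$seed, stream))
    mult <- stats::rlnorm(n_mice, meanlog = 0, sdlog = config$infection_sdlog)
    res <- vector("list", n_mice * nrow(zones))
    k <- 0L
    for (m in seq_len(n_mice)) {
      for (i in seq_len(nrow(zones))) {
        lam <- intensity[zones$zone[i]]
        if (is.na(lam)) lam <- 0
        vol_mm3 <- zones$volume_voxels[i] / 1e6  # 10-um voxels -> mm^3
        n <- stats::rpois(1, lam * vol_mm3 * mult[m])
        if (n == 0) next
        ml <- stats::runif(n, zones$ml_min_um[i], zones$ml_max_um[i])
        side <- sample(c(-1, 1), n, replace = TRUE)
        x <- ml * side
        y <- stats::runif(n, zones$ap_min_um[i], zones$ap_max_um[i])
        z <- stats::runif(n, zones$dv_min_um[i], zones$dv_max_um[i])
        k <- k + 1L
        res[[k]] <- data.frame(
          x_um = x, y_um = y, z_um = z,
          hemisphere = ifelse(x < 0, "L", "R"),
          lobule = zones$lobule[i], zone = zones$zone[i],
          mouse_id = sprintf("mouse%02d", m),
          marker = marker, stringsAsFactors = FALSE)
      }
    }
    if (k == 0L)
      return(data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                        hemisphere = character(), lobule = character(),
                        zone = character(), mouse_id = character(),
                        marker = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, res[seq_len(k)])
    if (isTRUE(config$collapse_posterior)) {
      ap_edge <- max(zones$ap_max_um[zones$vermal])
      out$y_um <- pmin(out$y_um, ap_edge)
    }
    rownames(out) <- NULL
    out
  }

  list(inputs = draw_cloud(config$input_intensity, "mossy_fiber_terminal",
                           "anatomy_input"),
       outputs = draw_cloud(config$output_intensity, "purkinje_soma",
                            "anatomy_output"))
}
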