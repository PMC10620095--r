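#' Parametric cerebellar atlas
#'
#' A simplified reference geometry for the cerebellar cortex: every lobule
#' (and, for lobules with a mediolateral connectivity boundary, every
#' medial/lateral sub-lobule) is represented as an axis-aligned box in a
#' common reference space, with a volume expressed as a count of 10-um
#' reference voxels. The boxes are a parametric stand-in for the Allen mesh:
#' they carry realistic CCF-scale volumes and mediolateral extents so that
#' all density arithmetic (fractions, normalized densities, the 1e-11
#' classification threshold, sub-lobule splits) behaves as it does on the
#' real annotation volume.
#'
#' Coordinates are in micrometres. `x_um` is signed mediolateral position
#' (negative = left hemisphere, 0 = midline), `y_um` anteroposterior,
#' `z_um` dorsoventral. Zone extents are stored as absolute distance from
#' the midline (`ml_min_um`, `ml_max_um`); a point at signed position x
#' falls in a zone when `abs(x)` is inside that interval.
#'
#' @param pathway `"fastigial"` (default) or `"dentate"`. Selects the set of
#'   mediolateral split thresholds used to divide SIM, Crus 1, Crus 2 (and,
#'   for the dentate pathway, PRM) into medial and lateral sub-lobules:
#'   fastigial SIM 2.5 mm, Crus 1 3.2 mm, Crus 2 2.7 mm from the midline;
#'   dentate SIM 2.2 mm, Crus 1 2.2 mm, Crus 2 1.7 mm, PRM 2.2 mm.
#' @return An object of class `cb_atlas`: a list with
#'   \describe{
#'     \item{zones}{data.frame, one row per zone (sub-lobule where split,
#'       lobule otherwise): `zone`, `lobule`, `volume_voxels` (10-um voxels),
#'       `ml_min_um`, `ml_max_um`, `ap_min_um`, `ap_max_um`, `dv_min_um`,
#'       `dv_max_um`, `vermal` (spans the midline).}
#'     \item{splits}{named numeric, split threshold in um from the midline
#'       per splittable lobule.}
#'     \item{pathway}{the pathway string.}
#'   }
#' @examples
#' atl <- cb_atlas()
#' head(atl$zones)
#' atl$splits
#' @export
cb_atlas <- function(pathway = c("fastigial", "dentate")) {
  pathway <- match.arg(pathway)
  splits <- switch(pathway,
    fastigial = c("SIM" = 2500, "Crus 1" = 3200, "Crus 2" = 2700),
    dentate   = c("SIM" = 2200, "Crus 1" = 2200, "Crus 2" = 1700, "PRM" = 2200)
  )

  # Lobule-level geometry. Volumes are total (both hemispheres) counts of
  # 10-um voxels, on the scale of the real annotation volume (1 mm^3 = 1e6
  # voxels). AP bands are disjoint within the vermal and within the
  # hemispheric group so that box membership is unique; vermal and
  # hemispheric groups are separated along the mediolateral axis.
  lob <- data.frame(
    lobule = c("Lob I", "Lob II", "Lob III", "Lob IV-V", "Lob VI", "Lob VII",
               "Lob VIII", "Lob IX", "Lob X",
               "SIM", "Crus 1", "Crus 2", "PRM", "COPY", "PFL", "FL"),
    volume_voxels = c(0.15e6, 0.5e6, 1.0e6, 2.2e6, 1.6e6, 0.8e6,
                      1.0e6, 1.3e6, 0.5e6,
                      2.6e6, 3.4e6, 2.4e6, 2.0e6, 0.9e6, 1.5e6, 0.4e6),
    ml_min = c(rep(0, 9), 1000, 1200, 1000, 1000, 1000, 3800, 3800),
    ml_max = c(rep(1000, 9), 4200, 4800, 4400, 3600, 3200, 5200, 5200),
    ap_min = c(seq(0, 8 * 900, by = 900),             # vermal: 900-um bands
               0, 1200, 2400, 3600, 4800, 6000, 7200),
    ap_max = c(seq(900, 9 * 900, by = 900),
               1200, 2400, 3600, 4800, 6000, 7200, 8400),
    dv_min = 0,
    dv_max = 2000,
    stringsAsFactors = FALSE
  )
  lob$vermal <- lob$ml_min == 0

  rows <- lapply(seq_len(nrow(lob)), function(i) {
    L <- lob[i, ]
    thr <- splits[L$lobule]
    if (is.na(thr)) {
      data.frame(zone = L$lobule, lobule = L$lobule,
                 volume_voxels = L$volume_voxels,
                 ml_min_um = L$ml_min, ml_max_um = L$ml_max,
                 ap_min_um = L$ap_min, ap_max_um = L$ap_max,
                 dv_min_um = L$dv_min, dv_max_um = L$dv_max,
                 vermal = L$vermal, stringsAsFactors = FALSE)
    } else {
      stopifnot(thr > L$ml_min, thr < L$ml_max)
      # box model: volume splits in proportion to mediolateral extent
      f_med <- (thr - L$ml_min) / (L$ml_max - L$ml_min)
      data.frame(
        zone = paste0(c("med-", "lat-"), L$lobule),
        lobule = L$lobule,
        volume_voxels = L$volume_voxels * c(f_med, 1 - f_med),
        ml_min_um = c(L$ml_min, thr), ml_max_um = c(thr, L$ml_max),
        ap_min_um = L$ap_min, ap_max_um = L$ap_max,
        dv_min_um = L$dv_min, dv_max_um = L$dv_max,
        vermal = L$vermal, stringsAsFactors = FALSE)
    }
  })
  zones <- do.call(rbind, rows)
  rownames(zones) <- NULL
  stopifnot(!anyDuplicated(zones$zone), all(zones$volume_voxels > 0))

  structure(list(zones = zones, splits = splits, pathway = pathway),
            class = "cb_atlas")
}

#' @export
print.cb_atlas <- function(x, ...) {
  cat("Parametric cerebellar atlas (", x$pathway, " pathway)\n", sep = "")
  cat(nrow(x$zones), "zones,",
      length(unique(x$zones$lobule)), "lobules; split thresholds (um):\n")
  print(x$splits)
  invisible(x)
}

#' Locate points in the atlas
#'
#' Maps signed reference coordinates to the atlas zone whose box contains
#' them. Zones are pairwise disjoint by construction, so membership is
#' unique; points outside every box get `NA`.
#'
#' @param atlas a [cb_atlas()] object.
#' @param x_um,y_um,z_um numeric vectors of coordinates (um; `x_um` signed
#'   mediolateral).
#' @return character vector of zone labels (`NA` where unassigned).
#' @export
atlas_zone_at <- function(atlas, x_um, y_um, z_um) {
  stopifnot(inherits(atlas, "cb_atlas"))
  n <- length(x_um)
  stopifnot(length(y_um) == n, length(z_um) == n)
  ml <- abs(x_um)
  out <- rep(NA_character_, n)
  z <- atlas$zones
  for (i in seq_len(nrow(z))) {
    hit <- ml >= z$ml_min_um[i] & ml < z$ml_max_um[i] &
      y_um >= z$ap_min_um[i] & y_um < z$ap_max_um[i] &
      z_um >= z$dv_min_um[i] & z_um < z$dv_max_um[i]
    out[hit & is.na(out)] <- z$zone[i]
  }
  out
}

#' Task epoch windows
#'
#' The delayed-response task timeline, expressed on a common per-trial time
#' base with the go cue at t = 0: a 0.5-s pre-sample baseline window, a
#' 1.3-s sample epoch, a 1.3-s delay epoch, and a 1.5-s response (answer)
#' window after the go cue.
#'
#' @return named list of `c(start, end)` windows in seconds:
#'   `presample`, `sample`, `delay`, `response`, plus `trial` (full span).
#' @examples
#' task_epochs()$delay  # c(-1.3, 0)
#' @export
task_epochs <- function() {
  list(
    presample = c(-3.1, -2.6),
    sample    = c(-2.6, -1.3),
    delay     = c(-1.3, 0),
    response  = c(0, 1.5),
    trial     = c(-3.1, 1.5)
  )
}

# internal: seconds in a window
epoch_duration <- function(win) win[2] - win[1]
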