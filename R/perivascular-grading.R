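# Vessel detection, 15 um perivascular zones, astroglia density grading.
#
# Grading rule (definitional): grade 0 = no perivascular astroglia;
# grade 1 = mild, density < 100 / mm^2; grade 2 = moderate, 100-300 / mm^2
# (both bounds included); grade 3 = severe, density > 300 / mm^2 or an
# astrogliotic scar surrounding the vessel. The density denominator is the
# area of the 15 um annulus (a pinned reconstruction: the reference area
# behind "per mm^2" is otherwise unspecified).

#' Detect vessel lumens in a hematoxylin OD map
#'
#' Lumens are bright (low-OD) connected regions: OD below
#' `lumen_rel_od` x median in-ROI OD, with area >= `min_lumen_area_um2`,
#' solidity >= `solidity_min`, not touching the image border, and centroid
#' inside the ROI.
#'
#' @param hema_map hematoxylin OD matrix (HE or counterstain channel).
#' @param roi_mask logical ROI matrix, congruent with `hema_map`.
#' @param pixel_size_um physical pixel size.
#' @param min_lumen_area_um2 minimum lumen area (default 80, ~10 um
#'   equivalent diameter).
#' @param solidity_min minimum solidity (lumens are convex-ish).
#' @param lumen_rel_od relative OD cutoff defining "bright".
#' @param roi_name attached to detected vessels.
#' @return list of class `vessel_detection`: `vessels` (data.frame: id,
#'   centroid x/y, area_um2, equivalent_diameter_um, solidity, roi_name),
#'   `labels` (integer matrix of lumen labels), `lumen_mask`.
#' @export
detect_vessels <- function(hema_map, roi_mask, pixel_size_um = 1,
                           min_lumen_area_um2 = 80, solidity_min = 0.8,
                           lumen_rel_od = 0.5, roi_name = NA_character_) {
  if (!all(dim(hema_map) == dim(roi_mask))) stop("shape mismatch")
  med <- stats::median(hema_map[roi_mask])
  bright <- hema_map < lumen_rel_od * med & roi_mask
  labels <- label_components(bright, connectivity = 8)
  keep <- integer(0)
  info <- list()
  min_px <- min_lumen_area_um2 / pixel_size_um^2
  nr <- nrow(hema_map); nc <- ncol(hema_map)
  if (max(labels) > 0) {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    for (k in seq_len(max(labels))) {
      sel <- lab == k
      n <- sum(sel)
      if (n < min_px) next
      rows <- idx[sel, 1]; cols <- idx[sel, 2]
      if (any(rows == 1 | rows == nr | cols == 1 | cols == nc)) next
      sol <- pixel_solidity(rows, cols)
      if (sol < solidity_min) next
      cy <- mean(rows) - 1; cx <- mean(cols) - 1
      if (!roi_mask[round(cy) + 1, round(cx) + 1]) next
      keep <- c(keep, k)
      info[[length(info) + 1]] <- data.frame(
        id = k, x = cx, y = cy, area_um2 = n * pixel_size_um^2,
        equivalent_diameter_um = 2 * sqrt(n * pixel_size_um^2 / pi),
        solidity = sol, roi_name = roi_name)
    }
  }
  out_labels <- labels
  out_labels[!(labels %in% keep)] <- 0L
  vessels <- if (length(info)) do.call(rbind, info) else
    data.frame(id = integer(0), x = numeric(0), y = numeric(0),
               area_um2 = numeric(0), equivalent_diameter_um = numeric(0),
               solidity = numeric(0), roi_name = character(0))
  if (nrow(vessels)) {
    vessels$id <- match(vessels$id, keep)
    out_labels[out_labels > 0] <- match(out_labels[out_labels > 0], keep)
  }
  structure(list(vessels = vessels, labels = out_labels,
                 lumen_mask = out_labels > 0),
            class = "vessel_detection")
}

#' @export
print.vessel_detection <- function(x, ...) {
  cat(sprintf("<vessel_detection> %d lumen(s)\n", nrow(x$vessels)))
  invisible(x)
}

#' Build a vessel detection from manually outlined lumens
#'
#' Parity path for a visual workflow: instead of automated lumen detection,
#' lumen outlines are supplied as a CSV of polygon vertices (columns
#' `vessel_id`, `x`, `y`, pixel units, 0-based; vertices in drawing order
#' per vessel). Polygons are rasterised and packaged exactly like
#' [detect_vessels()] output, so grading works unchanged downstream.
#'
#' @param path CSV file of lumen outlines.
#' @param dim_px `c(rows, cols)` of the target image grid.
#' @param pixel_size_um physical pixel size.
#' @param roi_name attached to the vessels.
#' @return a `vessel_detection` object.
#' @export
vessels_from_outlines <- function(path, dim_px, pixel_size_um = 1,
                                  roi_name = NA_character_) {
  df <- utils::read.csv(path)
  need <- c("vessel_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("outline file needs columns: ", paste(need, collapse = ", "))
  labels <- matrix(0L, dim_px[1], dim_px[2])
  ids <- unique(df$vessel_id)
  info <- list()
  for (k in seq_along(ids)) {
    poly <- df[df$vessel_id == ids[k], ]
    if (nrow(poly) < 3) stop("vessel ", ids[k], ": need >= 3 vertices")
    # even-odd rule point-in-polygon over the bounding box
    x0 <- max(0, floor(min(poly$x))); x1 <- min(dim_px[2] - 1, ceiling(max(poly$x)))
    y0 <- max(0, floor(min(poly$y))); y1 <- min(dim_px[1] - 1, ceiling(max(poly$y)))
    xs <- x0:x1; ys <- y0:y1
    px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
    nv <- nrow(poly)
    inside <- rep(FALSE, length(px))
    j <- nv
    for (i in seq_len(nv)) {
      xi <- poly$x[i]; yi <- poly$y[i]; xj <- poly$x[j]; yj <- poly$y[j]
      cross <- (yi > py) != (yj > py) &
        px < (xj - xi) * (py - yi) / (yj - yi) + xi
      inside <- xor(inside, cross & is.finite(cross))
      j <- i
    }
    sub <- labels[ys + 1, xs + 1, drop = FALSE]
    sub[matrix(inside, length(ys), length(xs))] <- k
    labels[ys + 1, xs + 1] <- sub
    n <- sum(inside)
    if (n == 0) next
    info[[length(info) + 1]] <- data.frame(
      id = k, x = mean(px[inside]), y = mean(py[inside]),
      area_um2 = n * pixel_size_um^2,
      equivalent_diameter_um = 2 * sqrt(n * pixel_size_um^2 / pi),
      solidity = NA_real_, roi_name = roi_name)
  }
  vessels <- if (length(info)) do.call(rbind, info) else
    data.frame(id = integer(0), x = numeric(0), y = numeric(0),
               area_um2 = numeric(0), equivalent_diameter_um = numeric(0),
               solidity = numeric(0), roi_name = character(0))
  structure(list(vessels = vessels, labels = labels,
                 lumen_mask = labels > 0),
            class = "vessel_detection")
}

#' Perivascular zone (annulus) of one vessel
#'
#' Pixels with Euclidean distance to the lumen in (0, `distance_um`\],
#' intersected with the tissue mask and excluding every detected lumen
#' (including other vessels').
#'
#' @param detection a `vessel_detection` from [detect_vessels()].
#' @param vessel_id label of the vessel of interest.
#' @param distance_um zone depth (15 um grading standard).
#' @param tissue_mask logical matrix of analysable tissue.
#' @param pixel_size_um physical pixel size.
#' @return list: `annulus` (logical matrix), `area_mm2`, `distance_px`
#'   (distance map to this lumen, for close-range checks).
#' @export
perivascular_zone <- function(detection, vessel_id, distance_um = 15,
                              tissue_mask = NULL, pixel_size_um = 1) {
  stopifnot(distance_um > 0)
  lumen <- detection$labels == vessel_id
  if (!any(lumen)) stop("unknown vessel id ", vessel_id)
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(!lumen),
                                         nrow(lumen), ncol(lumen))))
  annulus <- d > 0 & d * pixel_size_um <= distance_um & !detection$lumen_mask
  if (!is.null(tissue_mask)) {
    had_zone <- any(annulus)
    annulus <- annulus & tissue_mask
    if (had_zone && !any(annulus)) stop("vessel outside tissue")
  }
  list(annulus = annulus, area_mm2 = mask_area_mm2(annulus, pixel_size_um),
       distance_px = d)
}

#' Count astroglia in a perivascular zone
#'
#' A cell is counted when its soma centroid lies in the annulus; a centroid
#' exactly on the outer boundary (distance = `distance_um`) is inside by the
#' inclusive rule used to build the annulus.
#'
#' @param astro_cells data.frame with centroid columns `x`, `y` (0-based
#'   pixels), e.g. from [measure_cells()] on the GFAP slide.
#' @param zone output of [perivascular_zone()].
#' @return list: `count`, `density_per_mm2`.
#' @export
count_perivascular_astroglia <- function(astro_cells, zone) {
  if (zone$area_mm2 <= 0) stop("zero-area annulus")
  if (nrow(astro_cells) == 0)
    return(list(count = 0L, density_per_mm2 = 0))
  xi <- round(astro_cells$x) + 1; yi <- round(astro_cells$y) + 1
  ok <- xi >= 1 & xi <= ncol(zone$annulus) & yi >= 1 & yi <= nrow(zone$annulus)
  inside <- rep(FALSE, nrow(astro_cells))
  inside[ok] <- zone$annulus[cbind(yi[ok], xi[ok])]
  n <- sum(inside)
  list(count = as.integer(n), density_per_mm2 = n / zone$area_mm2)
}

#' Grade a vessel's perivascular astrogliosis
#'
#' `scar` forces grade 3; otherwise density > 300 / mm^2 is grade 3,
#' 100-300 / mm^2 grade 2 (bounds included), any astroglia below 100 / mm^2
#' grade 1, and no astroglia at all grade 0.
#'
#' @param density_per_mm2 perivascular astroglia density (>= 0).
#' @param astro_count number of perivascular astroglia (>= 0).
#' @param scar astrogliotic scar surrounding the vessel.
#' @return integer grade 0-3.
#' @export
grade_vessel <- function(density_per_mm2, astro_count, scar = FALSE) {
  if (any(density_per_mm2 < 0) || any(astro_count < 0))
    stop("negative inputs")
  ifelse(scar, 3L,
    ifelse(density_per_mm2 > 300, 3L,
      ifelse(density_per_mm2 >= 100, 2L,
        ifelse(astro_count > 0, 1L, 0L))))
}

#' Detect an astrogliotic scar around a vessel
#'
#' Scar = a dense contiguous GFAP-positive band in the inner ring: angular
#' coverage of positive pixels >= `coverage_min` of 360 degrees AND
#' positive-area fraction of the band >= `area_frac_min`.
#'
#' @param gfap_positive_mask logical matrix of GFAP-positive pixels.
#' @param zone output of [perivascular_zone()] (its annulus is the band).
#' @param detection the `vessel_detection` (for the vessel centroid).
#' @param vessel_id vessel label.
#' @param coverage_min angular coverage threshold (fraction of 360 deg).
#' @param area_frac_min positive-area fraction threshold within the band.
#' @param n_sectors angular resolution of the coverage measure.
#' @return logical.
#' @export
detect_scar <- function(gfap_positive_mask, zone, detection, vessel_id,
                        coverage_min = 0.75, area_frac_min = 0.5,
                        n_sectors = 72) {
  band <- zone$annulus
  if (!any(band)) return(FALSE)
  pos <- gfap_positive_mask & band
  area_frac <- sum(pos) / sum(band)
  if (area_frac < area_frac_min) return(FALSE)
  v <- detection$vessels[detection$vessels$id == vessel_id, ]
  idx <- which(pos, arr.ind = TRUE)
  ang <- atan2(idx[, 1] - 1 - v$y, idx[, 2] - 1 - v$x) %% (2 * pi)
  sect <- 1L + as.integer(ang / (2 * pi) * n_sectors) %% n_sectors
  coverage <- length(unique(sect)) / n_sectors
  coverage >= coverage_min
}

#' Close-range perivascular inflammation flag
#'
#' TRUE when at least one astroglia centroid lies within `distance_um` of
#' the lumen boundary (boundary value included).
#'
#' @inheritParams count_perivascular_astroglia
#' @param distance_um close-range distance (default 5 um, a pinned
#'   reconstruction; the rating protocol quantifies no distance).
#' @param pixel_size_um physical pixel size.
#' @export
close_range_flag <- function(astro_cells, zone, distance_um = 5,
                             pixel_size_um = 1) {
  if (nrow(astro_cells) == 0) return(FALSE)
  xi <- round(astro_cells$x) + 1; yi <- round(astro_cells$y) + 1
  ok <- xi >= 1 & xi <= ncol(zone$distance_px) &
    yi >= 1 & yi <= nrow(zone$distance_px)
  if (!any(ok)) return(FALSE)
  d <- zone$distance_px[cbind(yi[ok], xi[ok])] * pixel_size_um
  any(d > 0 & d <= distance_um)
}

#' Assess all vessels of one region
#'
#' Runs zone construction, counting, scar detection, grading and the
#' close-range flag for every detected vessel.
#'
#' @param detection `vessel_detection` from [detect_vessels()].
#' @param astro_cells GFAP cell table ([measure_cells()]).
#' @param gfap_positive_mask GFAP positive-pixel mask (for scar detection).
#' @param tissue_mask logical tissue mask.
#' @param pixel_size_um physical pixel size.
#' @param distance_um perivascular zone depth.
#' @param close_range_um close-range distance.
#' @param scar_coverage_min,scar_area_frac_min scar criteria.
#' @return data.frame of class `vessel_assessment`: one row per vessel with
#'   `vessel_id`, `annulus_area_mm2`, `astro_count`, `density_per_mm2`,
#'   `grade`, `close_range`, `scar`.
#' @export
assess_vessels <- function(detection, astro_cells, gfap_positive_mask = NULL,
                           tissue_mask = NULL, pixel_size_um = 1,
                           distance_um = 15, close_range_um = 5,
                           scar_coverage_min = 0.75,
                           scar_area_frac_min = 0.5) {
  ids <- detection$vessels$id
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    zone <- perivascular_zone(detection, ids[i], distance_um, tissue_mask,
                              pixel_size_um)
    cnt <- count_perivascular_astroglia(astro_cells, zone)
    scar <- if (is.null(gfap_positive_mask)) FALSE else
      detect_scar(gfap_positive_mask, zone, detection, ids[i],
                  scar_coverage_min, scar_area_frac_min)
    out[[i]] <- data.frame(
      vessel_id = ids[i], annulus_area_mm2 = zone$area_mm2,
      astro_count = cnt$count, density_per_mm2 = cnt$density_per_mm2,
      grade = grade_vessel(cnt$density_per_mm2, cnt$count, scar),
      close_range = close_range_flag(astro_cells, zone, close_range_um,
                                     pixel_size_um),
      scar = scar)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(vessel_id = integer(0), annulus_area_mm2 = numeric(0),
               astro_count = integer(0), density_per_mm2 = numeric(0),
               grade = integer(0), close_range = logical(0),
               scar = logical(0))
  class(res) <- c("vessel_assessment", "data.frame")
  res
}

#' Summarise vessel assessments for one region
#'
#' Percentages of vessels with any inflammation (grade >= 1) and with each
#' grade, plus the close-range percentage; grade percentages over grades 0-3
#' sum to 100.
#'
#' @param assessments `vessel_assessment` data.frame (>= 1 row).
#' @param subject_id,roi_name identifiers.
#' @return one-row data.frame of class `region_vascular_summary`.
#' @export
summarize_region <- function(assessments, subject_id = NA_character_,
                             roi_name = NA_character_) {
  if (nrow(assessments) == 0) stop("empty assessment list")
  g <- assessments$grade
  out <- data.frame(
    subject_id = subject_id, roi_name = roi_name,
    n_vessels = length(g),
    pct_with_inflammation = 100 * mean(g >= 1),
    pct_mild = 100 * mean(g == 1),
    pct_moderate = 100 * mean(g == 2),
    pct_severe = 100 * mean(g == 3),
    pct_close_range = 100 * mean(assessments$close_range),
    stringsAsFactors = FALSE)
  class(out) <- c("region_vascular_summary", "data.frame")
  out
}
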