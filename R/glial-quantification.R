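# Segmentation and morphometrics of DAB-positive glia within ROIs.
#
# Thresholding follows a cohort-level rule: per subject, candidate positive
# pixels are found by Otsu's method on the in-ROI DAB optical density; the
# working threshold is the cohort mean of the per-subject candidate mean
# ODs, scaled by a factor kappa (default 0.5, placing the cut near the
# positive/background boundary rather than at the positive-class centre).
# Per-subject candidate means are retained so threshold settings can be
# checked on an individual basis.

#' Derive the cohort-wide intensity threshold for one stain
#'
#' @param dab_maps_by_subject named list (subject id -> DAB OD matrix).
#' @param roi_sets named list (subject id -> [roi_set()] on the same grid).
#' @param stain_kind stain the threshold is for (`IBA1_DAB` or `GFAP_DAB`).
#' @param kappa scaling factor applied to the cohort mean candidate OD.
#' @return object of class `cohort_threshold`: `threshold_od`,
#'   `per_subject_means`, `stain_kind`, `kappa`, `derivation`.
#' @export
derive_cohort_threshold <- function(dab_maps_by_subject, roi_sets, stain_kind,
                                    kappa = 0.5) {
  stopifnot(length(dab_maps_by_subject) >= 1)
  ids <- names(dab_maps_by_subject)
  means <- rep(NA_real_, length(ids)); names(means) <- ids
  for (id in ids) {
    dab <- dab_maps_by_subject[[id]]
    rs <- roi_sets[[id]]
    roi <- Reduce(`|`, rs$masks)
    if (!any(roi)) next
    v <- dab[roi]
    cut <- otsu_threshold(v)
    cand <- v[v >= cut]
    if (length(cand)) means[id] <- mean(cand)
  }
  if (all(!is.finite(means)))
    stop("no positive candidates in any subject")
  thr <- kappa * mean(means, na.rm = TRUE)
  if (thr <= 0) stop("derived threshold is not positive")
  structure(list(threshold_od = thr, stain_kind = stain_kind, kappa = kappa,
                 per_subject_means = means, derivation = "cohort_mean"),
            class = "cohort_threshold")
}

#' @export
print.cohort_threshold <- function(x, ...) {
  cat(sprintf("<cohort_threshold> %s: %.4g OD (kappa = %g x mean of %d subject candidate means, %s)\n",
              x$stain_kind, x$threshold_od, x$kappa,
              sum(is.finite(x$per_subject_means)), x$derivation))
  invisible(x)
}

#' Segment DAB-positive objects within an ROI
#'
#' Positive mask = (DAB OD >= threshold) within the ROI; 8-connected
#' components; holes in somata filled; components below the minimum object
#' area removed (objects exactly at the minimum are kept). Objects straddling
#' the ROI edge are clipped to the ROI.
#'
#' @param dab_map DAB OD matrix.
#' @param roi_mask logical matrix, congruent with `dab_map`.
#' @param threshold OD cutoff (a number or a `cohort_threshold`).
#' @param min_object_area_um2 size filter (default 20, below soma scale).
#' @param pixel_size_um physical pixel size.
#' @return list: `labels` (integer matrix), `mask` (logical), `n_objects`.
#' @export
segment_positive <- function(dab_map, roi_mask, threshold,
                             min_object_area_um2 = 20, pixel_size_um = 1) {
  if (!all(dim(dab_map) == dim(roi_mask))) stop("shape mismatch")
  if (inherits(threshold, "cohort_threshold")) threshold <- threshold$threshold_od
  mask <- dab_map >= threshold & roi_mask
  mask <- as.matrix(EBImage::fillHull(matrix(as.numeric(mask),
                                             nrow(mask), ncol(mask)))) != 0
  mask <- mask & roi_mask
  labels <- label_components(mask, connectivity = 8)
  min_px <- max(1, ceiling(min_object_area_um2 / pixel_size_um^2))
  if (max(labels) > 0) {
    sizes <- tabulate(labels[labels > 0], nbins = max(labels))
    drop <- which(sizes < min_px)
    if (length(drop)) {
      labels[labels %in% drop] <- 0L
      keep <- sort(unique(labels[labels > 0]))
      labels[labels > 0] <- match(labels[labels > 0], keep)
    }
  }
  list(labels = labels, mask = labels > 0, n_objects = max(labels))
}

#' Measure one segmented cell
#'
#' Area from the pixel count, perimeter as the closed-polygon length through
#' boundary-pixel centres, circularity `4 * pi * area / perimeter^2` clamped
#' to \[0, 1\], skeleton length from Zhang-Suen thinning with orthogonal
#' steps counted 1 and diagonal steps sqrt(2), and mean OD over the object.
#'
#' @param object_mask logical matrix containing one connected component.
#' @param dab_map congruent OD matrix.
#' @param pixel_size_um physical pixel size.
#' @return one-row data.frame (`area_um2`, `perimeter_um`, `circularity`,
#'   `skeleton_length_um`, `mean_od`, centroid `x`/`y`).
#' @export
measure_cell <- function(object_mask, dab_map, pixel_size_um = 1) {
  npx <- sum(object_mask)
  if (npx == 0) stop("empty object")
  idx <- which(object_mask, arr.ind = TRUE)
  area <- npx * pixel_size_um^2
  if (npx == 1) {
    per <- 0; circ <- 1; skel <- 0
  } else {
    oc <- EBImage::ocontour(matrix(as.numeric(object_mask),
                                   nrow(object_mask), ncol(object_mask)))[[1]]
    # light circular smoothing of the boundary chain removes the stair-step
    # bias of the 8-connected contour (which overestimates a disk's
    # perimeter by ~8%)
    oc <- smooth_contour(oc, k = 5)
    per <- polygon_perimeter(oc) * pixel_size_um
    circ <- if (per > 0) min(1, 4 * pi * area / per^2) else 1
    skel <- skeleton_length_px(skeletonize(object_mask)) * pixel_size_um
  }
  data.frame(area_um2 = area, perimeter_um = per, circularity = circ,
             skeleton_length_um = skel,
             mean_od = mean(dab_map[object_mask]),
             x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

#' Measure all labelled cells
#'
#' Runs [measure_cell()] on each label over its bounding box.
#'
#' @param labels integer label matrix from [segment_positive()].
#' @param dab_map congruent OD matrix.
#' @param pixel_size_um physical pixel size.
#' @param roi_name attached to each row.
#' @return data.frame with one row per object (columns of [measure_cell()]
#'   plus `label` and `roi_name`).
#' @export
measure_cells <- function(labels, dab_map, pixel_size_um = 1,
                          roi_name = NA_character_) {
  n <- max(labels)
  if (n == 0)
    return(cbind(data.frame(label = integer(0)),
                 measure_cell(matrix(TRUE, 1, 1), matrix(0, 1, 1))[0, ],
                 data.frame(roi_name = character(0))))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  out <- vector("list", n)
  for (k in seq_len(n)) {
    sel <- lab == k
    rr <- range(idx[sel, 1]); cc <- range(idx[sel, 2])
    sub <- labels[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == k
    dsub <- dab_map[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    m <- measure_cell(sub, dsub, pixel_size_um)
    m$x <- m$x + cc[1] - 1
    m$y <- m$y + rr[1] - 1
    m$label <- k
    out[[k]] <- m
  }
  res <- do.call(rbind, out)
  res$roi_name <- roi_name
  res[, c("label", "x", "y", "area_um2", "perimeter_um", "circularity",
          "skeleton_length_um", "mean_od", "roi_name")]
}

#' Per-region outcome metrics
#'
#' Frequency (objects per mm^2 of ROI), positive-area percentage, intensity
#' percentage (mean positive-pixel OD / `od_max` x 100), and unweighted means
#' of skeleton length and circularity over cells. For GFAP, frequency,
#' length and circularity are reported as `NA`: astroglia counts are not
#' meaningful where scarring merges cells into contiguous sheets.
#'
#' @param cells data.frame from [measure_cells()].
#' @param binary_mask positive-pixel mask after size filtering.
#' @param dab_map congruent OD matrix.
#' @param roi_mask logical ROI matrix (must be non-empty).
#' @param stain_kind `"IBA1_DAB"` or `"GFAP_DAB"`.
#' @param pixel_size_um physical pixel size.
#' @param od_max OD corresponding to 100% intensity (default 2.0).
#' @param subject_id,roi_name identifiers attached to the row.
#' @return one-row data.frame of class `region_metrics`.
#' @export
region_metrics <- function(cells, binary_mask, dab_map, roi_mask, stain_kind,
                           pixel_size_um = 1, od_max = 2,
                           subject_id = NA_character_,
                           roi_name = NA_character_) {
  roi_px <- sum(roi_mask)
  if (roi_px == 0) stop("empty ROI")
  pos <- binary_mask & roi_mask
  area_pct <- 100 * sum(pos) / roi_px
  intensity_pct <- if (any(pos)) 100 * mean(dab_map[pos]) / od_max else 0
  gfap <- stain_kind == "GFAP_DAB"
  out <- data.frame(
    subject_id = subject_id, roi_name = roi_name, stain_kind = stain_kind,
    frequency_per_mm2 = if (gfap) NA_real_ else
      nrow(cells) / mask_area_mm2(roi_mask, pixel_size_um),
    area_pct = area_pct,
    intensity_pct = min(100, intensity_pct),
    avg_length_um = if (gfap || nrow(cells) == 0) NA_real_ else
      mean(cells$skeleton_length_um),
    avg_circularity = if (gfap || nrow(cells) == 0) NA_real_ else
      mean(cells$circularity),
    n_objects = nrow(cells),
    stringsAsFactors = FALSE)
  class(out) <- c("region_metrics", "data.frame")
  out
}
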