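# Image, mask, landmark and cohort-table I/O.
#
# All images are 8-bit on disk (TIFF preferred, PNG accepted). In memory a
# stain image keeps integer channel values in [0, 255]; masks are logical
# matrices. Physical scale is carried as micrometres per pixel edge.

STAIN_KINDS <- c("HE", "IBA1_DAB", "GFAP_DAB")
ROI_NAMES <- c("NAWM", "WMH")

#' Construct a stain image
#'
#' @param pixels numeric array `h x w x 3` (RGB) or matrix (single channel),
#'   values in \[0, 255\].
#' @param pixel_size_um micrometres per pixel edge (> 0).
#' @param stain_kind one of `"HE"`, `"IBA1_DAB"`, `"GFAP_DAB"`.
#' @param subject_id subject identifier string.
#' @return an object of class `stain_image`.
#' @export
stain_image <- function(pixels, pixel_size_um, stain_kind, subject_id = NA_character_) {
  stain_kind <- match.arg(stain_kind, STAIN_KINDS)
  if (!is.numeric(pixels) || length(dim(pixels)) %in% c(2, 3) == FALSE)
    stop("pixels must be a numeric matrix or h x w x 3 array")
  if (length(dim(pixels)) == 3 && dim(pixels)[3] != 3)
    stop("3-d pixel arrays must have 3 channels")
  if (any(dim(pixels)[1:2] == 0)) stop("raster is empty")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive number")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255)
    stop("channel values must lie in [0, 255]")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         stain_kind = stain_kind, subject_id = subject_id),
    class = "stain_image"
  )
}

#' @export
print.stain_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stain_image> %s, %d x %d px (%s), %.3g um/px, subject %s\n",
              x$stain_kind, d[1], d[2],
              if (length(d) == 3) "RGB" else "1-channel",
              x$pixel_size_um, x$subject_id))
  invisible(x)
}

#' @export
dim.stain_image <- function(x) dim(x$pixels)

# Read a raster file as a numeric array scaled to [0, 255] integers.
# 16-bit TIFF input is rescaled by its maximum with a warning.
read_raster_8bit <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    info <- tiff::readTIFF(path, payload = FALSE)
    bits <- max(unlist(info[["bits.per.sample"]]), 8)
    px <- tiff::readTIFF(path)        # scaled to [0, 1]
    if (bits > 8) {
      warning("non-8-bit image ", basename(path),
              ": rescaled to 8-bit by max normalisation")
      if (max(px) > 0) px <- px / max(px)
    }
    px <- round(px * 255)
  } else if (ext == "png") {
    px <- round(png::readPNG(path) * 255)
  } else {
    stop("unreadable format (expect TIFF or PNG): ", path)
  }
  if (length(dim(px)) == 3) {
    if (dim(px)[3] >= 3) px <- px[, , 1:3, drop = FALSE] else px <- px[, , 1]
  }
  px
}

#' Read a stain image from disk
#'
#' Accepts 8-bit TIFF or PNG; deeper TIFFs are linearly rescaled to 8-bit by
#' max normalisation, with a warning. Optionally block-averages the raster to
#' a coarser working resolution.
#'
#' @param path TIFF or PNG file.
#' @inheritParams stain_image
#' @param working_pixel_size_um if given and larger than `pixel_size_um`, the
#'   image is downsampled by the nearest integer block factor.
#' @return a [stain_image()].
#' @export
read_stain_image <- function(path, pixel_size_um, stain_kind,
                             subject_id = NA_character_,
                             working_pixel_size_um = NULL) {
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive number")
  px <- read_raster_8bit(path)
  if (!is.null(working_pixel_size_um) &&
      working_pixel_size_um > pixel_size_um) {
    f <- max(1L, as.integer(round(working_pixel_size_um / pixel_size_um)))
    if (f > 1L) {
      if (length(dim(px)) == 3) {
        px <- simplify2array(lapply(1:3, function(k) block_average(px[, , k], f)))
      } else {
        px <- block_average(px, f)
      }
      px <- round(px)
      pixel_size_um <- pixel_size_um * f
    }
  }
  stain_image(px, pixel_size_um, stain_kind, subject_id)
}

#' Write a stain image (or plain raster) to disk
#'
#' @param image a [stain_image()] or numeric matrix/array in \[0, 255\].
#' @param path output TIFF or PNG path.
#' @export
write_stain_image <- function(image, path) {
  px <- if (inherits(image, "stain_image")) image$pixels else image
  px01 <- px / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px01, path, bits.per.sample = 8L, compression = "none")
  } else if (ext == "png") {
    png::writePNG(px01, path)
  } else stop("unsupported output format: ", path)
  invisible(path)
}

#' Construct an ROI set
#'
#' @param masks named list of logical matrices (names among `NAWM`, `WMH`).
#' @param grid `"MRI"` or `"HISTOLOGY"`: the coordinate grid the masks live on.
#' @param pixel_size_um micrometres per pixel on that grid.
#' @return object of class `roi_set`.
#' @export
roi_set <- function(masks, grid = c("HISTOLOGY", "MRI"), pixel_size_um) {
  grid <- match.arg(grid)
  if (length(masks) == 0) stop("empty mask set")
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("masks must be named")
  dims <- lapply(masks, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1)
    stop("mask shape mismatch")
  masks <- lapply(masks, function(m) m != 0)
  if (all(c("NAWM", "WMH") %in% names(masks)) &&
      any(masks$NAWM & masks$WMH))
    stop("ROIs overlap: NAWM and WMH masks share foreground pixels")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  empty <- vapply(masks, function(m) !any(m), logical(1))
  structure(list(masks = masks, grid = grid, pixel_size_um = pixel_size_um,
                 empty = empty),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("<roi_set> on %s grid, %d x %d px, %.3g um/px\n",
              x$grid, d[1], d[2], x$pixel_size_um))
  for (nm in names(x$masks)) {
    cat(sprintf("  %s: %d px (%.4g mm^2)%s\n", nm, sum(x$masks[[nm]]),
                mask_area_mm2(x$masks[[nm]], x$pixel_size_um),
                if (x$empty[[nm]]) " [absent]" else ""))
  }
  invisible(x)
}

#' Read named ROI masks from disk
#'
#' Single-channel mask files are binarised at > 0. NAWM/WMH overlap is an
#' error: the two regions are distinct tissue states.
#'
#' @param paths_by_name named character vector of mask files.
#' @inheritParams roi_set
#' @return a [roi_set()].
#' @export
read_roi_masks <- function(paths_by_name, grid = c("HISTOLOGY", "MRI"),
                           pixel_size_um) {
  grid <- match.arg(grid)
  if (length(paths_by_name) == 0) stop("empty mask set")
  masks <- lapply(paths_by_name, function(p) {
    m <- read_raster_8bit(p)
    if (length(dim(m)) == 3) stop("mask file must be single-channel: ", p)
    m > 0
  })
  roi_set(masks, grid, pixel_size_um)
}

#' Write binary masks of an ROI set to disk
#'
#' @param rois a [roi_set()].
#' @param paths_by_name named character vector matching `names(rois$masks)`.
#' @export
write_roi_masks <- function(rois, paths_by_name) {
  for (nm in names(paths_by_name)) {
    write_stain_image(matrix(ifelse(rois$masks[[nm]], 255, 0),
                             nrow(rois$masks[[nm]])),
                      paths_by_name[[nm]])
  }
  invisible(paths_by_name)
}

COHORT_REQUIRED_COLS <- c("subject_id", "group", "age", "sex",
                          "fixation_interval_months", "fazekas")

#' Read and validate a cohort metadata table
#'
#' Delimited text (comma or tab, by extension) with one row per subject.
#' Required columns: `subject_id`, `group` (hypertension/control), `age`,
#' `sex` (F/M), `fixation_interval_months`, `fazekas` (0-3). Any further
#' columns are kept as optional covariates.
#'
#' @param path CSV/TSV file.
#' @return `data.frame` of class `cohort_table`.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) stop("could not parse cohort table: ", conditionMessage(e)))
  if (nrow(df) == 0) stop("cohort table is empty")
  validate_cohort_table(df)
}

#' Validate an in-memory cohort table
#' @param df data.frame with the columns of [read_cohort_table()].
#' @export
validate_cohort_table <- function(df) {
  missing_cols <- setdiff(COHORT_REQUIRED_COLS, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id")
  if (!all(df$group %in% c("hypertension", "control")))
    stop("group must be 'hypertension' or 'control'")
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (any(!is.finite(df$age)) || any(df$age <= 0)) stop("age must be > 0")
  bad <- !(df$fazekas %in% 0:3)
  if (any(bad))
    stop("fazekas outside 0-3 for subject(s): ",
         paste(df$subject_id[bad], collapse = ", "))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a landmark table
#'
#' CSV with columns `name`, `x_moving`, `y_moving`, `x_fixed`, `y_fixed`
#' (0-based pixel coordinates).
#' @param path CSV file.
#' @return data.frame of landmark pairs.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_moving", "y_moving", "x_fixed", "y_fixed")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("landmark file missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}
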