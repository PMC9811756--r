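# Synthetic cell / vessel specifications and slide rendering.
#
# Cells and vessels are kept as data frames (one row per object) with
# positions in pixels (0-based) and sizes in micrometres. Rendering follows
# the Beer-Lambert forward model that stain separation inverts: per-object
# stain amounts accumulate into concentration maps, and
# RGB = I0 * 10^(-M %*% c) channel-wise.

CELL_PHENOTYPES <- c("ramified", "amoeboid", "astro_star")

#' Construct cell specifications
#'
#' @param x,y centre coordinates in pixels (0-based).
#' @param phenotype `"ramified"` or `"amoeboid"` microglia (IBA1 slides) or
#'   `"astro_star"` astroglia (GFAP slides).
#' @param soma_radius_um soma radius (> 0).
#' @param n_branches number of process arms (>= 2 for ramified, 0 for
#'   amoeboid).
#' @param branch_length_um arm length beyond the soma.
#' @param stain_amount DAB optical-density amplitude of the cell.
#' @param angle0 orientation of the first arm (radians).
#' @return data.frame with one row per cell.
#' @export
cell_spec <- function(x, y, phenotype, soma_radius_um = 3.5,
                      n_branches = 0L, branch_length_um = 0,
                      stain_amount = 0.6, angle0 = 0) {
  if (length(x) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      phenotype = character(0), soma_radius_um = numeric(0),
                      n_branches = integer(0), branch_length_um = numeric(0),
                      stain_amount = numeric(0), angle0 = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(x = x, y = y, phenotype = phenotype,
                   soma_radius_um = soma_radius_um,
                   n_branches = as.integer(n_branches),
                   branch_length_um = branch_length_um,
                   stain_amount = stain_amount, angle0 = angle0,
                   stringsAsFactors = FALSE)
  if (!all(df$phenotype %in% CELL_PHENOTYPES))
    stop("unknown phenotype")
  if (any(df$soma_radius_um <= 0)) stop("soma_radius_um must be > 0")
  if (any(df$stain_amount < 0)) stop("negative stain amounts")
  if (any(df$phenotype == "ramified" & df$n_branches < 2))
    stop("ramified cells need n_branches >= 2")
  if (any(df$phenotype == "amoeboid" & df$n_branches != 0))
    stop("amoeboid cells have n_branches = 0")
  df
}

#' Construct vessel specifications
#'
#' @param x,y lumen centre in pixels (0-based).
#' @param a_um,b_um lumen semi-axes in micrometres (> 0).
#' @param orientation_rad ellipse orientation.
#' @param wall_thickness_um vessel wall thickness.
#' @param perivascular_density_per_mm2 target astroglia density in the
#'   15 um annulus (>= 0).
#' @param scar whether an astrogliotic scar band surrounds the vessel.
#' @return data.frame with one row per vessel.
#' @export
vessel_spec <- function(x, y, a_um, b_um, orientation_rad = 0,
                        wall_thickness_um = 3,
                        perivascular_density_per_mm2 = 0, scar = FALSE) {
  df <- data.frame(x = x, y = y, a_um = a_um, b_um = b_um,
                   orientation_rad = orientation_rad,
                   wall_thickness_um = wall_thickness_um,
                   perivascular_density_per_mm2 = perivascular_density_per_mm2,
                   scar = scar)
  if (any(df$a_um <= 0 | df$b_um <= 0)) stop("lumen semi-axes must be > 0")
  if (any(df$perivascular_density_per_mm2 < 0))
    stop("perivascular density must be >= 0")
  df
}

# Which stain slide a phenotype is visible on.
phenotype_stain <- function(phenotype) {
  ifelse(phenotype == "astro_star", "GFAP_DAB", "IBA1_DAB")
}

# Ring with optional partial angular coverage (arc_frac of 360 degrees,
# starting at arc_start radians), between concentric ellipses (semi-axes
# inner a/b and outer a/b, common orientation theta).
add_ring <- function(canvas, cx, cy, a_in, b_in, a_out, b_out, theta, amount,
                     arc_frac = 1, arc_start = 0) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  r <- max(a_out, b_out)
  x0 <- max(0, floor(cx - r)); x1 <- min(nc - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(nr - 1, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)) - cx
  py <- rep(ys, times = length(xs)) - cy
  u <- px * cos(theta) + py * sin(theta)
  v <- -px * sin(theta) + py * cos(theta)
  inside <- ((u / a_out)^2 + (v / b_out)^2 <= 1) &
    ((u / a_in)^2 + (v / b_in)^2 > 1)
  if (arc_frac < 1) {
    ang <- (atan2(v, u) - arc_start) %% (2 * pi)
    inside <- inside & ang <= arc_frac * 2 * pi
  }
  sub <- canvas[ys + 1, xs + 1, drop = FALSE]
  idx <- matrix(inside, length(ys), length(xs))
  sub[idx] <- sub[idx] + amount
  canvas[ys + 1, xs + 1] <- sub
  canvas
}

# Draw one cell's DAB concentration footprint.
draw_cell_conc <- function(conc, cell, pixel_size_um, arm_width_px = 1.5) {
  r_px <- cell$soma_radius_um / pixel_size_um
  conc <- add_disk(conc, cell$x, cell$y, r_px, cell$stain_amount)
  nb <- cell$n_branches
  if (nb > 0 && cell$branch_length_um > 0) {
    len_px <- (cell$soma_radius_um + cell$branch_length_um) / pixel_size_um
    angs <- cell$angle0 + 2 * pi * (seq_len(nb) - 1) / nb
    for (a in angs) {
      conc <- add_segment(conc, cell$x, cell$y,
                          cell$x + len_px * cos(a), cell$y + len_px * sin(a),
                          arm_width_px, cell$stain_amount)
    }
  }
  conc
}

#' Render a synthetic brightfield slide
#'
#' Builds per-stain concentration maps (hematoxylin background texture,
#' vessel lumens/walls, cell bodies and arms, scar bands) and converts them
#' to 8-bit RGB with the Beer-Lambert forward model
#' `RGB = I0 * 10^(-M %*% c)`, the exact inverse of [deconvolve()].
#'
#' @param cells cell data.frame ([cell_spec()]); may be NULL.
#' @param vessels vessel data.frame ([vessel_spec()]); may be NULL.
#' @param dim_px `c(rows, cols)` raster size.
#' @param stain_kind which slide to render (`HE`, `IBA1_DAB`, `GFAP_DAB`):
#'   microglia appear on IBA1, astroglia and scars on GFAP, somata only
#'   (hematoxylin) on HE.
#' @param pixel_size_um physical pixel size.
#' @param I0 per-channel background intensity.
#' @param background list: `hema` (mean hematoxylin OD), `noise_amp`
#'   (SD of the smooth texture field), `noise_sigma_px` (its correlation
#'   length), `pixel_noise_sd` (iid OD noise), `lumen_hema`, `wall_hema`.
#' @param scar_amount,scar_coverage GFAP OD and angular coverage of rendered
#'   scar bands.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param subject_id carried into the returned image.
#' @param quantize_8bit round pixel values to 8-bit integers (as a scanner
#'   would); `FALSE` keeps the continuous Beer-Lambert intensities, making
#'   the render -> deconvolve loop exact to numerical precision.
#' @return a [stain_image()] (RGB); the attribute `"conc"` holds the true
#'   concentration maps used.
#' @export
render_slide <- function(cells = NULL, vessels = NULL, dim_px,
                         stain_kind = "IBA1_DAB", pixel_size_um = 1,
                         I0 = c(255, 255, 255),
                         background = list(), scar_amount = 0.8,
                         scar_coverage = 0.9, seed = NULL,
                         subject_id = NA_character_, quantize_8bit = TRUE) {
  bg <- utils::modifyList(list(hema = 0.18, noise_amp = 0.03,
                               noise_sigma_px = 8, pixel_noise_sd = 0.01,
                               lumen_hema = 0.02, wall_hema = 0.12),
                          background)
  if (!is.null(seed)) set.seed(seed)
  nr <- dim_px[1]; nc <- dim_px[2]
  if (!is.null(cells) && nrow(cells)) {
    reach <- (cells$soma_radius_um + cells$branch_length_um) / pixel_size_um
    if (any(cells$x - reach < -1 | cells$x + reach > nc |
            cells$y - reach < -1 | cells$y + reach > nr))
      stop("object outside raster")
    if (any(cells$stain_amount < 0)) stop("negative stain amounts")
  }
  conc_h <- matrix(bg$hema, nr, nc)
  if (bg$noise_amp > 0)
    conc_h <- conc_h + bg$noise_amp * smooth_noise_field(nr, nc, bg$noise_sigma_px)
  conc_d <- matrix(0, nr, nc)

  if (!is.null(vessels) && nrow(vessels)) {
    for (i in seq_len(nrow(vessels))) {
      v <- vessels[i, ]
      a <- v$a_um / pixel_size_um; b <- v$b_um / pixel_size_um
      w <- v$wall_thickness_um / pixel_size_um
      conc_h <- add_ring(conc_h, v$x, v$y, a, b, a + w, b + w,
                         v$orientation_rad, bg$wall_hema)
      conc_h <- add_ellipse(conc_h, v$x, v$y, a, b, v$orientation_rad,
                            bg$lumen_hema, assign = TRUE)
      if (isTRUE(v$scar) && stain_kind == "GFAP_DAB") {
        band <- 15 / pixel_size_um
        conc_d <- add_ring(conc_d, v$x, v$y, a, b, a + band, b + band,
                           v$orientation_rad, scar_amount,
                           arc_frac = scar_coverage,
                           arc_start = stats::runif(1, 0, 2 * pi))
      }
    }
  }

  if (!is.null(cells) && nrow(cells)) {
    for (i in seq_len(nrow(cells))) {
      cl <- cells[i, ]
      if (stain_kind == "HE") {
        conc_h <- add_disk(conc_h, cl$x, cl$y,
                           cl$soma_radius_um / pixel_size_um, 0.25)
      } else if (phenotype_stain(cl$phenotype) == stain_kind) {
        conc_d <- draw_cell_conc(conc_d, cl, pixel_size_um)
      }
    }
  }

  if (bg$pixel_noise_sd > 0) {
    conc_h <- conc_h + matrix(stats::rnorm(nr * nc, 0, bg$pixel_noise_sd), nr, nc)
    conc_d <- conc_d + matrix(stats::rnorm(nr * nc, 0, bg$pixel_noise_sd), nr, nc)
  }
  conc_h[conc_h < 0] <- 0
  conc_d[conc_d < 0] <- 0

  M <- default_hdab_vectors()$matrix
  I0 <- rep_len(I0, 3)
  px <- array(0, c(nr, nc, 3))
  for (k in 1:3) {
    od_k <- M[k, 1] * conc_h + M[k, 2] * conc_d
    v <- I0[k] * 10^(-od_k)
    if (quantize_8bit) v <- round(v)
    px[, , k] <- pmin(255, pmax(0, v))
  }
  img <- stain_image(px, pixel_size_um, stain_kind, subject_id)
  attr(img, "conc") <- list(hematoxylin = conc_h, dab = conc_d)
  img
}

# Rejection-sample n points inside mask (logical matrix) with a minimum
# centre spacing; returns data.frame(x, y) (0-based) or errors out.
place_points <- function(n, mask, min_spacing_px, max_tries_per_point = 400) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  idx <- which(mask)
  if (length(idx) == 0) stop("empty placement region")
  nr <- nrow(mask)
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  while (length(xs) < n) {
    tries <- tries + 1
    if (tries > max_tries_per_point * n)
      stop("placement region too small to hold ", n,
           " points at spacing ", min_spacing_px,
           "; reduce the requested density")
    i <- idx[sample.int(length(idx), 1)]
    x <- ((i - 1) %/% nr) + stats::runif(1, -0.5, 0.5)
    y <- ((i - 1) %% nr) + stats::runif(1, -0.5, 0.5)
    if (length(xs) == 0 || min((xs - x)^2 + (ys - y)^2) >= min_spacing_px^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x = xs, y = ys)
}

#' Populate a vessel's perivascular annulus at a target astroglia density
#'
#' Places `round(target_density * annulus_area_mm2)` star-shaped astroglia
#' uniformly in the 0-15 um annulus around the lumen, with a minimum centre
#' spacing of twice the soma radius, so the realised density is within one
#' count of the target.
#'
#' @param vessel one-row data.frame from [vessel_spec()].
#' @param target_density_per_mm2 target density (>= 0).
#' @param dim_px slide raster size `c(rows, cols)` (annulus is clipped to it).
#' @param pixel_size_um physical pixel size.
#' @param soma_radius_um astroglia soma radius.
#' @param zone_um annulus outer distance (15 um grading zone).
#' @param stain_amount GFAP OD per cell.
#' @param placement_band_um distance band (from the lumen boundary) in which
#'   soma centres are placed. The default keeps centres 2 um clear of both
#'   zone boundaries so a soma sits unambiguously inside the zone; the cell
#'   count itself is always `round(density x full annulus area)`.
#' @param seed RNG seed; `NULL` uses current RNG state.
#' @return cell data.frame with attributes `annulus_area_mm2` and
#'   `boundary_distance_um` (per placed cell).
#' @export
make_vessel_with_density <- function(vessel, target_density_per_mm2, dim_px,
                                     pixel_size_um = 1, soma_radius_um = 4,
                                     zone_um = 15, stain_amount = 0.6,
                                     placement_band_um = c(2, 13),
                                     seed = NULL) {
  stopifnot(target_density_per_mm2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  a <- vessel$a_um / pixel_size_um; b <- vessel$b_um / pixel_size_um
  zone_px <- zone_um / pixel_size_um
  r_max <- max(a, b) + zone_px + 3
  x0 <- max(0, floor(vessel$x - r_max)); x1 <- min(dim_px[2] - 1, ceiling(vessel$x + r_max))
  y0 <- max(0, floor(vessel$y - r_max)); y1 <- min(dim_px[1] - 1, ceiling(vessel$y + r_max))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)) - vessel$x
  py <- rep(ys, times = length(xs)) - vessel$y
  th <- vessel$orientation_rad
  u <- px * cos(th) + py * sin(th)
  v <- -px * sin(th) + py * cos(th)
  lumen <- matrix((u / a)^2 + (v / b)^2 <= 1, length(ys), length(xs))
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(!lumen),
                                         nrow(lumen), ncol(lumen))))
  annulus <- d > 0 & d * pixel_size_um <= zone_um
  area_mm2 <- mask_area_mm2(annulus, pixel_size_um)
  n <- round(target_density_per_mm2 * area_mm2)
  if (n == 0) {
    out <- cell_spec(numeric(0), numeric(0), character(0))
    attr(out, "annulus_area_mm2") <- area_mm2
    attr(out, "boundary_distance_um") <- numeric(0)
    return(out)
  }
  band <- d * pixel_size_um >= placement_band_um[1] &
    d * pixel_size_um <= placement_band_um[2]
  if (!any(band)) band <- annulus
  pts <- tryCatch(
    place_points(n, band, 2 * soma_radius_um / pixel_size_um),
    error = function(e) stop("annulus too small for the requested density (",
                             target_density_per_mm2, "/mm^2): ",
                             conditionMessage(e)))
  dist_um <- d[cbind(round(pts$y) + 1, round(pts$x) + 1)] * pixel_size_um
  out <- cell_spec(pts$x + x0, pts$y + y0, rep("astro_star", n),
                   soma_radius_um = soma_radius_um,
                   n_branches = rep(6L, n),
                   branch_length_um = soma_radius_um * 1.5,
                   stain_amount = stain_amount,
                   angle0 = stats::runif(n, 0, 2 * pi))
  attr(out, "annulus_area_mm2") <- area_mm2
  attr(out, "boundary_distance_um") <- dist_um
  out
}
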