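# Synthetic cohort generation: paired "MRI" and histology rasters, ROI
# masks, cells, vessels, covariates and ground truth for every downstream
# stage. The generator's defaults define the study conditions used by the
# validation suite; effect directions follow the qualitative pattern of the
# motivating cohort (hypertension > control and WMH > NAWM for activation
# outcomes), with magnitudes chosen as free parameters of the simulation.

#' Cohort specification
#'
#' All parameters of the synthetic cohort: design (17 hypertension vs 5
#' control by default, mirroring the motivating study design), per-outcome
#' baselines, additive group and ROI effects, between-sample noise SDs,
#' rendering texture, and the parameters of the degraded MRI counterpart.
#' Group/ROI deltas are multiplied by `effect_scale` (0 gives a null cohort).
#'
#' @param n_hypertension,n_control subjects per group (>= 1).
#' @param seed RNG seed for the whole cohort.
#' @param effect_scale multiplier on all group/ROI deltas.
#' @param ... overrides for any default listed in the function body.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hypertension = 17, n_control = 5, seed = 1,
                        effect_scale = 1, ...) {
  spec <- list(
    n_hypertension = n_hypertension, n_control = n_control, seed = seed,
    effect_scale = effect_scale,
    pixel_size_um = 1,
    slide_dim = c(450, 900),
    roi_size_px = 350, roi_margin_px = 50,
    # microglia (IBA1)
    microglia_density_mm2 = 270, microglia_density_group = 20,
    microglia_density_roi = 80, microglia_density_sd = 40,
    amoeboid_frac = 0.35, amoeboid_frac_group = 0.10,
    amoeboid_frac_roi = 0.10, amoeboid_frac_sd = 0.04,
    iba1_od = 0.60, iba1_od_group = 0.10, iba1_od_roi = 0.08,
    iba1_od_sd = 0.04,
    branch_length_um = 12, branch_length_group = -1.5,
    branch_length_roi = -2.5, branch_length_sd = 1,
    n_branches_range = c(3L, 6L),
    soma_radius_ramified_um = 3.5, soma_radius_amoeboid_um = 5,
    soma_radius_astro_um = 4,
    microglia_spacing_um = 26,
    # astroglia (GFAP)
    astro_density_mm2 = 700, astro_density_group = 150,
    astro_density_roi = 250, astro_density_sd = 80,
    gfap_od = 0.55, gfap_od_group = 0.10, gfap_od_roi = 0.08,
    gfap_od_sd = 0.04,
    astro_spacing_um = 11, astro_arm_length_um = 16,
    # vessels and perivascular astrogliosis (lumen radii span capillary to
    # small-arteriole scale so annulus areas, and hence grade quantisation,
    # vary realistically)
    vessels_per_roi = 5L, lumen_radius_um = c(12, 40),
    wall_thickness_um = 3, vessel_spacing_um = 90,
    peri_density_mm2 = 180, peri_density_group = 120, peri_density_roi = 150,
    peri_density_sd = 120, peri_zero_prob = 0.05,
    scar_prob = 0.04, scar_prob_group = 0.06, scar_prob_roi = 0.08,
    # optional WMH-burden-linked effects (act on fazekas >= 2)
    burden_iba1_od = 0, burden_microglia_density = 0,
    # covariates
    age_mean = 80, age_sd = 8, sex_p_female = 0.45,
    fixation_mean = 50, fixation_sd = 12,
    age_slope_iba1_od = 0.001,
    fazekas_probs_control = c(0.2, 0.8, 0, 0),
    fazekas_probs_htn = c(0.12, 0.29, 0.53, 0.06),
    # rendering
    hema_background = 0.18, hema_noise_amp = 0.03, hema_noise_sigma_px = 8,
    pixel_noise_sd = 0.01,
    # MRI counterpart
    mri_downsample = 4, mri_rot_deg = 6, mri_blur_um = 6,
    mri_warp_amp_px = 1.5, n_landmarks = 12
  )
  spec <- utils::modifyList(spec, list(...))
  if (spec$n_hypertension < 1 || spec$n_control < 1)
    stop("need at least one subject per group")
  sds <- grep("_sd$", names(spec), value = TRUE)
  if (any(unlist(spec[sds]) < 0)) stop("noise SDs must be >= 0")
  class(spec) <- "cohort_spec"
  spec
}

# argument order matters: pmax/pmin keep the first argument's attributes
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw subject-level covariates for the whole cohort (consumes RNG).
draw_subjects <- function(spec) {
  n <- spec$n_hypertension + spec$n_control
  group <- c(rep("hypertension", spec$n_hypertension),
             rep("control", spec$n_control))
  faz <- integer(n)
  for (i in seq_len(n)) {
    p <- if (group[i] == "hypertension") spec$fazekas_probs_htn
         else spec$fazekas_probs_control
    faz[i] <- sample(0:3, 1, prob = p)
  }
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = group,
    age = round(clip(stats::rnorm(n, spec$age_mean, spec$age_sd), 55, 100), 1),
    sex = ifelse(stats::runif(n) < spec$sex_p_female, "F", "M"),
    fixation_interval_months =
      round(clip(stats::rnorm(n, spec$fixation_mean, spec$fixation_sd), 2, 120), 1),
    fazekas = faz,
    stringsAsFactors = FALSE
  )
}

# Latent per-(subject x ROI) outcome parameters; the additive
# outcome-generating model: baseline + group delta + ROI delta (+ burden
# delta, + covariate slope) + iid Gaussian noise.
draw_latents <- function(spec, group, roi, age, fazekas) {
  es <- spec$effect_scale
  g <- as.numeric(group == "hypertension")
  w <- as.numeric(roi == "WMH")
  b <- as.numeric(fazekas >= 2)
  lin <- function(base, dg, dr, sd, extra = 0) {
    base + es * (g * dg + w * dr) + extra + stats::rnorm(1, 0, sd)
  }
  list(
    microglia_density = clip(lin(spec$microglia_density_mm2,
                                 spec$microglia_density_group,
                                 spec$microglia_density_roi,
                                 spec$microglia_density_sd,
                                 b * spec$burden_microglia_density), 20, 2000),
    amoeboid_frac = clip(lin(spec$amoeboid_frac, spec$amoeboid_frac_group,
                             spec$amoeboid_frac_roi, spec$amoeboid_frac_sd),
                         0.02, 0.98),
    iba1_od = clip(lin(spec$iba1_od, spec$iba1_od_group, spec$iba1_od_roi,
                       spec$iba1_od_sd,
                       spec$age_slope_iba1_od * (age - spec$age_mean) +
                         b * spec$burden_iba1_od), 0.1, 1.8),
    branch_length = clip(lin(spec$branch_length_um, spec$branch_length_group,
                             spec$branch_length_roi, spec$branch_length_sd),
                         4, 30),
    astro_density = clip(lin(spec$astro_density_mm2, spec$astro_density_group,
                             spec$astro_density_roi, spec$astro_density_sd),
                         50, 3000),
    gfap_od = clip(lin(spec$gfap_od, spec$gfap_od_group, spec$gfap_od_roi,
                       spec$gfap_od_sd), 0.1, 1.8),
    peri_density = clip(lin(spec$peri_density_mm2, spec$peri_density_group,
                            spec$peri_density_roi, spec$peri_density_sd),
                        0, 1200),
    scar_prob = clip(spec$scar_prob +
                       es * (g * spec$scar_prob_group + w * spec$scar_prob_roi),
                     0, 0.6)
  )
}

#' Simulate the cohort's outcome-generating model without rendering images
#'
#' Draws covariates and the latent per-(subject x ROI) outcome values from
#' the same additive model [generate_cohort()] realises through object
#' placement. Used for statistical calibration at scale.
#'
#' @param spec a [cohort_spec()].
#' @return list with `subjects` (cohort table) and `outcomes` (long
#'   data.frame: subject_id, roi_name, outcome_name, value).
#' @export
simulate_true_metrics <- function(spec) {
  set.seed(spec$seed)
  subjects <- draw_subjects(spec)
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    for (roi in ROI_NAMES) {
      lat <- draw_latents(spec, subjects$group[i], roi,
                          subjects$age[i], subjects$fazekas[i])
      lat$scar_prob <- NULL
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subjects$subject_id[i], roi_name = roi,
        outcome_name = names(lat), value = unlist(lat),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  list(subjects = validate_cohort_table(subjects),
       outcomes = do.call(rbind, rows))
}

#' Build a degraded MRI counterpart of a histology-grid raster
#'
#' Applies a known affine (plus optional smooth low-amplitude sinusoidal
#' warp), Gaussian blur, block downsampling, a nonlinear intensity remap and
#' noise, and returns the true MRI-to-histology transform together with
#' exactly corresponding landmark pairs sampled from the true map.
#'
#' @param histology_image numeric matrix (anatomy/label raster on the
#'   histology grid, values 0-255).
#' @param transform_params list: `rot_deg`, `scale` (extra isotropic scale on
#'   top of the downsampling), `translation_px` (length-2, on the histology
#'   grid), `warp_amp_px`, `warp_period_px`.
#' @param blur_um Gaussian blur SD in micrometres.
#' @param downsample_factor MRI pixel size / histology pixel size (>= 1).
#' @param pixel_size_um histology pixel size.
#' @param n_landmarks number of landmark pairs (>= 10 by operating standard).
#' @param seed RNG seed; `NULL` uses current state.
#' @return list: `image` (MRI raster), `transform` (true `transform2d`,
#'   MRI -> histology; TPS on a dense grid when the warp is nonzero),
#'   `landmarks` (data.frame with moving = MRI, fixed = histology),
#'   `pixel_size_um` (MRI grid).
#' @export
make_mri_counterpart <- function(histology_image, transform_params = list(),
                                 blur_um = 6, downsample_factor = 4,
                                 pixel_size_um = 1, n_landmarks = 12,
                                 seed = NULL) {
  stopifnot(downsample_factor >= 1)
  if (!is.null(seed)) set.seed(seed)
  tp <- utils::modifyList(list(rot_deg = 6, scale = 1,
                               translation_px = c(0, 0),
                               warp_amp_px = 0, warp_period_px = 200),
                          transform_params)
  nr_h <- nrow(histology_image); nc_h <- ncol(histology_image)
  nr_m <- ceiling(nr_h / downsample_factor)
  nc_m <- ceiling(nc_h / downsample_factor)
  s <- downsample_factor * tp$scale
  if (abs(s) < 1e-9) stop("degenerate affine (zero scale)")
  rot <- tp$rot_deg * pi / 180
  c_m <- c((nc_m - 1) / 2, (nr_m - 1) / 2)
  c_h <- c((nc_h - 1) / 2, (nr_h - 1) / 2)
  R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2, byrow = TRUE)
  M <- R * s
  off <- c_h + tp$translation_px - M %*% c_m
  A <- rbind(cbind(M, as.vector(off)), c(0, 0, 1))
  true_map <- function(pts) {
    out <- cbind(pts, 1) %*% t(A)
    out <- out[, 1:2, drop = FALSE]
    if (tp$warp_amp_px > 0) {
      out[, 1] <- out[, 1] + tp$warp_amp_px *
        sin(2 * pi * pts[, 2] / tp$warp_period_px)
      out[, 2] <- out[, 2] + tp$warp_amp_px *
        cos(2 * pi * pts[, 1] / tp$warp_period_px)
    }
    out
  }
  # MRI raster: pull histology intensities through the true map, remap
  # nonlinearly (different modality contrast), blur and add noise
  gx <- rep(0:(nc_m - 1), each = nr_m)
  gy <- rep(0:(nr_m - 1), times = nr_m * 0 + nc_m)
  src <- true_map(cbind(gx, gy))
  vals <- sample_raster(histology_image, src[, 1], src[, 2],
                        method = "bilinear", background = 0)
  img <- matrix(vals, nr_m, nc_m)
  img <- 255 * (img / 255)^0.7
  sigma_px <- blur_um / (pixel_size_um * downsample_factor)
  if (sigma_px > 0.3) img <- as.matrix(EBImage::gblur(img, sigma = sigma_px))
  img <- img + matrix(stats::rnorm(nr_m * nc_m, 0, 2), nr_m, nc_m)
  img <- round(clip(img, 0, 255))

  # exact landmark pairs from the true map, spread over the MRI grid
  k <- max(10, n_landmarks)
  ncols <- ceiling(sqrt(k))
  nrows <- ceiling(k / ncols)
  lx <- seq(0.12, 0.88, length.out = ncols) * (nc_m - 1)
  ly <- seq(0.12, 0.88, length.out = nrows) * (nr_m - 1)
  mov <- as.matrix(expand.grid(x = lx, y = ly))[seq_len(k), , drop = FALSE]
  fix <- true_map(mov)
  landmarks <- data.frame(name = sprintf("L%02d", seq_len(k)),
                          x_moving = mov[, 1], y_moving = mov[, 2],
                          x_fixed = fix[, 1], y_fixed = fix[, 2])
  transform <- if (tp$warp_amp_px > 0) {
    gxc <- seq(-0.05, 1.05, length.out = 12) * (nc_m - 1)
    gyc <- seq(-0.05, 1.05, length.out = 12) * (nr_m - 1)
    ctrl <- as.matrix(expand.grid(x = gxc, y = gyc))
    dst <- true_map(ctrl)
    # tiny ridge keeps the dense regular-grid system well conditioned;
    # the interpolant still passes through the control points to < 1e-3 px
    structure(list(kind = "tps", fwd = tps_fit_one(ctrl, dst, lambda = 1e-6),
                   bwd = tps_fit_one(dst, ctrl, lambda = 1e-6), lambda = 1e-6),
              class = "transform2d")
  } else {
    affine_transform(A)
  }
  list(image = img, transform = transform, landmarks = landmarks,
       pixel_size_um = pixel_size_um * downsample_factor,
       true_map = true_map)
}

# ROI rectangles on the histology grid.
cohort_roi_masks <- function(spec) {
  nr <- spec$slide_dim[1]; nc <- spec$slide_dim[2]
  m <- spec$roi_margin_px; s <- spec$roi_size_px
  nawm <- matrix(FALSE, nr, nc)
  nawm[m + seq_len(s), m + seq_len(s)] <- TRUE
  wmh <- matrix(FALSE, nr, nc)
  wmh[m + seq_len(s), nc - m - s + seq_len(s)] <- TRUE
  roi_set(list(NAWM = nawm, WMH = wmh), grid = "HISTOLOGY",
          pixel_size_um = spec$pixel_size_um)
}

# Realise one subject: place objects per ROI according to the latents.
# Returns list(cells, vessels, truth) where truth holds realised per-ROI
# metrics recomputable from the object lists.
realize_subject <- function(spec, subject, rois) {
  px <- spec$pixel_size_um
  all_cells <- list(); all_vessels <- list()
  truth_rois <- list()
  keep_clear <- NULL  # lumen + annulus exclusion zone for parenchymal astro
  for (roi in ROI_NAMES) {
    mask <- rois$masks[[roi]]
    lat <- draw_latents(spec, subject$group, roi, subject$age, subject$fazekas)
    area_mm2 <- mask_area_mm2(mask, px)
    # vessels first: their annuli are reserved for perivascular astroglia.
    # The border keeps the whole 15 um annulus (plus a soma diameter and a
    # registration-error margin) inside the ROI, so measured and true
    # perivascular zones coincide.
    nv <- spec$vessels_per_roi
    vborder <- round((spec$lumen_radius_um[2] + spec$wall_thickness_um + 15 +
                        2 * spec$soma_radius_astro_um + 5) / px)
    vregion <- erode_rect(mask, vborder)
    vpts <- NULL
    for (relax in c(1, 0.9, 0.8, 0.7)) {
      vpts <- tryCatch(
        place_points(nv, vregion, relax * spec$vessel_spacing_um / px),
        error = function(e) NULL)
      if (!is.null(vpts)) break
    }
    if (is.null(vpts))
      stop("could not place ", nv, " vessels in the ", roi, " ROI")
    vdf <- list(); peri_cells <- list()
    for (j in seq_len(nv)) {
      a <- stats::runif(1, spec$lumen_radius_um[1], spec$lumen_radius_um[2])
      b <- stats::runif(1, spec$lumen_radius_um[1], a)
      dens <- if (stats::runif(1) < spec$peri_zero_prob) 0 else
        clip(stats::rnorm(1, lat$peri_density, spec$peri_density_sd / 2), 0, 2000)
      scar <- stats::runif(1) < lat$scar_prob
      v <- vessel_spec(vpts$x[j], vpts$y[j], a, b,
                       orientation_rad = stats::runif(1, 0, pi),
                       wall_thickness_um = spec$wall_thickness_um,
                       perivascular_density_per_mm2 = dens, scar = scar)
      pc <- make_vessel_with_density(v, dens, spec$slide_dim, px,
                                     soma_radius_um = spec$soma_radius_astro_um,
                                     stain_amount = lat$gfap_od)
      v$roi_name <- roi
      v$true_count <- nrow(pc)
      v$annulus_area_mm2 <- attr(pc, "annulus_area_mm2")
      v$true_density <- v$true_count / v$annulus_area_mm2
      v$true_grade <- grade_vessel(v$true_density, v$true_count, v$scar)
      v$true_close_range <- any(attr(pc, "boundary_distance_um") <= 5)
      vdf[[j]] <- v
      peri_cells[[j]] <- pc
    }
    vdf <- do.call(rbind, vdf)
    peri_cells <- do.call(rbind, peri_cells)

    # microglia
    n_mg <- round(lat$microglia_density * area_mm2)
    mpts <- place_points_relaxed(n_mg, mask, spec$microglia_spacing_um / px)
    n_amo <- round(n_mg * lat$amoeboid_frac)
    phen <- c(rep("amoeboid", n_amo), rep("ramified", n_mg - n_amo))
    nb <- ifelse(phen == "amoeboid", 0L,
                 sample(spec$n_branches_range[1]:spec$n_branches_range[2],
                        n_mg, replace = TRUE))
    mg <- cell_spec(mpts$x, mpts$y, phen,
                    soma_radius_um = ifelse(phen == "amoeboid",
                                            spec$soma_radius_amoeboid_um,
                                            spec$soma_radius_ramified_um),
                    n_branches = nb,
                    branch_length_um = ifelse(phen == "amoeboid", 0,
                                              lat$branch_length),
                    stain_amount = clip(stats::rnorm(n_mg, lat$iba1_od, 0.03),
                                        0.1, 2),
                    angle0 = stats::runif(n_mg, 0, 2 * pi))

    # parenchymal astroglia, kept clear of all perivascular zones
    clear <- vessel_clearance_mask(spec, vdf, mask)
    n_as <- round(lat$astro_density * area_mm2)
    apts <- place_points_relaxed(n_as, clear, spec$astro_spacing_um / px)
    as_cells <- cell_spec(apts$x, apts$y, rep("astro_star", n_as),
                          soma_radius_um = spec$soma_radius_astro_um,
                          n_branches = rep(6L, n_as),
                          branch_length_um = spec$astro_arm_length_um,
                          stain_amount = clip(stats::rnorm(n_as, lat$gfap_od, 0.03),
                                              0.1, 2),
                          angle0 = stats::runif(n_as, 0, 2 * pi))

    cells <- rbind(mg, as_cells, peri_cells)
    cells$roi_name <- roi
    all_cells[[roi]] <- cells
    all_vessels[[roi]] <- vdf
    truth_rois[[roi]] <- c(lat[c("microglia_density", "amoeboid_frac",
                                 "iba1_od", "branch_length", "astro_density",
                                 "gfap_od", "peri_density")],
      list(n_microglia = n_mg,
           realized_amoeboid_frac = if (n_mg > 0) n_amo / n_mg else NA_real_,
           realized_frequency_per_mm2 = n_mg / area_mm2,
           mean_skeleton_um = if (n_mg > 0)
             mean(mg$n_branches * mg$branch_length_um) else NA_real_,
           roi_area_mm2 = area_mm2,
           grades = as.integer(vdf$true_grade),
           pct_severe = 100 * mean(vdf$true_grade == 3),
           pct_close_range = 100 * mean(vdf$true_close_range)))
  }
  list(cells = do.call(rbind, all_cells),
       vessels = do.call(rbind, all_vessels),
       truth = truth_rois)
}

# place_points with progressive spacing relaxation: dense draws near the
# random-packing limit can stall pure rejection sampling, so the minimum
# spacing is reduced stepwise until placement succeeds.
place_points_relaxed <- function(n, mask, spacing_px) {
  for (relax in c(1, 0.85, 0.7, 0.5)) {
    pts <- tryCatch(place_points(n, mask, relax * spacing_px,
                                 max_tries_per_point = 200),
                    error = function(e) NULL)
    if (!is.null(pts)) return(pts)
  }
  stop("could not place ", n, " points even at half spacing")
}

# Shrink a rectangular mask by `border` pixels (cheap erosion for the
# axis-aligned ROI rectangles used by the generator).
erode_rect <- function(mask, border) {
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  r0 <- rr[1] + border; r1 <- rr[2] - border
  c0 <- cc[1] + border; c1 <- cc[2] - border
  if (r0 <= r1 && c0 <= c1) out[r0:r1, c0:c1] <- TRUE
  out & mask
}

# Mask pixels far enough from every lumen that a parenchymal astroglia
# placed there cannot touch a perivascular one: perivascular cells extend to
# 13 um (band) + soma + arm from the lumen, parenchymal arms reach
# soma + arm inward from their centre, plus slack.
vessel_clearance_mask <- function(spec, vessels, mask) {
  px <- spec$pixel_size_um
  clear <- mask
  if (is.null(vessels) || nrow(vessels) == 0) return(clear)
  peri_extent <- 13 + spec$soma_radius_astro_um +
    1.5 * spec$soma_radius_astro_um
  par_reach <- spec$soma_radius_astro_um + spec$astro_arm_length_um
  guard <- (peri_extent + par_reach + 3) / px
  for (j in seq_len(nrow(vessels))) {
    v <- vessels[j, ]
    r <- max(v$a_um, v$b_um) / px + guard
    clear <- add_ellipse(clear, v$x, v$y, r, r, 0, FALSE, assign = TRUE)
  }
  clear & mask
}

#' Generate a synthetic cohort on disk
#'
#' Writes, per subject: HE / IBA1 / GFAP slide TIFFs, ROI masks on the MRI
#' grid (plus the true histology-grid masks for reference), the degraded MRI
#' counterpart, exact landmark pairs, the true MRI-to-histology transform and
#' a ground-truth JSON; plus one cohort metadata CSV. Fully deterministic for
#' a fixed spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) list with `dir`, `subjects` (cohort table),
#'   `truth` (per-subject ground truth), `rois_hist` (true histology-grid
#'   ROI set).
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  subjects <- draw_subjects(spec)
  rois <- cohort_roi_masks(spec)
  px <- spec$pixel_size_um
  bg <- list(hema = spec$hema_background, noise_amp = spec$hema_noise_amp,
             noise_sigma_px = spec$hema_noise_sigma_px,
             pixel_noise_sd = spec$pixel_noise_sd)
  truth_all <- list()
  for (i in seq_len(nrow(subjects))) {
    sub <- subjects[i, ]
    sdir <- file.path(out_dir, "subjects", sub$subject_id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    real <- realize_subject(spec, sub, rois)
    for (stain in c("HE", "IBA1_DAB", "GFAP_DAB")) {
      img <- render_slide(real$cells, real$vessels, spec$slide_dim,
                          stain_kind = stain, pixel_size_um = px,
                          background = bg, subject_id = sub$subject_id)
      fn <- c(HE = "he.tiff", IBA1_DAB = "iba1.tiff",
              GFAP_DAB = "gfap.tiff")[[stain]]
      write_stain_image(img, file.path(sdir, fn))
    }
    # anatomy raster for the MRI counterpart: WMH bright, vessels dark
    anat <- matrix(100, spec$slide_dim[1], spec$slide_dim[2])
    anat[rois$masks$WMH] <- 190
    anat <- anat + 25 * smooth_noise_field(nrow(anat), ncol(anat), 20)
    for (j in seq_len(nrow(real$vessels))) {
      v <- real$vessels[j, ]
      anat <- add_ellipse(anat, v$x, v$y, v$a_um / px, v$b_um / px,
                          v$orientation_rad, 30, assign = TRUE)
    }
    anat <- clip(anat, 0, 255)
    mri <- make_mri_counterpart(
      anat,
      transform_params = list(rot_deg = spec$mri_rot_deg,
                              translation_px = stats::rnorm(2, 0, 3),
                              warp_amp_px = spec$mri_warp_amp_px,
                              warp_period_px = 200),
      blur_um = spec$mri_blur_um, downsample_factor = spec$mri_downsample,
      pixel_size_um = px, n_landmarks = spec$n_landmarks)
    write_stain_image(mri$image, file.path(sdir, "mri.png"))
    # ROI masks on the MRI grid, pulled back through the true map
    nr_m <- nrow(mri$image); nc_m <- ncol(mri$image)
    gx <- rep(0:(nc_m - 1), each = nr_m)
    gy <- rep(0:(nr_m - 1), times = nc_m)
    src <- mri$true_map(cbind(gx, gy))
    mri_masks <- lapply(rois$masks, function(m) {
      matrix(sample_raster(matrix(as.numeric(m), nrow(m)), src[, 1], src[, 2],
                           method = "nearest", background = 0) != 0,
             nr_m, nc_m)
    })
    write_roi_masks(roi_set(mri_masks, "MRI", mri$pixel_size_um),
                    c(NAWM = file.path(sdir, "roi_NAWM_mri.png"),
                      WMH = file.path(sdir, "roi_WMH_mri.png")))
    write_roi_masks(rois, c(NAWM = file.path(sdir, "roi_NAWM_hist_true.png"),
                            WMH = file.path(sdir, "roi_WMH_hist_true.png")))
    utils::write.csv(mri$landmarks, file.path(sdir, "landmarks.csv"),
                     row.names = FALSE)
    write_transform(mri$transform, file.path(sdir, "transform_true.json"))
    truth <- list(subject_id = sub$subject_id, rois = real$truth,
                  vessels = real$vessels, n_cells = nrow(real$cells))
    jsonlite::write_json(truth, file.path(sdir, "truth.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
    truth_all[[sub$subject_id]] <- c(truth, list(cells = real$cells))
  }
  utils::write.csv(subjects, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  invisible(list(dir = out_dir, subjects = validate_cohort_table(subjects),
                 truth = truth_all, rois_hist = rois))
}
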