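# Shared fixture builders. All rasters are generated in code at test time.

# Rasterised disk mask: radius r pixels, centred in a square raster.
disk_mask <- function(r, pad = 5) {
  n <- 2 * r + 2 * pad + 1
  c0 <- (n - 1) / 2
  xs <- rep(0:(n - 1), each = n)
  ys <- rep(0:(n - 1), times = n)
  matrix((xs - c0)^2 + (ys - c0)^2 <= r^2, n, n)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# A random affine with bounded rotation/scale, mapping points exactly.
random_affine <- function(max_rot_deg = 20, scale_range = c(0.5, 2)) {
  th <- stats::runif(1, -max_rot_deg, max_rot_deg) * pi / 180
  s <- stats::runif(1, scale_range[1], scale_range[2])
  t <- stats::runif(2, -20, 20)
  matrix(c(cos(th) * s, -sin(th) * s, t[1],
           sin(th) * s,  cos(th) * s, t[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

# Landmarks under a given homogeneous affine.
landmarks_under <- function(A, n = 12, noise_sd = 0) {
  mov <- cbind(stats::runif(n, 0, 200), stats::runif(n, 0, 200))
  fix <- cbind(mov, 1) %*% t(A)
  data.frame(x_moving = mov[, 1], y_moving = mov[, 2],
             x_fixed = fix[, 1] + stats::rnorm(n, 0, noise_sd),
             y_fixed = fix[, 2] + stats::rnorm(n, 0, noise_sd))
}

# Render a slide of well-separated microglia; returns list(cells, image).
microglia_slide <- function(n, dim_px = NULL, spacing = 34,
                            amoeboid_frac = 0.5, stain = 0.65,
                            noise = FALSE, seed = 1) {
  set.seed(seed)
  if (is.null(dim_px)) dim_px <- max(340, ceiling(sqrt(n) * 42) + 80)
  margin <- 20
  roi <- matrix(FALSE, dim_px, dim_px)
  roi[(margin + 1):(dim_px - margin), (margin + 1):(dim_px - margin)] <- TRUE
  pts <- gliovasc:::place_points(n, roi, spacing)
  phen <- ifelse(stats::runif(n) < amoeboid_frac, "amoeboid", "ramified")
  cells <- cell_spec(pts$x, pts$y, phen,
                     soma_radius_um = ifelse(phen == "amoeboid", 5, 3.5),
                     n_branches = ifelse(phen == "amoeboid", 0L, 5L),
                     branch_length_um = ifelse(phen == "amoeboid", 0, 12),
                     stain_amount = stain,
                     angle0 = stats::runif(n, 0, 2 * pi))
  bg <- if (noise) list() else list(noise_amp = 0, pixel_noise_sd = 0)
  img <- render_slide(cells, NULL, c(dim_px, dim_px), "IBA1_DAB",
                      background = bg, seed = seed + 1)
  list(cells = cells, image = img)
}

# Outcome table from the table-level cohort simulation.
simulated_outcomes <- function(spec) {
  sim <- simulate_true_metrics(spec)
  merge(sim$outcomes, sim$subjects, by = "subject_id", sort = FALSE)
}
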