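test_that("cell and vessel specs enforce their invariants", {
  expect_error(cell_spec(1, 1, "ramified", n_branches = 1L), "n_branches")
  expect_error(cell_spec(1, 1, "amoeboid", n_branches = 2L), "amoeboid")
  expect_error(cell_spec(1, 1, "amoeboid", soma_radius_um = 0), "soma")
  expect_error(cell_spec(1, 1, "amoeboid", stain_amount = -1), "negative")
  expect_error(vessel_spec(1, 1, 0, 5), "semi-axes")
  expect_error(vessel_spec(1, 1, 5, 5, perivascular_density_per_mm2 = -1),
               ">= 0")
  expect_error(cohort_spec(n_control = 0), "at least one")
  expect_error(cohort_spec(iba1_od_sd = -1), "SDs")
})

test_that("rendering is deterministic and background-exact", {
  # zero objects, zero noise: uniform background colour everywhere
  img <- render_slide(NULL, NULL, c(30, 40), "HE",
                      background = list(noise_amp = 0, pixel_noise_sd = 0),
                      seed = 81)
  for (k in 1:3) expect_equal(length(unique(as.vector(img$pixels[, , k]))), 1)

  # fixed seed: identical rasters
  cl <- cell_spec(c(20, 40), c(20, 35), c("amoeboid", "ramified"),
                  soma_radius_um = c(5, 3.5), n_branches = c(0L, 4L),
                  branch_length_um = c(0, 10), stain_amount = 0.6,
                  angle0 = c(0, 1))
  a <- render_slide(cl, NULL, c(60, 60), "IBA1_DAB", seed = 82)
  b <- render_slide(cl, NULL, c(60, 60), "IBA1_DAB", seed = 82)
  expect_identical(a$pixels, b$pixels)

  # objects outside the raster are rejected
  expect_error(render_slide(cell_spec(59, 59, "amoeboid", soma_radius_um = 6),
                            NULL, c(60, 60), "IBA1_DAB", seed = 83),
               "outside")
})

test_that("phenotypes render on their own stains only", {
  cl <- rbind(cell_spec(20, 20, "amoeboid", soma_radius_um = 5,
                        stain_amount = 0.7),
              cell_spec(45, 45, "astro_star", soma_radius_um = 4,
                        n_branches = 6L, branch_length_um = 6,
                        stain_amount = 0.7))
  bg <- list(noise_amp = 0, pixel_noise_sd = 0)
  iba <- attr(render_slide(cl, NULL, c(64, 64), "IBA1_DAB", background = bg,
                           seed = 1), "conc")$dab
  gfa <- attr(render_slide(cl, NULL, c(64, 64), "GFAP_DAB", background = bg,
                           seed = 1), "conc")$dab
  expect_gt(iba[21, 21], 0); expect_equal(iba[46, 46], 0)
  expect_gt(gfa[46, 46], 0); expect_equal(gfa[21, 21], 0)
})

test_that("the MRI counterpart returns exact landmark pairs and a true map", {
  anat <- matrix(runif(120 * 160, 0, 255), 120, 160)
  # identity-ish: no rotation, no warp, factor 1
  m0 <- make_mri_counterpart(anat, transform_params = list(rot_deg = 0),
                             blur_um = 0, downsample_factor = 1,
                             n_landmarks = 10, seed = 84)
  expect_equal(dim(m0$image), dim(anat))
  expect_equal(m0$transform$kind, "affine")
  expect_equal(transform_points(m0$transform, cbind(5:10, 7:12)),
               cbind(5:10, 7:12), tolerance = 1e-9)

  # known rotation + scale: truth transform maps landmarks with zero residual
  m1 <- make_mri_counterpart(anat, transform_params = list(rot_deg = 10,
                                                           scale = 1),
                             blur_um = 4, downsample_factor = 2,
                             n_landmarks = 12, seed = 85)
  pred <- transform_points(m1$transform,
                           as.matrix(m1$landmarks[, c("x_moving", "y_moving")]))
  expect_lt(max(abs(pred - as.matrix(m1$landmarks[, c("x_fixed", "y_fixed")]))),
            1e-9)

  # with warp: landmark pairs still sampled exactly from the true map
  m2 <- make_mri_counterpart(anat, transform_params = list(rot_deg = 5,
                                                           warp_amp_px = 2),
                             blur_um = 4, downsample_factor = 2,
                             n_landmarks = 12, seed = 86)
  mov <- as.matrix(m2$landmarks[, c("x_moving", "y_moving")])
  expect_equal(m2$true_map(mov),
               unname(as.matrix(m2$landmarks[, c("x_fixed", "y_fixed")])),
               tolerance = 1e-12)
  expect_equal(m2$transform$kind, "tps")

  expect_error(make_mri_counterpart(anat,
                                    transform_params = list(scale = 0)),
               "degenerate")
})

test_that("a tiny cohort writes a complete, deterministic file tree", {
  spec <- cohort_spec(n_hypertension = 2, n_control = 2, seed = 87,
                      slide_dim = c(300, 600), roi_size_px = 220,
                      vessels_per_roi = 3L, lumen_radius_um = c(10, 20),
                      vessel_spacing_um = 70, n_landmarks = 10)
  d1 <- withr::local_tempdir()
  g <- generate_cohort(spec, d1)
  expect_equal(nrow(g$subjects), 4)
  expect_length(list.dirs(file.path(d1, "subjects"), recursive = FALSE), 4)
  for (id in g$subjects$subject_id) {
    sd <- file.path(d1, "subjects", id)
    expect_true(all(file.exists(file.path(sd, c(
      "he.tiff", "iba1.tiff", "gfap.tiff", "mri.png",
      "roi_NAWM_mri.png", "roi_WMH_mri.png", "landmarks.csv",
      "transform_true.json", "truth.json")))))
  }
  expect_true(file.exists(file.path(d1, "cohort.csv")))

  # byte-identical regeneration under the same spec
  d2 <- withr::local_tempdir()
  generate_cohort(spec, d2)
  for (f in c("cohort.csv", "subjects/S01/he.tiff", "subjects/S01/iba1.tiff",
              "subjects/S03/gfap.tiff", "subjects/S02/mri.png",
              "subjects/S04/landmarks.csv", "subjects/S01/truth.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6),
                     label = f)
  }
})

test_that("ground truth is self-consistent with the object lists", {
  spec <- cohort_spec(n_hypertension = 1, n_control = 1, seed = 88,
                      slide_dim = c(300, 600), roi_size_px = 220,
                      vessels_per_roi = 3L, lumen_radius_um = c(10, 20),
                      vessel_spacing_um = 70)
  d <- withr::local_tempdir()
  g <- generate_cohort(spec, d)
  for (id in names(g$truth)) {
    tr <- g$truth[[id]]
    cells <- tr$cells
    for (roi in c("NAWM", "WMH")) {
      rt <- tr$rois[[roi]]
      mg <- cells[cells$roi_name == roi &
                    cells$phenotype %in% c("ramified", "amoeboid"), ]
      expect_equal(nrow(mg), rt$n_microglia)
      expect_equal(mean(mg$phenotype == "amoeboid"),
                   rt$realized_amoeboid_frac)
      expect_equal(nrow(mg) / rt$roi_area_mm2, rt$realized_frequency_per_mm2)
      expect_equal(mean(mg$n_branches * mg$branch_length_um),
                   rt$mean_skeleton_um)
      vs <- tr$vessels[tr$vessels$roi_name == roi, ]
      expect_equal(rt$grades, as.integer(vs$true_grade))
      expect_equal(rt$pct_severe, 100 * mean(vs$true_grade == 3))
      # per-vessel density identity and grade rule consistency
      expect_equal(vs$true_density, vs$true_count / vs$annulus_area_mm2)
      expect_equal(as.integer(vs$true_grade),
                   as.integer(grade_vessel(vs$true_density, vs$true_count,
                                           vs$scar)))
    }
  }
})

test_that("group deltas are realised in the ground truth within sampling error", {
  set.seed(89)
  # amoeboid fraction delta: +0.1 x effect scale 2 = +0.2
  diffs <- replicate(12, {
    sim <- simulate_true_metrics(cohort_spec(
      n_hypertension = 10, n_control = 10, seed = sample.int(1e7, 1),
      effect_scale = 2))
    ot <- merge(sim$outcomes, sim$subjects, by = "subject_id")
    d <- ot[ot$outcome_name == "amoeboid_frac", ]
    mean(d$value[d$group == "hypertension"]) -
      mean(d$value[d$group == "control"])
  })
  expect_lt(abs(mean(diffs) - 0.2), 3 * sd(diffs) / sqrt(length(diffs)) + 0.02)

  # all deltas zero: group difference is pure noise
  sim0 <- simulate_true_metrics(cohort_spec(n_hypertension = 30,
                                            n_control = 30, seed = 90,
                                            effect_scale = 0))
  ot0 <- merge(sim0$outcomes, sim0$subjects, by = "subject_id")
  d0 <- ot0[ot0$outcome_name == "iba1_od", ]
  tt <- t.test(value ~ group, data = d0)
  expect_gt(tt$p.value, 0.001)
})

test_that("scar rendering covers the requested fraction of the inner ring", {
  v <- vessel_spec(80, 80, 20, 20, 0, scar = TRUE)
  gf <- render_slide(NULL, v, c(160, 160), "GFAP_DAB",
                     background = list(noise_amp = 0, pixel_noise_sd = 0),
                     scar_coverage = 0.9, seed = 91)
  conc <- attr(gf, "conc")$dab
  # coverage measured on the rendered band, 5 um outside the lumen
  ang <- seq(0, 2 * pi, length.out = 721)[-721]
  ring_vals <- conc[cbind(round(80 + 25 * sin(ang)) + 1,
                          round(80 + 25 * cos(ang)) + 1)]
  expect_gte(mean(ring_vals > 0), 0.85)
  expect_lte(mean(ring_vals > 0), 0.95)
})
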