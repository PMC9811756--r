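# Helper: detection + zone for a single rendered circular vessel.
single_vessel_fixture <- function(r_um = 20, dim_px = c(200, 300),
                                  center = c(150, 100), seed = 1) {
  v <- vessel_spec(center[1], center[2], r_um, r_um, 0)
  he <- render_slide(NULL, v, dim_px, "HE",
                     background = list(noise_amp = 0, pixel_noise_sd = 0),
                     seed = seed)
  det <- detect_vessels(separate_stains(he)$maps$hematoxylin,
                        matrix(TRUE, dim_px[1], dim_px[2]), 1)
  det
}

test_that("rendered elliptical lumens are detected; small/absent ones are not", {
  set.seed(41)
  vs <- vessel_spec(x = c(60, 170, 280, 120, 250), y = c(60, 60, 60, 170, 170),
                    a_um = c(12, 20, 30, 16, 25), b_um = c(10, 15, 22, 12, 20),
                    orientation_rad = runif(5, 0, pi))
  he <- render_slide(NULL, vs, c(240, 340), "HE",
                     background = list(noise_amp = 0.02, pixel_noise_sd = 0.01),
                     seed = 42)
  det <- detect_vessels(separate_stains(he)$maps$hematoxylin,
                        matrix(TRUE, 240, 340), 1)
  expect_equal(nrow(det$vessels), 5)

  # uniform tissue: no lumens
  he0 <- render_slide(NULL, NULL, c(100, 100), "HE",
                      background = list(noise_amp = 0.02,
                                        pixel_noise_sd = 0.01), seed = 43)
  det0 <- detect_vessels(separate_stains(he0)$maps$hematoxylin,
                         matrix(TRUE, 100, 100), 1)
  expect_equal(nrow(det0$vessels), 0)

  # a lumen below the minimum area is excluded
  tiny <- vessel_spec(50, 50, 4, 4, 0)   # ~50 um^2 < 80
  het <- render_slide(NULL, tiny, c(100, 100), "HE",
                      background = list(noise_amp = 0, pixel_noise_sd = 0),
                      seed = 44)
  dett <- detect_vessels(separate_stains(het)$maps$hematoxylin,
                         matrix(TRUE, 100, 100), 1, min_lumen_area_um2 = 80)
  expect_equal(nrow(dett$vessels), 0)
})

test_that("the perivascular annulus matches its closed-form area", {
  for (r in c(15, 20, 30)) {
    det <- single_vessel_fixture(r_um = r, dim_px = c(2 * r + 80, 2 * r + 80),
                                 center = c(r + 40, r + 40))
    z <- perivascular_zone(det, det$vessels$id[1], 15,
                           matrix(TRUE, 2 * r + 80, 2 * r + 80), 1)
    closed <- pi * ((r + 15)^2 - r^2) * 1e-6
    expect_lt(abs(z$area_mm2 - closed) / closed, 0.05)
  }
})

test_that("the annulus vanishes as the distance goes to zero and excludes lumens", {
  det <- single_vessel_fixture()
  z <- perivascular_zone(det, det$vessels$id[1], 1e-6,
                         matrix(TRUE, 200, 300), 1)
  expect_equal(sum(z$annulus), 0)
  expect_error(perivascular_zone(det, det$vessels$id[1], 0), "distance_um > 0")

  # two abutting vessels: each annulus excludes the other's lumen
  vs <- vessel_spec(x = c(120, 165), y = c(100, 100), a_um = c(18, 18),
                    b_um = c(18, 18))
  he <- render_slide(NULL, vs, c(200, 300), "HE",
                     background = list(noise_amp = 0, pixel_noise_sd = 0),
                     seed = 45)
  det2 <- detect_vessels(separate_stains(he)$maps$hematoxylin,
                         matrix(TRUE, 200, 300), 1)
  expect_equal(nrow(det2$vessels), 2)
  z1 <- perivascular_zone(det2, det2$vessels$id[1], 15,
                          matrix(TRUE, 200, 300), 1)
  expect_equal(sum(z1$annulus & det2$lumen_mask), 0)
})

test_that("perivascular astroglia counting is arithmetic on centroids", {
  det <- single_vessel_fixture(r_um = 25, dim_px = c(220, 220),
                               center = c(110, 110))
  z <- perivascular_zone(det, det$vessels$id[1], 15,
                         matrix(TRUE, 220, 220), 1)
  # 10 centroids placed inside the annulus at distance ~7 um
  ang <- seq(0, 2 * pi, length.out = 11)[1:10]
  cells <- data.frame(x = 110 + 32 * cos(ang), y = 110 + 32 * sin(ang))
  cnt <- count_perivascular_astroglia(cells, z)
  expect_equal(cnt$count, 10L)
  expect_equal(cnt$density_per_mm2, 10 / z$area_mm2)

  # no cells
  expect_equal(count_perivascular_astroglia(cells[0, ], z)$count, 0L)
  # centroid at the outer boundary (distance = 15 um) is counted
  d <- z$distance_px
  at15 <- which(d == 15 & z$annulus, arr.ind = TRUE)
  if (nrow(at15)) {
    cells15 <- data.frame(x = at15[1, 2] - 1, y = at15[1, 1] - 1)
    expect_equal(count_perivascular_astroglia(cells15, z)$count, 1L)
  }
})

test_that("the grading rule reproduces the printed definitions", {
  expect_equal(grade_vessel(50, 1, FALSE), 1L)    # mild: < 100 / mm^2
  expect_equal(grade_vessel(350, 2, FALSE), 3L)   # severe: > 300 / mm^2
  expect_equal(grade_vessel(0, 0, FALSE), 0L)     # none
  expect_equal(grade_vessel(150, 1, TRUE), 3L)    # scar forces severe
  # boundary conventions: 100 and 300 are moderate
  expect_equal(grade_vessel(100, 1, FALSE), 2L)
  expect_equal(grade_vessel(300, 2, FALSE), 2L)
  expect_equal(grade_vessel(99.999, 1, FALSE), 1L)
  expect_equal(grade_vessel(300.001, 2, FALSE), 3L)
  expect_error(grade_vessel(-1, 0, FALSE), "negative")
})

test_that("grading agrees with a direct piecewise oracle over a dense sweep", {
  oracle <- function(density, count, scar) {
    if (scar) return(3L)
    if (count == 0) return(0L)
    if (density > 300) return(3L)
    if (density >= 100) return(2L)
    1L
  }
  for (scar in c(FALSE, TRUE)) {
    for (density in 0:500) {
      count <- if (density == 0) 0L else max(1L, round(density / 250))
      expect_identical(grade_vessel(density, count, scar),
                       oracle(density, count, scar))
    }
  }
})

test_that("adding an astroglia inside the annulus never lowers the grade", {
  set.seed(46)
  det <- single_vessel_fixture(r_um = 20, dim_px = c(200, 200),
                               center = c(100, 100))
  z <- perivascular_zone(det, det$vessels$id[1], 15,
                         matrix(TRUE, 200, 200), 1)
  ang <- runif(12, 0, 2 * pi)
  cells <- data.frame(x = 100 + 27 * cos(ang), y = 100 + 27 * sin(ang))
  grades <- vapply(0:12, function(k) {
    cnt <- count_perivascular_astroglia(cells[seq_len(k), , drop = FALSE], z)
    grade_vessel(cnt$density_per_mm2, cnt$count, FALSE)
  }, integer(1))
  expect_true(all(diff(grades) >= 0))
})

test_that("scar detection requires both angular coverage and band fill", {
  mkscar <- function(coverage) {
    v <- vessel_spec(100, 100, 20, 20, 0, scar = TRUE)
    gf <- render_slide(NULL, v, c(200, 200), "GFAP_DAB",
                       background = list(noise_amp = 0, pixel_noise_sd = 0),
                       scar_coverage = coverage, seed = 47)
    he <- render_slide(NULL, v, c(200, 200), "HE",
                       background = list(noise_amp = 0, pixel_noise_sd = 0),
                       seed = 47)
    det <- detect_vessels(separate_stains(he)$maps$hematoxylin,
                          matrix(TRUE, 200, 200), 1)
    z <- perivascular_zone(det, det$vessels$id[1], 15,
                           matrix(TRUE, 200, 200), 1)
    pos <- separate_stains(gf)$maps$dab >= 0.3
    detect_scar(pos, z, det, det$vessels$id[1])
  }
  expect_true(mkscar(1.0))     # full ring
  expect_false(mkscar(0.5))    # half-ring fails the 75% coverage rule

  # isolated cells at ~10% coverage are not a scar
  det <- single_vessel_fixture(r_um = 20, dim_px = c(200, 200),
                               center = c(100, 100))
  z <- perivascular_zone(det, det$vessels$id[1], 15,
                         matrix(TRUE, 200, 200), 1)
  pos <- matrix(FALSE, 200, 200); pos[100:104, 128:132] <- TRUE
  expect_false(detect_scar(pos, z, det, det$vessels$id[1]))
})

test_that("the close-range flag follows the 5 um inclusive rule", {
  det <- single_vessel_fixture(r_um = 20, dim_px = c(200, 200),
                               center = c(100, 100))
  z <- perivascular_zone(det, det$vessels$id[1], 15,
                         matrix(TRUE, 200, 200), 1)
  near <- data.frame(x = 123, y = 100)      # ~3 um from the boundary
  far <- data.frame(x = 132.5, y = 100)     # ~12 um away
  expect_true(close_range_flag(near, z, 5, 1))
  expect_false(close_range_flag(far, z, 5, 1))
  # exactly at 5 um (distance map value 25 - 20 = 5): counted
  d <- z$distance_px
  at5 <- which(d == 5, arr.ind = TRUE)
  if (nrow(at5)) {
    exact <- data.frame(x = at5[1, 2] - 1, y = at5[1, 1] - 1)
    expect_true(close_range_flag(exact, z, 5, 1))
  }
})

test_that("region summaries are percentage arithmetic and conserve mass", {
  ass <- data.frame(vessel_id = 1:4, annulus_area_mm2 = 0.003,
                    astro_count = c(1, 2, 2, 3),
                    density_per_mm2 = c(50, 150, 200, 400),
                    grade = c(1L, 2L, 2L, 3L),
                    close_range = c(FALSE, TRUE, FALSE, TRUE),
                    scar = FALSE)
  s <- summarize_region(ass, "S", "WMH")
  expect_equal(s$pct_mild, 25)
  expect_equal(s$pct_moderate, 50)
  expect_equal(s$pct_severe, 25)
  expect_equal(s$pct_with_inflammation, 100)
  expect_equal(s$pct_close_range, 50)
  expect_equal(s$n_vessels, 4)

  # grade percentages over 0-3 sum to 100
  set.seed(48)
  for (i in 1:20) {
    g <- sample(0:3, sample(1:12, 1), replace = TRUE)
    a2 <- data.frame(vessel_id = seq_along(g), annulus_area_mm2 = 0.003,
                     astro_count = g, density_per_mm2 = g * 100,
                     grade = g, close_range = FALSE, scar = FALSE)
    s2 <- summarize_region(a2, "S", "NAWM")
    pct0 <- 100 * mean(g == 0)
    expect_equal(s2$pct_mild + s2$pct_moderate + s2$pct_severe + pct0, 100)
  }

  # all grade 0 and singleton cases
  a0 <- data.frame(vessel_id = 1, annulus_area_mm2 = 0.003, astro_count = 0,
                   density_per_mm2 = 0, grade = 0L, close_range = FALSE,
                   scar = FALSE)
  s0 <- summarize_region(a0, "S", "NAWM")
  expect_equal(unlist(s0[c("pct_with_inflammation", "pct_mild",
                           "pct_moderate", "pct_severe", "pct_close_range")]),
               c(pct_with_inflammation = 0, pct_mild = 0, pct_moderate = 0,
                 pct_severe = 0, pct_close_range = 0))
  a3 <- data.frame(vessel_id = 1, annulus_area_mm2 = 0.003, astro_count = 5,
                   density_per_mm2 = 500, grade = 3L, close_range = TRUE,
                   scar = FALSE)
  s3 <- summarize_region(a3, "S", "WMH")
  expect_equal(c(s3$pct_with_inflammation, s3$pct_mild, s3$pct_moderate,
                 s3$pct_severe, s3$pct_close_range), c(100, 0, 0, 100, 100))
  expect_error(summarize_region(ass[0, ], "S", "WMH"), "empty")
})

test_that("generated perivascular densities are realised within one cell", {
  set.seed(49)
  for (dens in c(0, 200, 400, 800)) {
    v <- vessel_spec(110, 110, 25, 20, 0.4)
    pc <- make_vessel_with_density(v, dens, c(220, 220), 1,
                                   soma_radius_um = 4, seed = 50 + dens)
    area <- attr(pc, "annulus_area_mm2")
    expect_equal(nrow(pc), round(dens * area))
    expect_lte(abs(nrow(pc) / area - dens), 1 / area + 1e-9)
    if (nrow(pc)) {
      d <- attr(pc, "boundary_distance_um")
      expect_true(all(d > 0 & d <= 15))
    }
  }
  # an annulus genuinely too small for the requested spacing errors out
  vtiny <- vessel_spec(30, 30, 6, 6, 0)
  expect_error(make_vessel_with_density(vtiny, 20000, c(60, 60), 1,
                                        soma_radius_um = 6, seed = 51),
               "density")
})

test_that("manually outlined lumens grade identically to detected ones", {
  # a 20 um circular lumen supplied as a 24-gon outline
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  poly <- data.frame(vessel_id = 1, x = 100 + 20 * cos(ang),
                     y = 100 + 20 * sin(ang))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(poly, f, row.names = FALSE)
  det <- vessels_from_outlines(f, c(200, 200), 1)
  expect_equal(nrow(det$vessels), 1)
  expect_lt(abs(det$vessels$area_um2 - pi * 400) / (pi * 400), 0.05)
  z <- perivascular_zone(det, 1, 15, matrix(TRUE, 200, 200), 1)
  closed <- pi * ((20 + 15)^2 - 400) * 1e-6
  expect_lt(abs(z$area_mm2 - closed) / closed, 0.06)
  cells <- data.frame(x = 100 + 27 * cos(ang[1:4]),
                      y = 100 + 27 * sin(ang[1:4]))
  cnt <- count_perivascular_astroglia(cells, z)
  expect_equal(cnt$count, 4L)
  expect_error(vessels_from_outlines(f, c(200, 200)) -> d2, NA)
  bad <- data.frame(vessel_id = 1, x = 1:2, y = 1:2)
  write.csv(bad, f, row.names = FALSE)
  expect_error(vessels_from_outlines(f, c(50, 50)), "3 vertices")
})
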