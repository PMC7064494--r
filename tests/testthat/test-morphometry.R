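test_that("resolution normalization preserves physical geometry", {
  s <- generate_phantom(tiny_spec(), seed = 5)
  m <- s$micrograph  # 1 um/px regime

  # identity: target equals current calibration
  same <- normalize_resolution(m, 1.0)
  expect_identical(same$pixels, m$pixels)

  # downscale 2x: pixel counts shrink ~4x but um^2 area is stable within 5%
  nrm <- normalize_resolution(m, 2.0, masks = s$masks)
  a_before <- sum(s$masks$inner) * 1.0^2
  a_after <- sum(nrm$masks$inner) * 2.0^2
  expect_lt(abs(a_after / a_before - 1), 0.05)
  expect_equal(nrm$micrograph$microns_per_pixel, 2.0)

  # a constant image stays constant at any scale
  cm <- micrograph(matrix(77L, 64, 64), 0.5)
  expect_true(all(normalize_resolution(cm, 1.0)$pixels == 77L))

  expect_error(normalize_resolution(m, -1), "positive")
})

test_that("local entropy map matches direct histogram entropy", {
  # constant image: single-symbol histogram, zero bits everywhere
  cm <- micrograph(matrix(100L, 48, 48), 1)
  expect_true(all(local_entropy_map(cm, 5) == 0))

  # a neighbourhood holding two intensities in equal counts is one fair
  # coin: exactly 1 bit. At the (1,1) corner a radius-2 disk covers 6
  # pixels; make 3 of them bright.
  px <- matrix(10L, 32, 32)
  px[1, 1] <- px[1, 2] <- px[2, 1] <- 200L
  e <- local_entropy_map(micrograph(px, 1), 2)
  expect_equal(e[1, 1], 1.0)

  # i.i.d. uniform noise: interior entropies in (0, 8]; sampled pixels
  # agree with the independent oracle
  set.seed(42)
  noisy <- micrograph(matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64), 1)
  e <- local_entropy_map(noisy, 9)
  interior <- e[10:55, 10:55]
  expect_true(all(interior > 0 & interior <= 8))
  set.seed(7)
  ii <- sample(10:55, 20, replace = TRUE)
  jj <- sample(10:55, 20, replace = TRUE)
  for (k in 1:20)
    expect_equal(e[ii[k], jj[k]],
                 oracle_entropy_at(noisy$pixels, ii[k], jj[k], 9),
                 tolerance = 1e-12)

  expect_error(local_entropy_map(noisy, 0), ">= 1")
  expect_error(local_entropy_map(noisy, 40), "exceeds")
})

test_that("canny edges localize on intensity steps", {
  # constant image: no edges
  cm <- micrograph(matrix(50L, 64, 64), 1)
  expect_equal(sum(canny_edges(cm)), 0L)

  # vertical two-level step, 64 rows: a ~1-px-wide vertical edge whose
  # pixel count is within 10% of the row count (oracle: one smoothed
  # gradient sign-change ridge per row)
  step <- matrix(40L, 64, 64)
  step[, 33:64] <- 200L
  ed <- canny_edges(micrograph(step, 1))
  expect_lt(abs(sum(ed) - 64) / 64, 0.10)
  edge_cols <- which(apply(ed, 2, any))
  expect_true(all(edge_cols %in% 31:34))

  expect_error(canny_edges(cm, low = 5, high = 2), "thresholds")
})

test_that("zero-noise phantom edges hug the region interfaces", {
  spec <- tiny_spec(region_texture = list(
    background = list(mean = 40, sd = 0, smooth = 0),
    inner = list(mean = 150, sd = 0, smooth = 0),
    te = list(mean = 110, sd = 0, smooth = 0),
    zp = list(mean = 190, sd = 0, smooth = 0)))
  s <- generate_phantom(spec, seed = 2)
  ed <- canny_edges(s$micrograph)
  pts <- which(ed, arr.ind = TRUE)
  pts_xy <- cbind(pts[, 2] - 1, pts[, 1] - 1)
  g <- s$geometry
  shrink <- c(0, g$zp_px, g$zp_px + g$te_px)
  d <- Reduce(pmin, lapply(shrink, function(sh)
    blastometry:::dist_to_polygon_cpp(
      pts_xy, ellipse_polygon(g$cx, g$cy, g$a - sh, g$b - sh, g$theta))))
  expect_true(all(d <= 3))
})

test_that("region geometry agrees with pixel-count and contour oracles", {
  # 10x10 px square region at 1 um/px
  zp <- matrix(FALSE, 64, 64); zp[2:11, 2:11] <- TRUE
  te <- matrix(FALSE, 64, 64); te[20:29, 20:29] <- TRUE
  inner <- matrix(FALSE, 64, 64); inner[40:49, 40:49] <- TRUE
  g <- region_geometry(region_masks(zp, te, inner), 1)
  expect_equal(unname(g$area), c(100, 100, 100))
  for (p in g$perimeter) expect_lt(abs(p - 40) / 40, 0.10)

  # disk of radius 20 px at 0.5 um/px: area within 2% of pi * (10 um)^2
  xs <- matrix(rep(0:63, each = 64), 64, 64)
  ys <- matrix(rep(0:63, 64), 64, 64)
  disk <- (xs - 31)^2 + (ys - 31)^2 <= 20^2
  te2 <- matrix(FALSE, 64, 64); te2[56:61, 2:7] <- TRUE
  inner2 <- matrix(FALSE, 64, 64); inner2[56:61, 56:61] <- TRUE
  g2 <- region_geometry(region_masks(disk, te2, inner2), 0.5)
  expect_lt(abs(g2$area[["zp"]] - pi * 100) / (pi * 100), 0.02)

  expect_error(region_geometry(region_masks(zp, te, matrix(FALSE, 64, 64)), 1),
               "inner")
})

test_that("extract_features returns 24 finite calibrated values", {
  s <- generate_phantom(tiny_spec(), seed = 8)
  fv <- extract_features(s$micrograph, s$masks)
  expect_length(fv, 24L)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_identical(attr(fv, "units"), feature_units())
  expect_true(all(fv[grep("^area_", names(fv))] > 0))
  expect_true(all(fv[grep("^perimeter_", names(fv))] > 0))
  expect_true(all(fv[grep("^sd_", names(fv))] >= 0))
  ent <- fv[grep("^mean_entropy_", names(fv))]
  expect_true(all(ent >= 0 & ent <= 8))

  # determinism
  expect_identical(fv, extract_features(s$micrograph, s$masks))
})

test_that("zero-noise phantom features: flat texture, near-zero entropy", {
  spec <- tiny_spec(region_texture = list(
    background = list(mean = 40, sd = 0, smooth = 0),
    inner = list(mean = 150, sd = 0, smooth = 0),
    te = list(mean = 110, sd = 0, smooth = 0),
    zp = list(mean = 190, sd = 0, smooth = 0)))
  s <- generate_phantom(spec, seed = 4)
  fv <- extract_features(s$micrograph, s$masks)
  expect_equal(unname(fv[grep("^sd_intensity_", names(fv))]), c(0, 0, 0))
  # entropy map is zero strictly inside each region (only interface
  # neighbourhoods mix intensities)
  e <- local_entropy_map(s$micrograph, 9)
  nr <- nrow(e); nc <- ncol(e)
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  g <- s$geometry
  rad <- ((xs - g$cx) * cos(g$theta) + (ys - g$cy) * sin(g$theta))^2 /
    (g$a - g$zp_px - g$te_px - 10)^2 +
    (-(xs - g$cx) * sin(g$theta) + (ys - g$cy) * cos(g$theta))^2 /
    (g$b - g$zp_px - g$te_px - 10)^2
  deep <- rad <= 1
  expect_true(any(deep))
  expect_true(all(e[deep] == 0))
})

test_that("um-valued features are stable across the two calibration regimes", {
  spec <- tiny_spec()
  s20 <- generate_phantom(spec, seed = 31, objective = "20x")
  s40 <- generate_phantom(spec, seed = 31, objective = "40x")
  f20 <- extract_features(s20$micrograph, s20$masks)
  f40 <- extract_features(s40$micrograph, s40$masks)
  geom <- grep("^(area|perimeter)_", names(f20), value = TRUE)
  expect_true(all(abs(f40[geom] / f20[geom] - 1) <= 0.05))
})
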