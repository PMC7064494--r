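test_that("load_micrograph reads 8-bit grayscale and RGB with calibration", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "const.png")
  png::writePNG(matrix(128 / 255, 64, 64), p1)
  m <- load_micrograph(p1, 0.5)
  expect_s3_class(m, "micrograph")
  expect_true(all(m$pixels == 128L))
  expect_equal(m$microns_per_pixel, 0.5)
  expect_equal(m$sample_id, "const")

  # RGB with R = G = B = 200 -> luminance 200 everywhere
  p2 <- file.path(d, "rgb.png")
  png::writePNG(array(200 / 255, c(48, 48, 3)), p2)
  m2 <- load_micrograph(p2, 1)
  expect_true(all(m2$pixels == 200L))

  expect_error(load_micrograph(file.path(d, "missing.png"), 1), "not found")
  expect_error(load_micrograph(p1, 0), "positive")
})

test_that("16-bit input is rescaled by max-normalization", {
  # oracle: direct arithmetic — raw 16-bit values v map to round(v/max*255)
  d <- withr::local_tempdir()
  raw16 <- matrix(0L, 32, 32)
  raw16[1:3, 1:3] <- matrix(c(0L, 1000L, 2000L, 8000L, 16000L, 24000L,
                              32000L, 40000L, 48000L), 3, 3)
  p <- file.path(d, "deep.tif")
  tiff::writeTIFF(raw16 / 65535, p, bits.per.sample = 16L)
  m <- load_micrograph(p, 1)
  expect_equal(max(m$pixels), 255L)
  expect_equal(m$pixels[1:3, 1:3],
               matrix(as.integer(round(raw16[1:3, 1:3] / 48000 * 255)), 3, 3))
})

test_that("rasterization matches the brute-force point-in-polygon oracle", {
  # three concentric axis-aligned squares of half-widths 30/20/10 about
  # (63, 63) on a 128x128 frame; boundary-inclusive pixel centres
  sq <- function(h) cbind(c(63 - h, 63 + h, 63 + h, 63 - h),
                          c(63 - h, 63 - h, 63 + h, 63 + h))
  ann <- region_annotation(sq(30), sq(20), sq(10))
  masks <- rasterize_annotation(ann, c(128L, 128L))
  expect_equal(sum(masks$inner), 21L^2)
  expect_equal(sum(masks$te), 41L^2 - 21L^2)
  expect_equal(sum(masks$zp), 61L^2 - 41L^2)

  # property: agreement with the oracle on random star-shaped polygons
  for (seed in 1:3) {
    set.seed(seed)
    nv <- sample(5:40, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 8, 30)
    poly <- cbind(40 + rad * cos(ang), 40 + rad * sin(ang))
    got <- blastometry:::rasterize_polygon_cpp(poly, 80L, 80L)
    expect_identical(got, oracle_rasterize(poly, 80L, 80L))
  }
})

test_that("invalid annotations are rejected with the offending boundary named", {
  sq <- function(h) cbind(c(63 - h, 63 + h, 63 + h, 63 - h),
                          c(63 - h, 63 - h, 63 + h, 63 + h))
  # identical ZP/TE and TE/inner boundaries -> empty trophectoderm annulus
  expect_error(rasterize_annotation(region_annotation(sq(30), sq(20), sq(20)),
                                    c(128L, 128L)),
               "trophectoderm")
  # self-intersecting bow-tie
  bow <- cbind(c(10, 50, 10, 50), c(10, 50, 50, 10))
  expect_error(region_annotation(sq(30), sq(20), bow), "self-intersecting")
  # non-nested
  far <- sq(10) + 100
  expect_error(region_annotation(sq(30), far, sq(5)), "nested")
})

test_that("annotation JSON and mask PNG round-trip exactly", {
  sq <- function(h) cbind(c(63 - h, 63 + h, 63 + h, 63 - h),
                          c(63 - h, 63 - h, 63 + h, 63 + h))
  ann <- region_annotation(sq(30), sq(20), sq(10))
  d <- withr::local_tempdir()
  f <- file.path(d, "ann.json")
  write_annotation_json(ann, f)
  ann2 <- read_annotation_json(f)
  expect_equal(unclass(ann2), unclass(ann), tolerance = 1e-12)

  s <- generate_phantom(tiny_spec(), seed = 3)
  fm <- file.path(d, "mask.png")
  write_mask_png(s$masks, fm)
  expect_identical(read_mask_png(fm), s$masks)
})

test_that("b-hCG labelling thresholds at exactly 20 mUI/mL", {
  expect_identical(label_outcome(20), 1L)
  expect_identical(label_outcome(19.99), 0L)
  expect_identical(label_outcome(0), 0L)
  expect_identical(label_outcome(c(0, 19.99, 20, 350)), c(0L, 0L, 1L, 1L))
  expect_error(label_outcome(-1), "negative")
  # monotone non-decreasing in concentration
  x <- sort(runif(50, 0, 40))
  expect_true(all(diff(label_outcome(x)) >= 0))
})

test_that("load_cohort round-trips a phantom cohort with ground-truth labels", {
  d <- withr::local_tempdir()
  spec <- tiny_spec()
  coh <- generate_cohort(spec, 6, seed = 13, dir = d)
  entries <- load_cohort(file.path(d, "manifest.csv"))
  expect_length(entries, 6L)
  for (i in seq_along(entries)) {
    expect_identical(entries[[i]]$micrograph$pixels,
                     coh$samples[[i]]$micrograph$pixels)
    expect_identical(entries[[i]]$masks, coh$samples[[i]]$masks)
    expect_identical(entries[[i]]$record$label,
                     label_outcome(as.numeric(coh$samples[[i]]$bhcg_mUI_per_mL)))
  }
  # labels come from thresholding the manifest's b-hCG column
  man <- read.csv(file.path(d, "manifest.csv"))
  expect_identical(vapply(entries, function(e) e$record$label, integer(1)),
                   label_outcome(man$bhcg_mUI_per_mL))
})

test_that("manifest validation reports the offending row", {
  d <- withr::local_tempdir()
  generate_cohort(tiny_spec(), 3, seed = 1, dir = d)
  man <- read.csv(file.path(d, "manifest.csv"))
  man$image_path[2] <- "images/nonexistent.png"
  write.csv(man, file.path(d, "manifest.csv"), row.names = FALSE)
  expect_error(load_cohort(file.path(d, "manifest.csv")), "row 2")

  man$image_path[2] <- man$image_path[1]
  man$sample_id[2] <- man$sample_id[1]
  write.csv(man, file.path(d, "manifest.csv"), row.names = FALSE)
  expect_error(load_cohort(file.path(d, "manifest.csv")), "duplicate")

  write.csv(man[, setdiff(names(man), "mask_path")],
            file.path(d, "manifest.csv"), row.names = FALSE)
  expect_error(load_cohort(file.path(d, "manifest.csv")), "mask_path")
})
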