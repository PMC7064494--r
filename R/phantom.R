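#' Specification of the synthetic blastocyst phantom
#'
#' The phantom emulates the structure of a day 5-6 blastocyst micrograph:
#' three nested, concentric elliptical regions (zona pellucida annulus,
#' trophectoderm annulus, inner area) on a darker background, each region
#' rendered as its mean intensity plus Gaussian-smoothed white noise. Two
#' calibration regimes stand in for 20x and 40x objectives. A logistic model
#' on per-sample latent values (zona pellucida thickness, trophectoderm
#' texture SD, patient age, all z-scored against their nominal
#' distributions) drives the b-hCG outcome.
#'
#' @param embryo_diameter_um nominal embryo diameter (um); blastocysts are
#'   about 180 um across at transfer.
#' @param zp_thickness_um,te_thickness_um nominal zona pellucida and
#'   trophectoderm thickness (um).
#' @param eccentricity maximum ellipse eccentricity in \[0, 1).
#' @param calibration named numeric vector of um/px for the two objective
#'   regimes.
#' @param image_size optional named list of `c(rows, cols)` per regime;
#'   computed from the geometry when `NULL`.
#' @param region_texture named list (`background`, `inner`, `te`, `zp`) of
#'   lists with `mean` (0-255), `sd` (noise SD, >= 0) and `smooth`
#'   (Gaussian smoothing length, px).
#' @param age_mean_years,age_sd_years patient-age distribution (years).
#' @param prevalence_target fraction of positive outcomes the logistic
#'   intercept is set to (at zero latent effect).
#' @param outcome_coeffs named coefficients on the z-scored latents
#'   (`zp_thickness`, `te_texture_sd`, `age`); may include an `intercept`
#'   overriding `prevalence_target`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(embryo_diameter_um = 180,
                         zp_thickness_um = 18,
                         te_thickness_um = 20,
                         eccentricity = 0.15,
                         calibration = c("20x" = 1.0, "40x" = 0.5),
                         image_size = NULL,
                         region_texture = list(
                           background = list(mean = 40, sd = 6, smooth = 2),
                           inner = list(mean = 150, sd = 8, smooth = 2),
                           te = list(mean = 110, sd = 14, smooth = 2),
                           zp = list(mean = 190, sd = 10, smooth = 2)),
                         age_mean_years = 34.4,
                         age_sd_years = 5.5,
                         prevalence_target = 0.5298,
                         outcome_coeffs = c(zp_thickness = 0.8,
                                            te_texture_sd = 0.8,
                                            age = -0.8)) {
  if (zp_thickness_um + te_thickness_um >= embryo_diameter_um / 2)
    stop("zp_thickness_um + te_thickness_um must be < embryo_diameter_um / 2")
  if (eccentricity < 0 || eccentricity >= 1)
    stop("eccentricity must be in [0, 1)")
  if (any(calibration <= 0)) stop("calibration values must be positive")
  if (is.null(names(calibration)) || anyDuplicated(names(calibration)))
    stop("calibration must be a uniquely named vector (one entry per regime)")
  for (nm in names(region_texture)) {
    tx <- region_texture[[nm]]
    if (tx$sd < 0) stop("noise SD for region '", nm, "' must be >= 0")
    if (tx$mean < 0 || tx$mean > 255)
      stop("mean intensity for region '", nm, "' must be in [0, 255]")
  }
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stop("prevalence_target must be in (0, 1)")
  if (!"intercept" %in% names(outcome_coeffs))
    outcome_coeffs <- c(intercept = unname(qlogis(prevalence_target)),
                        outcome_coeffs)
  if (is.null(image_size)) {
    image_size <- lapply(calibration, function(mpp)
      rep(32L * ceiling(1.35 * embryo_diameter_um / mpp / 32), 2L))
    names(image_size) <- names(calibration)
  }
  for (nm in names(calibration)) {
    max_radius_px <- 1.1 * embryo_diameter_um / 2 / calibration[[nm]]
    if (2 * max_radius_px + 4 > min(image_size[[nm]]))
      stop("embryo does not fit the ", paste(image_size[[nm]], collapse = "x"),
           " frame at ", calibration[[nm]], " um/px")
  }
  structure(
    list(embryo_diameter_um = embryo_diameter_um,
         zp_thickness_um = zp_thickness_um,
         te_thickness_um = te_thickness_um,
         eccentricity = eccentricity,
         calibration = calibration,
         image_size = image_size,
         region_texture = region_texture,
         age_mean_years = age_mean_years,
         age_sd_years = age_sd_years,
         prevalence_target = prevalence_target,
         outcome_coeffs = outcome_coeffs),
    class = "phantom_spec")
}

# Smoothed-noise texture field with unit variance (renormalized after
# smoothing so the requested SD is the realized SD).
texture_field <- function(nr, nc, smooth) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (smooth > 0) {
    z <- gaussian_blur_cpp(z, smooth)
    s <- sd(as.vector(z))
    if (s > 0) z <- z / s
  }
  z
}

#' Generate one synthetic blastocyst sample
#'
#' Deterministic for a fixed `(spec, seed)` pair. Per-sample geometry
#' (diameter, layer thicknesses, eccentricity, orientation) and age are
#' drawn around the spec's nominal values; the b-hCG outcome is drawn from
#' the spec's logistic model via [assign_outcome()].
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @param objective which calibration regime to render (name into
#'   `spec$calibration`).
#' @param sample_id sample identifier.
#' @return An object of class `phantom_sample`: list with `micrograph`,
#'   `masks`, `age_years`, `bhcg_mUI_per_mL`, `latent`, `objective`,
#'   `geometry` (the generating ellipse parameters, for ground-truth
#'   checks) and `seed_used`.
#' @export
generate_phantom <- function(spec, seed, objective = names(spec$calibration)[1],
                             sample_id = sprintf("phantom_%06d", seed)) {
  stopifnot(inherits(spec, "phantom_spec"))
  objective <- match.arg(objective, names(spec$calibration))
  mpp <- spec$calibration[[objective]]
  sz <- spec$image_size[[objective]]
  nr <- sz[1]; nc <- sz[2]
  with_seed(seed, {
    # latent draws (truncated at 2 SD so geometry always fits the frame)
    trunc2 <- function(mean, sd) mean + max(-2, min(2, rnorm(1))) * sd
    diam <- trunc2(spec$embryo_diameter_um, 0.03 * spec$embryo_diameter_um)
    zp_t <- trunc2(spec$zp_thickness_um, 0.15 * spec$zp_thickness_um)
    te_t <- trunc2(spec$te_thickness_um, 0.10 * spec$te_thickness_um)
    te_sd_nom <- spec$region_texture$te$sd
    te_sd <- if (te_sd_nom > 0) max(0.1, trunc2(te_sd_nom, 0.2 * te_sd_nom))
             else 0
    age <- spec$age_mean_years + max(-3, min(3, rnorm(1))) * spec$age_sd_years
    age <- min(max(age, 18), 50)
    ecc <- runif(1, 0, spec$eccentricity)
    theta <- runif(1, 0, pi)

    a0 <- diam / 2 / mpp                 # semi-major axis, px
    b0 <- a0 * sqrt(1 - ecc^2)
    if (2 * a0 + 4 > min(nr, nc))
      stop("phantom geometry does not fit the ", nr, "x", nc, " frame")
    zp_px <- zp_t / mpp
    te_px <- te_t / mpp
    cx <- (nc - 1) / 2; cy <- (nr - 1) / 2

    xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc) - cx
    ys <- matrix(rep(0:(nr - 1), nc), nr, nc) - cy
    u <- xs * cos(theta) + ys * sin(theta)
    v <- -xs * sin(theta) + ys * cos(theta)
    rad <- function(a, b) (u / a)^2 + (v / b)^2
    in_outer <- rad(a0, b0) <= 1
    in_mid <- rad(a0 - zp_px, b0 - zp_px) <= 1
    in_inner <- rad(a0 - zp_px - te_px, b0 - zp_px - te_px) <= 1
    masks <- region_masks(zp = in_outer & !in_mid,
                          te = in_mid & !in_inner,
                          inner = in_inner)

    tx <- spec$region_texture
    tx$te$sd <- te_sd                    # realized trophectoderm texture
    img <- matrix(tx$background$mean, nr, nc) +
      tx$background$sd * texture_field(nr, nc, tx$background$smooth)
    for (nm in c("inner", "te", "zp")) {
      reg <- masks[[nm]]
      field <- tx[[nm]]$mean +
        tx[[nm]]$sd * texture_field(nr, nc, tx[[nm]]$smooth)
      img[reg] <- field[reg]
    }
    img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), nr, nc)

    latent <- c(
      zp_thickness = (zp_t - spec$zp_thickness_um) /
        (0.15 * spec$zp_thickness_um),
      te_texture_sd = if (te_sd_nom > 0)
        (te_sd - te_sd_nom) / (0.2 * te_sd_nom) else 0,
      age = (age - spec$age_mean_years) / spec$age_sd_years)
    bhcg <- assign_outcome(latent, spec$outcome_coeffs,
                           seed = derive_seed(seed, 7L))
    structure(
      list(micrograph = micrograph(img, mpp, sample_id),
           masks = masks,
           age_years = age,
           bhcg_mUI_per_mL = bhcg,
           latent = latent,
           objective = objective,
           geometry = list(cx = cx, cy = cy, a = a0, b = b0,
                           zp_px = zp_px, te_px = te_px, theta = theta,
                           diameter_um = diam, zp_thickness_um = zp_t,
                           te_thickness_um = te_t),
           seed_used = seed),
      class = "phantom_sample")
  })
}

#' Draw a b-hCG outcome from the logistic latent model
#'
#' The positive-outcome probability is
#' `plogis(intercept + sum(coeffs * latent))`; positives receive a lognormal
#' b-hCG concentration above the 20 mUI/mL decision threshold, negatives a
#' concentration below it.
#'
#' @param latent named numeric vector of latent values.
#' @param coeffs named coefficients; names other than `intercept` must occur
#'   in `latent`.
#' @param seed integer seed.
#' @return b-hCG concentration (mUI/mL) with attribute `prob`, the positive
#'   probability used.
#' @export
assign_outcome <- function(latent, coeffs, seed) {
  slope <- coeffs[setdiff(names(coeffs), "intercept")]
  unknown <- setdiff(names(slope), names(latent))
  if (length(unknown))
    stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "))
  eta <- sum(c(coeffs["intercept"], 0), na.rm = TRUE) +
    sum(slope * latent[names(slope)])
  p <- plogis(eta)
  with_seed(seed, {
    positive <- runif(1) < p
    bhcg <- if (positive) 20 + rlnorm(1, meanlog = log(80), sdlog = 0.7)
            else 20 * rbeta(1, 1.2, 5)
    structure(bhcg, prob = p)
  })
}

#' Generate a synthetic cohort
#'
#' Draws `n` independent phantom samples with per-sample seeds derived from
#' the master seed, split across the spec's two calibration regimes. When
#' `dir` is given, images and label masks are written as 8-bit grayscale
#' PNGs and a manifest CSV in the layout read back by [load_cohort()].
#'
#' @param spec a [phantom_spec()].
#' @param n number of samples (>= 1).
#' @param seed master seed.
#' @param objective_counts named integer vector of samples per calibration
#'   regime (must sum to `n`); defaults to a 90:44 split rounded to `n`.
#' @param positives optional exact number of positive outcomes. When set,
#'   samples are drawn from the same generative model but accepted against
#'   the outcome quota, emulating a cohort with a known class balance (a
#'   retrospective cohort reports its observed counts); when `NULL`
#'   (default) the positive count is binomial around the logistic model's
#'   mean.
#' @param dir optional output directory.
#' @return A list with `samples` (list of `phantom_sample`) and `manifest`
#'   (data frame); when `dir` is given the manifest's paths are relative to
#'   `dir` and `manifest.csv` is written there.
#' @export
generate_cohort <- function(spec, n, seed, objective_counts = NULL,
                            positives = NULL, dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive count")
  n <- as.integer(n)
  regimes <- names(spec$calibration)
  if (is.null(objective_counts)) {
    n1 <- round(n * 90 / 134)
    objective_counts <- setNames(c(n1, n - n1), regimes[1:2])
  }
  if (!setequal(names(objective_counts), regimes) ||
      sum(objective_counts) != n)
    stop("objective_counts must name every calibration regime and sum to n")
  obj_by_sample <- rep(names(objective_counts), objective_counts)
  if (!is.null(positives)) {
    positives <- as.integer(positives)
    if (positives < 0L || positives > n)
      stop("`positives` must be between 0 and n")
  }
  quota <- c(neg = if (is.null(positives)) n else n - positives,
             pos = if (is.null(positives)) n else positives)

  samples <- vector("list", n)
  rows <- vector("list", n)
  attempt <- 0L
  for (i in seq_len(n)) {
    sid <- sprintf("sample_%04d", i)
    repeat {
      attempt <- attempt + 1L
      if (attempt > 60L * n)
        stop("could not satisfy the positive-count quota; outcome model ",
             "too one-sided")
      s <- generate_phantom(spec, seed = derive_seed(seed, attempt),
                            objective = obj_by_sample[i], sample_id = sid)
      cls <- if (label_outcome(as.numeric(s$bhcg_mUI_per_mL)) == 1L) "pos"
             else "neg"
      if (quota[[cls]] > 0L) {
        quota[[cls]] <- quota[[cls]] - 1L
        break
      }
    }
    samples[[i]] <- s
    rows[[i]] <- data.frame(
      sample_id = sid,
      image_path = file.path("images", paste0(sid, ".png")),
      mask_path = file.path("masks", paste0(sid, "_mask.png")),
      age_years = s$age_years,
      microns_per_pixel = s$micrograph$microns_per_pixel,
      objective = s$objective,
      bhcg_mUI_per_mL = as.numeric(s$bhcg_mUI_per_mL),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_micrograph(samples[[i]]$micrograph,
                       file.path(dir, manifest$image_path[i]))
      write_mask_png(samples[[i]]$masks, file.path(dir, manifest$mask_path[i]))
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}
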