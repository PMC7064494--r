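#' Names and units of the 24 morphometric features
#'
#' Eight metrics are computed independently for each of the three annotated
#' regions (zona pellucida `zp`, trophectoderm `te`, inner area `inner`):
#' area (um^2), perimeter (um), mean and SD of the raw 8-bit intensity,
#' mean and SD of the local-entropy map (bits), Canny edge length (um) and
#' edge density (1/um).
#'
#' @return `feature_names()`: character vector of the 24 feature names, in
#'   canonical order. `feature_units()`: named character vector of units.
#' @export
feature_names <- function() {
  metrics <- c("area", "perimeter", "mean_intensity", "sd_intensity",
               "mean_entropy", "sd_entropy", "edge_length", "edge_density")
  as.vector(vapply(c("zp", "te", "inner"),
                   function(r) paste0(metrics, "_", r), character(8)))
}

#' @rdname feature_names
#' @export
feature_units <- function() {
  units <- c(area = "um^2", perimeter = "um", mean_intensity = "intensity",
             sd_intensity = "intensity", mean_entropy = "bits",
             sd_entropy = "bits", edge_length = "um", edge_density = "1/um")
  nm <- feature_names()
  setNames(units[sub("_(zp|te|inner)$", "", nm)], nm)
}

default_config <- function() {
  list(entropy_radius_px = 9L,
       canny_sigma = 1.0,
       canny_percentiles = c(0.6, 0.9),
       target_um_per_px = 1.0)
}

#' Resample a micrograph to a target calibration
#'
#' Bilinear resampling of the image (nearest-neighbour for masks) so that
#' one pixel corresponds to `target` micrometres; physical geometry is
#' preserved within resampling tolerance. Texture and edge statistics are
#' computed at a common calibration so they are comparable across the 20x
#' and 40x acquisition regimes.
#'
#' @param m a [micrograph()].
#' @param target target calibration (um/px, > 0).
#' @param masks optional [region_masks()] co-registered with `m`.
#' @return When `masks` is `NULL`, the resampled [micrograph()]; otherwise a
#'   list with `micrograph` and `masks`.
#' @export
normalize_resolution <- function(m, target = 1.0, masks = NULL) {
  stopifnot(inherits(m, "micrograph"))
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("`target` must be a single positive number")
  if (isTRUE(all.equal(m$microns_per_pixel, target))) {
    return(if (is.null(masks)) m else list(micrograph = m, masks = masks))
  }
  f <- m$microns_per_pixel / target
  nr <- max(1L, as.integer(round(nrow(m$pixels) * f)))
  nc <- max(1L, as.integer(round(ncol(m$pixels) * f)))
  px <- resize_bilinear_cpp(m$pixels + 0.0, nr, nc)
  px <- matrix(as.integer(pmin(pmax(round(px), 0), 255)), nr, nc)
  m2 <- micrograph(px, target, m$sample_id)
  if (is.null(masks)) return(m2)
  lab <- resize_nearest_cpp(masks_to_label(masks), nr, nc)
  list(micrograph = m2, masks = label_to_masks(lab))
}

#' Local-entropy texture map
#'
#' Each output pixel holds the Shannon entropy (base 2, bits) of the 256-bin
#' intensity histogram over the disk neighbourhood of the given radius,
#' restricted to pixels inside the frame. Values lie in \[0, 8\] bits and are
#' zero exactly when the neighbourhood is constant.
#'
#' @param m a [micrograph()].
#' @param radius disk radius in pixels (>= 1, at most half the smaller image
#'   extent).
#' @return Numeric matrix of entropies, same shape as the image.
#' @export
local_entropy_map <- function(m, radius = 9L) {
  stopifnot(inherits(m, "micrograph"))
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be >= 1")
  if (radius > min(dim(m$pixels)) / 2)
    stop("`radius` (", radius, ") exceeds half the image extent")
  entropy_filter_cpp(m$pixels, radius)
}

#' Canny edge detection
#'
#' Standard Canny: Gaussian smoothing, Sobel gradient, non-maximum
#' suppression and hysteresis thresholding. By default the hysteresis
#' thresholds adapt per image to percentiles of the gradient magnitude,
#' since acquisition settings (illumination, camera) vary across
#' micrographs.
#'
#' @param m a [micrograph()].
#' @param sigma Gaussian smoothing SD in pixels (> 0).
#' @param low,high explicit hysteresis thresholds on gradient magnitude
#'   (`0 <= low < high`); when `NULL`, taken from `percentiles`.
#' @param percentiles two gradient-magnitude percentiles used for the
#'   adaptive thresholds.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(m, sigma = 1.0, low = NULL, high = NULL,
                        percentiles = c(0.6, 0.9)) {
  stopifnot(inherits(m, "micrograph"))
  if (sigma <= 0) stop("`sigma` must be positive")
  sm <- gaussian_blur_cpp(m$pixels + 0.0, sigma)
  g <- sobel_gradient_cpp(sm)
  if (is.null(low) || is.null(high)) {
    q <- quantile(g$mag, percentiles, names = FALSE)
    low <- q[1]; high <- q[2]
    if (high <= 0)  # flat image: no gradient support at all
      return(matrix(FALSE, nrow(sm), ncol(sm)))
    if (low >= high) low <- high / 2
  }
  if (low < 0 || low >= high)
    stop("invalid Canny thresholds: need 0 <= low < high, got low = ", low,
         ", high = ", high)
  canny_nms_hysteresis_cpp(g$mag, g$gx, g$gy, low, high)
}

# Perimeter of a binary mask: length of its longest marching-squares contour
# (the outer boundary), via grDevices::contourLines on a zero-padded grid.
mask_perimeter_px <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- mask
  cl <- contourLines(x = 0:(nr + 1L), y = 0:(nc + 1L), z = z, levels = 0.5)
  if (!length(cl)) return(0)
  max(vapply(cl, function(cc) {
    xs <- c(cc$x, cc$x[1]); ys <- c(cc$y, cc$y[1])
    sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }, numeric(1)))
}

#' Region geometry in micrometres
#'
#' Area is the pixel count scaled by the squared calibration; perimeter is
#' the length of the region's outer marching-squares contour scaled by the
#' calibration.
#'
#' @param masks a [region_masks()].
#' @param microns_per_pixel calibration (um/px).
#' @return Named list with `area` and `perimeter`, each a named numeric
#'   vector over `zp`, `te`, `inner` (um^2 and um).
#' @export
region_geometry <- function(masks, microns_per_pixel) {
  stopifnot(inherits(masks, "region_masks"), microns_per_pixel > 0)
  regions <- c("zp", "te", "inner")
  for (r in regions)
    if (!any(masks[[r]])) stop("region '", r, "' is empty")
  area <- vapply(regions, function(r)
    sum(masks[[r]]) * microns_per_pixel^2, numeric(1))
  perimeter <- vapply(regions, function(r)
    mask_perimeter_px(masks[[r]]) * microns_per_pixel, numeric(1))
  list(area = area, perimeter = perimeter)
}

#' Extract the 24-element morphometric feature vector
#'
#' Geometry (area, perimeter) is computed at the native calibration;
#' intensity statistics are taken from the native image; the local-entropy
#' map and Canny edges are computed after resampling image and masks to the
#' common `target_um_per_px` calibration so texture scales are comparable
#' across objectives. Edge length is the count of Canny edge pixels inside a
#' region converted to micrometres, and edge density is edge length divided
#' by region area.
#'
#' @param m a [micrograph()].
#' @param masks a [region_masks()] on the same grid.
#' @param config list of tuning parameters; see [default_config()] source
#'   for keys (`entropy_radius_px`, `canny_sigma`, `canny_percentiles`,
#'   `target_um_per_px`).
#' @return Named numeric vector of exactly 24 finite values in the order of
#'   [feature_names()], with a `units` attribute.
#' @export
extract_features <- function(m, masks, config = default_config()) {
  stopifnot(inherits(m, "micrograph"), inherits(masks, "region_masks"))
  if (!identical(dim(m$pixels), dim(masks$zp)))
    stop("micrograph and masks do not share a pixel grid (sample '",
         m$sample_id, "')")
  cfg <- utils::modifyList(default_config(), config)
  regions <- c("zp", "te", "inner")
  geom <- region_geometry(masks, m$microns_per_pixel)

  nrm <- normalize_resolution(m, cfg$target_um_per_px, masks)
  ent <- local_entropy_map(nrm$micrograph, cfg$entropy_radius_px)
  edges <- canny_edges(nrm$micrograph, sigma = cfg$canny_sigma,
                       percentiles = cfg$canny_percentiles)

  out <- numeric(0)
  for (r in regions) {
    reg_native <- masks[[r]]
    reg_norm <- nrm$masks[[r]]
    if (!any(reg_norm))
      stop("region '", r, "' is empty after resolution normalization ",
           "(sample '", m$sample_id, "')")
    px <- m$pixels[reg_native]
    ev <- ent[reg_norm]
    edge_len <- sum(edges & reg_norm) * cfg$target_um_per_px
    vals <- c(geom$area[[r]], geom$perimeter[[r]],
              mean(px), if (length(px) > 1) sd(px) else 0,
              mean(ev), if (length(ev) > 1) sd(ev) else 0,
              edge_len, edge_len / geom$area[[r]])
    out <- c(out, vals)
  }
  out <- setNames(out, feature_names())
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite feature(s) ", paste(names(out)[bad], collapse = ", "),
         " for sample '", m$sample_id, "'")
  attr(out, "units") <- feature_units()
  out
}

# Normalize the two cohort shapes (generate_cohort output or load_cohort
# entries) into a common entry list.
as_cohort_entries <- function(cohort) {
  if (is.list(cohort) && !is.null(cohort$samples)) cohort <- cohort$samples
  lapply(cohort, function(e) {
    if (inherits(e, "phantom_sample")) {
      list(micrograph = e$micrograph, masks = e$masks,
           record = list(sample_id = e$micrograph$sample_id,
                         age_years = e$age_years,
                         label = label_outcome(as.numeric(e$bhcg_mUI_per_mL))))
    } else if (!is.null(e$micrograph) && !is.null(e$masks) &&
               !is.null(e$record)) {
      e
    } else {
      stop("unrecognized cohort entry; expected phantom samples or ",
           "load_cohort() entries")
    }
  })
}

#' Build the cohort feature table
#'
#' Runs [extract_features()] on every cohort entry and assembles the feature
#' table consumed by [fit_reduction()] and [cross_validate()]: sample id,
#' the 24 features, patient age and the binary outcome label.
#'
#' @param cohort output of [generate_cohort()] or [load_cohort()].
#' @param config see [extract_features()].
#' @return Data frame with columns `sample_id`, the 24 features,
#'   `age_years`, `label`.
#' @export
extract_feature_table <- function(cohort, config = default_config()) {
  entries <- as_cohort_entries(cohort)
  rows <- lapply(entries, function(e) {
    fv <- extract_features(e$micrograph, e$masks, config)
    cbind(data.frame(sample_id = e$record$sample_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)),
          data.frame(age_years = e$record$age_years,
                     label = as.integer(e$record$label)))
  })
  do.call(rbind, rows)
}
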