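#' Region masks for the three annotated blastocyst regions
#'
#' Holds three pairwise-disjoint logical pixel masks over the image grid:
#' `zp` (zona pellucida annulus), `te` (trophectoderm annulus) and `inner`
#' (blastocoel plus inner cell mass).
#'
#' @param zp,te,inner logical matrices of identical dimensions.
#' @return An object of class `region_masks`.
#' @export
region_masks <- function(zp, te, inner) {
  ms <- list(zp = zp, te = te, inner = inner)
  for (nm in names(ms)) {
    if (!is.matrix(ms[[nm]]) || !is.logical(ms[[nm]]))
      stop("mask '", nm, "' must be a logical matrix")
  }
  d <- dim(zp)
  if (!identical(d, dim(te)) || !identical(d, dim(inner)))
    stop("region masks must share dimensions")
  if (any(zp & te) || any(zp & inner) || any(te & inner))
    stop("region masks must be pairwise disjoint")
  structure(ms, class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf("<region_masks %d x %d px: zp=%d, te=%d, inner=%d pixels>\n",
              nrow(x$zp), ncol(x$zp), sum(x$zp), sum(x$te), sum(x$inner)))
  invisible(x)
}

# Label encoding shared with the phantom writer:
# 0 = background, 1 = inner, 2 = trophectoderm, 3 = zona pellucida.
masks_to_label <- function(masks) {
  lab <- matrix(0L, nrow(masks$zp), ncol(masks$zp))
  lab[masks$inner] <- 1L
  lab[masks$te] <- 2L
  lab[masks$zp] <- 3L
  lab
}

label_to_masks <- function(label) {
  if (!all(label %in% 0:3))
    stop("label mask values must be in {0, 1, 2, 3}")
  region_masks(zp = label == 3L, te = label == 2L, inner = label == 1L)
}

#' Read / write a label-mask PNG
#'
#' Masks are stored as single-channel 8-bit PNGs with labels
#' 0 = background, 1 = inner area, 2 = trophectoderm, 3 = zona pellucida.
#'
#' @param masks a [region_masks()] object.
#' @param path file path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a [region_masks()].
#' @export
write_mask_png <- function(masks, path) {
  stopifnot(inherits(masks, "region_masks"))
  png::writePNG(masks_to_label(masks) / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  arr <- to_gray(png::readPNG(path), path)
  label_to_masks(matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr)))
}

# ---- polygon annotations ----------------------------------------------------

as_polygon <- function(p, name) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L)
    stop("boundary '", name, "' must be an n x 2 matrix with n >= 3")
  if (anyNA(p) || !all(is.finite(p)))
    stop("boundary '", name, "' contains non-finite coordinates")
  storage.mode(p) <- "double"
  unname(p)
}

#' Region annotation from three nested boundary polygons
#'
#' The three closed boundaries, in 0-based pixel coordinates (x = column,
#' y = row), are the zona pellucida outer boundary, the ZP/trophectoderm
#' interface and the trophectoderm/inner-area interface. They must be simple
#' (non-self-intersecting) and strictly nested.
#'
#' @param zp_outer,zp_te,te_inner n x 2 matrices of (x, y) vertices.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(zp_outer, zp_te, te_inner) {
  ann <- list(zp_outer = as_polygon(zp_outer, "zp_outer"),
              zp_te = as_polygon(zp_te, "zp_te"),
              te_inner = as_polygon(te_inner, "te_inner"))
  for (nm in names(ann)) {
    if (polygon_self_intersects(ann[[nm]]))
      stop("boundary '", nm, "' is self-intersecting")
  }
  check_nested(ann$zp_te, ann$zp_outer, "zp_te", "zp_outer")
  check_nested(ann$te_inner, ann$zp_te, "te_inner", "zp_te")
  structure(ann, class = "region_annotation")
}

# Segment-crossing test for non-adjacent edges; O(n^2), annotations are small.
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) break
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

# Ray-casting point-in-polygon for validation (vertices of the inner polygon
# must lie inside or on the outer one).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xs2 <- xs[c(2:n, 1L)]; ys2 <- ys[c(2:n, 1L)]
  vapply(seq_along(px), function(k) {
    # on-boundary points count as inside
    dx <- xs2 - xs; dy <- ys2 - ys
    len2 <- dx^2 + dy^2
    t <- pmin(pmax(ifelse(len2 > 0,
                          ((px[k] - xs) * dx + (py[k] - ys) * dy) / len2, 0),
                   0), 1)
    d2 <- (xs + t * dx - px[k])^2 + (ys + t * dy - py[k])^2
    if (any(d2 < 1e-12)) return(TRUE)
    crossings <- (ys > py[k]) != (ys2 > py[k])
    xi <- xs + (py[k] - ys) / (ys2 - ys) * (xs2 - xs)
    sum(crossings & px[k] < xi, na.rm = TRUE) %% 2L == 1L
  }, logical(1))
}

check_nested <- function(inner, outer, inner_name, outer_name) {
  ok <- point_in_polygon(inner[, 1], inner[, 2], outer)
  if (!all(ok))
    stop("boundary '", inner_name, "' is not nested inside '", outer_name,
         "' (", sum(!ok), " vertices outside)")
  invisible(TRUE)
}

#' Rasterize a polygon annotation into region masks
#'
#' Pixel membership is decided by point-in-polygon at the pixel centre
#' (0-based integer coordinates); centres exactly on a boundary count as
#' inside. The zona pellucida mask is the set between the outer boundary and
#' the ZP/TE interface; the trophectoderm mask between the ZP/TE and TE/inner
#' interfaces; the inner mask inside the TE/inner interface.
#'
#' @param ann a [region_annotation()] (or a list with elements `zp_outer`,
#'   `zp_te`, `te_inner`).
#' @param shape integer vector `c(rows, cols)` of the image grid.
#' @return A [region_masks()] object.
#' @export
rasterize_annotation <- function(ann, shape) {
  if (!inherits(ann, "region_annotation"))
    ann <- region_annotation(ann$zp_outer, ann$zp_te, ann$te_inner)
  stopifnot(length(shape) == 2L, all(shape >= 1))
  for (nm in names(ann)) {
    p <- ann[[nm]]
    if (min(p[, 1]) < 0 || max(p[, 1]) > shape[2] - 1 ||
        min(p[, 2]) < 0 || max(p[, 2]) > shape[1] - 1)
      stop("boundary '", nm, "' extends outside the ", shape[1], "x",
           shape[2], " frame")
  }
  a <- rasterize_polygon_cpp(ann$zp_outer, shape[1], shape[2])
  b <- rasterize_polygon_cpp(ann$zp_te, shape[1], shape[2])
  c_ <- rasterize_polygon_cpp(ann$te_inner, shape[1], shape[2])
  zp <- a & !b
  te <- b & !c_
  if (!any(te))
    stop("degenerate annotation: boundary 'zp_te' and 'te_inner' enclose ",
         "no trophectoderm pixels")
  if (!any(zp))
    stop("degenerate annotation: boundary 'zp_outer' and 'zp_te' enclose ",
         "no zona pellucida pixels")
  if (!any(c_))
    stop("degenerate annotation: boundary 'te_inner' encloses no pixels")
  region_masks(zp = zp, te = te, inner = c_)
}

#' Read / write polygon annotations as JSON
#'
#' The JSON dialect is an object with keys `zp_outer`, `zp_te` and
#' `te_inner`, each an array of `[x, y]` pixel coordinates.
#'
#' @param ann a [region_annotation()].
#' @param path file path.
#' @return `write_annotation_json` returns `path` invisibly;
#'   `read_annotation_json` returns a [region_annotation()].
#' @export
write_annotation_json <- function(ann, path) {
  stopifnot(inherits(ann, "region_annotation"))
  jsonlite::write_json(lapply(unclass(ann), unname), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("zp_outer", "zp_te", "te_inner")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("annotation JSON missing boundaries: ", paste(miss, collapse = ", "))
  region_annotation(obj$zp_outer, obj$zp_te, obj$te_inner)
}

# ---- outcome labelling and cohort manifests ---------------------------------

#' Binary pregnancy-test label from a b-hCG concentration
#'
#' Serum beta-hCG of at least 20 mUI/mL, measured seven days after embryo
#' transfer, defines a positive pregnancy test.
#'
#' @param bhcg numeric vector of concentrations (mUI/mL), all >= 0.
#' @return Integer vector of 0/1 labels (1 = positive).
#' @export
label_outcome <- function(bhcg) {
  if (!is.numeric(bhcg) || anyNA(bhcg))
    stop("`bhcg` must be numeric without missing values")
  if (any(bhcg < 0))
    stop("negative b-hCG concentration: ", min(bhcg))
  as.integer(bhcg >= 20)
}

manifest_columns <- c("sample_id", "image_path", "mask_path", "age_years",
                      "microns_per_pixel", "objective")

#' Load a cohort from a manifest CSV
#'
#' The manifest has columns `sample_id`, `image_path`, `mask_path`,
#' `age_years`, `microns_per_pixel`, `objective` and at least one of
#' `bhcg_mUI_per_mL` or `label`; paths are resolved relative to the
#' manifest's directory. When only b-hCG is present, labels are derived with
#' [label_outcome()].
#'
#' @param manifest_path path to the manifest CSV.
#' @return A list of cohort entries, each a list with elements `micrograph`,
#'   `masks` and `record` (the manifest row with a resolved `label`).
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  miss <- setdiff(manifest_columns, names(man))
  if (length(miss))
    stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (!any(c("bhcg_mUI_per_mL", "label") %in% names(man)))
    stop("manifest needs a 'bhcg_mUI_per_mL' or 'label' column")
  if (anyDuplicated(man$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(man$sample_id[duplicated(man$sample_id)]),
               collapse = ", "))
  base <- dirname(normalizePath(manifest_path))
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    img_path <- file.path(base, row$image_path)
    msk_path <- file.path(base, row$mask_path)
    if (!file.exists(img_path))
      stop("manifest row ", i, " ('", row$sample_id, "'): image not found: ",
           row$image_path)
    if (!file.exists(msk_path))
      stop("manifest row ", i, " ('", row$sample_id, "'): mask not found: ",
           row$mask_path)
    if (!is.finite(row$age_years) || row$age_years <= 10 ||
        row$age_years >= 60)
      stop("manifest row ", i, ": age_years out of range (10, 60): ",
           row$age_years)
    label <- if ("label" %in% names(man) && !is.na(row$label))
      as.integer(row$label)
    else label_outcome(row$bhcg_mUI_per_mL)
    rec <- as.list(row)
    rec$label <- label
    list(micrograph = load_micrograph(img_path, row$microns_per_pixel,
                                      row$sample_id),
         masks = read_mask_png(msk_path),
         record = rec)
  })
}
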