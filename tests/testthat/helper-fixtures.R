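# Shared fixtures and independent oracles for the test suite.

# A scaled-down phantom (60 um embryo) for fast unit tests; the full-size
# defaults are exercised in test-acceptance.R.
tiny_spec <- function(...) {
  phantom_spec(embryo_diameter_um = 60,
               zp_thickness_um = 7,
               te_thickness_um = 8,
               ...)
}

# Brute-force point-in-polygon oracle: ray casting written independently of
# the package path, boundary points counted inside via segment distance.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary: distance from point to segment
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    t <- if (len2 > 0) ((px - xi) * dx + (py - yi) * dy) / len2 else 0
    t <- min(max(t, 0), 1)
    if (sqrt((xi + t * dx - px)^2 + (yi + t * dy - py)^2) < 1e-9) return(TRUE)
    if ((yi > py) != (yj > py) &&
        px < xi + (py - yi) / (yj - yi) * (xj - xi)) inside <- !inside
    j <- i
  }
  inside
}

oracle_rasterize <- function(poly, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc))
      out[i, j] <- oracle_point_in_polygon(j - 1, i - 1, poly)
  out
}

# Direct histogram entropy (bits) over a disk neighbourhood of one pixel;
# independent arithmetic on the raw intensities.
oracle_entropy_at <- function(pixels, i, j, radius) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  vals <- c()
  for (a in -radius:radius)
    for (b in -radius:radius)
      if (a^2 + b^2 <= radius^2) {
        ii <- i + a; jj <- j + b
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
          vals <- c(vals, pixels[ii, jj])
      }
  p <- table(vals) / length(vals)
  -sum(p * log2(p))
}

# Exhaustive pairwise AUC oracle (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (s1 in pos)
    for (s0 in neg)
      total <- total + (s1 > s0) + 0.5 * (s1 == s0)
  total / (length(pos) * length(neg))
}

# Closed polygon approximating an ellipse, 0-based pixel coordinates.
ellipse_polygon <- function(cx, cy, a, b, theta = 0, n = 180) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- cx + a * cos(t) * cos(theta) - b * sin(t) * sin(theta)
  y <- cy + a * cos(t) * sin(theta) + b * sin(t) * cos(theta)
  cbind(x, y)
}

# Synthetic 24-feature table (no images) for classifier-level tests: every
# feature carries the class signal (`sep` noise-SD units), so the leading
# principal component aligns with it; sep = 0 gives pure noise. Returns a
# table in the layout of extract_feature_table().
toy_feature_table <- function(n, sep = 0, seed = 1, prevalence = 0.5) {
  withr_seed <- function(s, code) blastometry:::with_seed(s, code)
  withr_seed(seed, {
    label <- as.integer(runif(n) < prevalence)
    X <- matrix(rnorm(n * 24), n, 24) + sep * label
    colnames(X) <- feature_names()
    data.frame(sample_id = sprintf("s%03d", seq_len(n)), X,
               age_years = pmin(pmax(rnorm(n, 34.4, 5.5), 18), 50),
               label = label, check.names = FALSE)
  })
}
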