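# Landmark scheme: 20 points per fish in image coordinates (x right, y down,
# pixels) with a mm-per-pixel scale. The four polygon vertex cycles used by
# the morphological predictors; areas are absolute (shoelace), so the image
# y-axis convention never flips signs.
predictor_polygons <- list(
  head    = c(1, 2, 4, 5, 6),
  total   = c(1, 2, 4, 7, 12, 15, 18, 19, 16, 13, 10, 9, 6),
  caudal  = c(12, 15, 14, 13, 10, 11),
  ventral = c(3, 8, 11, 10, 9, 6, 5)
)

#' Packaged template landmark configuration
#'
#' A schematic 20-landmark left-side carp outline used as the base shape by
#' the synthetic-study generator. The coordinates are synthetic (no published
#' configuration exists); they are laid out in image convention (y increases
#' downward) so that all four predictor polygon cycles are simple
#' (non-self-intersecting), and ship with a declared scale of 0.5 mm/pixel.
#'
#' @return A 20 x 2 matrix of (x, y) pixel coordinates with attribute
#'   `"scale"` (mm per pixel).
#' @examples
#' tpl <- template_landmarks()
#' attr(tpl, "scale")
#' @export
template_landmarks <- function() {
  f <- system.file("extdata", "template_landmarks_synthetic.csv",
                   package = "carpyield", mustWork = TRUE)
  df <- read.csv(f)
  xy <- as.matrix(df[order(df$landmark), c("x", "y")])
  rownames(xy) <- df$landmark[order(df$landmark)]
  attr(xy, "scale") <- 0.5
  xy
}

#' Interlandmark distance
#'
#' Euclidean distance between two landmarks,
#' `sqrt((xB - xA)^2 + (yB - yA)^2)`, optionally converted to mm.
#'
#' @param a,b numeric length-2 points (x, y).
#' @param scale mm per pixel (default 1 = return pixel units).
#' @return Distance (scalar).
#' @examples
#' interlandmark_distance(c(0, 0), c(3, 4))  # 5
#' @export
interlandmark_distance <- function(a, b, scale = 1) {
  stopifnot(is.finite(a), is.finite(b), length(a) == 2, length(b) == 2)
  scale * sqrt(sum((b - a)^2))
}

#' Polygon area by the shoelace formula
#'
#' Absolute (orientation-independent) area of the polygon whose vertices are
#' the given landmark indices, in traversal order.
#'
#' @param vertices integer vector of landmark indices (a cycle; the closing
#'   edge back to the first vertex is implicit). At least 3 distinct vertices.
#' @param xy k x 2 landmark coordinate matrix.
#' @param scale mm per pixel; areas are returned in `scale^2` units (mm^2
#'   when a real scale is supplied).
#' @param check_simple if `TRUE`, error when the polygon self-intersects.
#' @return Area (scalar).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' polygon_area(1:4, sq)  # 1
#' @export
polygon_area <- function(vertices, xy, scale = 1, check_simple = FALSE) {
  if (length(unique(vertices)) < 3) stop("polygon needs >= 3 distinct vertices")
  p <- xy[vertices, , drop = FALSE]
  if (check_simple && !is_simple_polygon(p))
    stop("polygon (", paste(vertices, collapse = "-"), ") self-intersects")
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  scale^2 * abs(sum(x * yn - xn * y)) / 2
}

# Simple-polygon test: no two non-adjacent edges intersect.
is_simple_polygon <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  inter <- function(a, b) {
    d1 <- a[3:4] - a[1:2]; d2 <- b[3:4] - b[1:2]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)  # parallel; overlap treated as simple
    t <- ((b[1] - a[1]) * d2[2] - (b[2] - a[2]) * d2[1]) / den
    u <- ((b[1] - a[1]) * d1[2] - (b[2] - a[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent via the closing edge
      if (inter(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Morphological predictors P1-P5 from one landmark configuration
#'
#' Computes the predictor set used by the published yield-prediction models:
#' \itemize{
#'   \item `P1` head area (cycle 1-2-4-5-6) / total body area
#'     (1-2-4-7-12-15-18-19-16-13-10-9-6), dimensionless;
#'   \item `P2` ultrasound thickness E8 (mm) / distance between landmarks 8
#'     and 9 (mm), dimensionless;
#'   \item `P3` caudal part area (12-15-14-13-10-11) / ventral part area
#'     (3-8-11-10-9-6-5), dimensionless;
#'   \item `P4` body weight (g); `P5` muscle fat content (%).
#' }
#' The area ratios are invariant to image scale and translation; `P2` is in
#' consistent units only because the landmark height is converted to mm via
#' `scale`.
#'
#' @param xy 20 x 2 landmark matrix (pixels, image convention).
#' @param scale mm per pixel (> 0).
#' @param E8 ultrasound abdominal muscle thickness, mm.
#' @param BW body weight, g.
#' @param pct_fat muscle fat content, %.
#' @param check_simple validate the polygon cycles (default `TRUE`).
#' @return Named numeric vector `P1..P5` (plus `E8`).
#' @export
compute_predictors <- function(xy, scale, E8, BW = NA_real_, pct_fat = NA_real_,
                               check_simple = TRUE) {
  stopifnot(nrow(xy) == 20, scale > 0, is.finite(E8), E8 > 0)
  areas <- vapply(predictor_polygons, polygon_area, numeric(1),
                  xy = xy, scale = scale, check_simple = check_simple)
  h89 <- interlandmark_distance(xy[8, ], xy[9, ], scale = scale)
  if (h89 <= 0 || areas[["total"]] <= 0 || areas[["ventral"]] <= 0)
    stop("degenerate denominator (height 8-9 or polygon area) in landmark configuration")
  c(P1 = unname(areas[["head"]] / areas[["total"]]),
    P2 = unname(E8 / h89),
    P3 = unname(areas[["caudal"]] / areas[["ventral"]]),
    P4 = unname(BW), P5 = unname(pct_fat), E8 = unname(E8))
}

#' Predictor table for a whole study
#'
#' Applies [compute_predictors()] to every fish, joining the wide landmark
#' table (columns `id`, `x1,y1,...,x20,y20`, `scale_mm_per_px`) with the
#' phenotype table (for `E8`, `BW` and the mean fat reading).
#'
#' @param landmarks wide landmark data frame as written by [write_study()].
#' @param phenotypes phenotype data frame with columns `id`, `E8`, `BW` and
#'   either `pct_Fat` or `fat1..fat4`.
#' @return Data frame `id`, `P1..P5` plus raw ultrasound columns present in
#'   `phenotypes` (`E4`, `E5`, `E6`, `E8`, `E23`).
#' @export
predictor_table <- function(landmarks, phenotypes) {
  m <- match(landmarks$id, phenotypes$id)
  if (anyNA(m)) stop("landmark ids missing from phenotype table: ",
                     paste(head(landmarks$id[is.na(m)]), collapse = ", "))
  ph <- phenotypes[m, ]
  fat <- if ("pct_Fat" %in% names(ph)) ph$pct_Fat
         else rowMeans(ph[, c("fat1", "fat2", "fat3", "fat4")])
  xs <- as.matrix(landmarks[, paste0("x", 1:20)])
  ys <- as.matrix(landmarks[, paste0("y", 1:20)])
  out <- t(vapply(seq_len(nrow(landmarks)), function(i) {
    compute_predictors(cbind(xs[i, ], ys[i, ]), scale = landmarks$scale_mm_per_px[i],
                       E8 = ph$E8[i], BW = ph$BW[i], pct_fat = fat[i],
                       check_simple = FALSE)
  }, numeric(6)))
  res <- data.frame(id = landmarks$id, out[, c("P1", "P2", "P3", "P4", "P5")])
  for (e in intersect(c("E4", "E5", "E6", "E8", "E23"), names(ph))) res[[e]] <- ph[[e]]
  res
}

#' Generalized Procrustes superimposition
#'
#' Aligns a set of landmark configurations by removing translation (centering
#' on the centroid), size (scaling to unit centroid size) and rotation
#' (iterative least-squares rotation to the evolving consensus until the
#' consensus stabilises). Full Procrustes scaling is used; an optional
#' orthogonal projection into the tangent space at the consensus is available.
#'
#' @param configs list of k x 2 landmark matrices (equal k), or a 3-d array
#'   `k x 2 x n`.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param max_iter maximum number of alignment sweeps.
#' @param tangent if `TRUE`, project aligned shapes into the tangent space at
#'   the consensus.
#' @return List of class `carp_gpa`: `aligned` (k x 2 x n array), `consensus`
#'   (k x 2), `centroid_sizes`, `iterations`, `rss` (per-iteration residual
#'   sum of squares, non-increasing).
#' @export
procrustes_superimpose <- function(configs, tol = 1e-10, max_iter = 100,
                                   tangent = FALSE) {
  if (is.array(configs) && length(dim(configs)) == 3)
    configs <- lapply(seq_len(dim(configs)[3]), function(i) configs[, , i])
  n <- length(configs)
  stopifnot(n >= 2)
  k <- nrow(configs[[1]])
  if (!all(vapply(configs, nrow, 1L) == k))
    stop("all configurations must have the same landmark count")
  csize <- numeric(n)
  shapes <- vector("list", n)
  for (i in seq_len(n)) {
    p <- scale(configs[[i]], scale = FALSE)  # center
    csize[i] <- sqrt(sum(p^2))
    if (csize[i] <= 0) stop("degenerate configuration ", i, " (zero centroid size)")
    shapes[[i]] <- p / csize[i]
  }
  rotate_to <- function(p, target) {
    s <- svd(crossprod(target, p))
    R <- s$v %*% t(s$u)
    if (det(R) < 0) {  # keep proper rotations only
      s$v[, 2] <- -s$v[, 2]
      R <- s$v %*% t(s$u)
    }
    p %*% R
  }
  consensus <- shapes[[1]]
  rss <- numeric(0)
  for (it in seq_len(max_iter)) {
    shapes <- lapply(shapes, rotate_to, target = consensus)
    newcon <- Reduce(`+`, shapes) / n
    newcon <- newcon / sqrt(sum(newcon^2))
    delta <- sqrt(mean((newcon - consensus)^2))
    consensus <- newcon
    rss <- c(rss, sum(vapply(shapes, function(p) sum((p - consensus)^2), 1)))
    if (delta < tol && it > 1) break
  }
  if (it == max_iter && delta >= tol)
    stop("generalized Procrustes analysis did not converge in ", max_iter,
         " iterations (last change ", format(delta), ")")
  if (tangent) {
    v <- as.vector(consensus)
    shapes <- lapply(shapes, function(p) {
      x <- as.vector(p)
      matrix(v + (x - sum(x * v) * v), k, 2)
    })
  }
  aligned <- array(unlist(shapes), dim = c(k, 2, n))
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = csize, iterations = it, rss = rss),
            class = "carp_gpa")
}

#' @export
print.carp_gpa <- function(x, ...) {
  cat("Generalized Procrustes superimposition:",
      dim(x$aligned)[3], "configurations of", dim(x$aligned)[1], "landmarks;",
      x$iterations, "iterations, final RSS", format(tail(x$rss, 1)), "\n")
  invisible(x)
}

#' Regression of Procrustes shape on a covariate
#'
#' Regresses every aligned Procrustes coordinate on a single covariate
#' (e.g. a log-log residual yield trait), giving the shape-change vector per
#' unit covariate, the percentage of total shape variance predicted, and the
#' predicted landmark configurations at the observed covariate minimum and
#' maximum (the wireframe endpoints of a shape-change visualisation).
#'
#' @param gpa a [carp_gpa][procrustes_superimpose] object (or a k x 2 x n
#'   array of aligned coordinates).
#' @param covariate numeric vector, one value per configuration.
#' @return List of class `carp_shape_regression`: `coefficients` (k x 2
#'   shape-change per unit covariate), `pct_variance` (percentage of total
#'   Procrustes variance explained), `predicted_min`/`predicted_max`
#'   (k x 2 configurations at the covariate extremes), `covariate_range`.
#' @export
shape_covariate_regression <- function(gpa, covariate) {
  aligned <- if (inherits(gpa, "carp_gpa")) gpa$aligned else gpa
  n <- dim(aligned)[3]; k <- dim(aligned)[1]
  stopifnot(length(covariate) == n)
  if (sd(covariate) == 0) stop("constant covariate")
  Y <- t(apply(aligned, 3, as.vector))        # n x 2k
  Yc <- scale(Y, scale = FALSE)
  xc <- covariate - mean(covariate)
  beta <- colSums(Yc * xc) / sum(xc^2)        # per-coordinate slope
  fitted <- outer(xc, beta)
  pct <- 100 * sum(fitted^2) / sum(Yc^2)
  mshape <- colMeans(Y)
  at <- function(x0) matrix(mshape + (x0 - mean(covariate)) * beta, k, 2)
  structure(list(coefficients = matrix(beta, k, 2),
                 pct_variance = pct,
                 predicted_min = at(min(covariate)),
                 predicted_max = at(max(covariate)),
                 covariate_range = range(covariate)),
            class = "carp_shape_regression")
}

#' @export
print.carp_shape_regression <- function(x, ...) {
  cat("Shape-on-covariate regression:",
      sprintf("%.2f%% of shape variance predicted", x$pct_variance), "\n")
  invisible(x)
}
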