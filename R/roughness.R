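as_polygon_xy <- function(polygon) {
  if (inherits(polygon, "boundary_polygon") || is.data.frame(polygon)) {
    list(x = polygon$x, y = polygon$y)
  } else if (is.matrix(polygon)) {
    list(x = polygon[, 1], y = polygon[, 2])
  } else stop("polygon must be a boundary_polygon, data.frame or 2-column matrix")
}

#' Polygon area (shoelace formula)
#'
#' @param polygon a [boundary_polygon()], data.frame with `x`,`y`, or
#'   2-column matrix; closure implicit.
#' @return positive area irrespective of vertex orientation.
#' @export
polygon_area <- function(polygon) {
  p <- as_polygon_xy(polygon)
  n <- length(p$x)
  if (n < 3) stop("polygon needs >= 3 vertices")
  i2 <- c(2:n, 1)
  a <- abs(sum(p$x * p$y[i2] - p$x[i2] * p$y)) / 2
  if (a <= 0) stop("degenerate polygon: zero area")
  a
}

#' Polygon perimeter
#'
#' Sum of consecutive segment lengths including the closing segment.
#'
#' @inheritParams polygon_area
#' @return total boundary length.
#' @export
polygon_perimeter <- function(polygon) {
  p <- as_polygon_xy(polygon)
  n <- length(p$x)
  if (n < 3) stop("polygon needs >= 3 vertices")
  i2 <- c(2:n, 1)
  sum(sqrt((p$x[i2] - p$x)^2 + (p$y[i2] - p$y)^2))
}

# exact area-normalized central second moments of the polygon interior
# (Green's theorem closed forms); returns mu20, mu02, mu11 and centroid
polygon_moments <- function(polygon) {
  p <- as_polygon_xy(polygon)
  n <- length(p$x)
  i2 <- c(2:n, 1)
  x1 <- p$x; y1 <- p$y; x2 <- p$x[i2]; y2 <- p$y[i2]
  cross <- x1 * y2 - x2 * y1
  A <- sum(cross) / 2                      # signed
  if (abs(A) < .Machine$double.eps) stop("degenerate polygon: zero area")
  cx <- sum((x1 + x2) * cross) / (6 * A)
  cy <- sum((y1 + y2) * cross) / (6 * A)
  sxx <- sum((x1^2 + x1 * x2 + x2^2) * cross) / 12
  syy <- sum((y1^2 + y1 * y2 + y2^2) * cross) / 12
  sxy <- sum((x1 * y2 + 2 * x1 * y1 + 2 * x2 * y2 + x2 * y1) * cross) / 24
  list(area = abs(A), cx = cx, cy = cy,
       mu20 = sxx / A - cx^2, mu02 = syy / A - cy^2, mu11 = sxy / A - cx * cy)
}

#' Equal-area best-fit ellipse of a polygon
#'
#' Orientation and axis ratio come from the region's exact second central
#' moments over the polygon interior (for a uniform ellipse the moment along
#' the major axis is a^2/4); the axes are then rescaled so the ellipse area
#' equals the polygon area -- the "Fit Ellipse" convention of image-analysis
#' practice. Isotropic regions return a circle with orientation 0.
#'
#' @inheritParams polygon_area
#' @return list of class `ellipse_fit`: `cx`, `cy`, semi-axes `a >= b`,
#'   orientation `theta` (radians), `area`.
#' @export
fit_equal_area_ellipse <- function(polygon) {
  m <- polygon_moments(polygon)
  theta <- 0.5 * atan2(2 * m$mu11, m$mu20 - m$mu02)
  common <- (m$mu20 + m$mu02) / 2
  diff <- sqrt(((m$mu20 - m$mu02) / 2)^2 + m$mu11^2)
  l1 <- common + diff; l2 <- max(common - diff, .Machine$double.eps)
  if (diff < 1e-12 * common) theta <- 0
  a0 <- 2 * sqrt(l1); b0 <- 2 * sqrt(l2)
  s <- sqrt(m$area / (pi * a0 * b0))
  structure(list(cx = m$cx, cy = m$cy, a = a0 * s, b = b0 * s,
                 theta = theta, area = m$area),
            class = "ellipse_fit")
}

#' Ellipse perimeter (Ramanujan's second approximation)
#'
#' Relative error below 1e-6 for aspect ratios up to 20.
#'
#' @param a,b semi-axes, `a >= b > 0`.
#' @return perimeter length.
#' @export
ellipse_perimeter <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("axes must be positive")
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Boundary roughness index
#'
#' Ratio of the perimeter of the area-matched best-fit ellipse to the
#' perimeter of the traced boundary. Smooth elliptical tracings give 1;
#' jagged boundaries with finger-like projections have longer perimeters at
#' the same area, giving smaller values.
#'
#' @inheritParams polygon_area
#' @return list of class `roughness_index` with `value`, `ellipse`,
#'   `polygon_perimeter`, `ellipse_perimeter`.
#' @export
roughness_index <- function(polygon) {
  fit <- fit_equal_area_ellipse(polygon)
  pe <- ellipse_perimeter(fit$a, fit$b)
  pp <- polygon_perimeter(polygon)
  structure(list(value = pe / pp, ellipse = fit,
                 polygon_perimeter = pp, ellipse_perimeter = pe),
            class = "roughness_index")
}

#' @export
print.roughness_index <- function(x, ...) {
  cat(sprintf("roughness index: %.4f (ellipse %.4g / boundary %.4g)\n",
              x$value, x$ellipse_perimeter, x$polygon_perimeter))
  invisible(x)
}

#' Per-animal aggregation and group comparison of roughness indices
#'
#' Slice indices are averaged within animal first, then the animal-level
#' means are compared with an unpaired two-tailed Student t test. Identical
#' zero-variance groups return p = 1 with a warning.
#'
#' @param index_a,index_b numeric slice-level indices for the two groups.
#' @param animal_a,animal_b animal ids per slice (default: one animal per
#'   value, i.e. inputs are already animal-level means).
#' @return list with `t`, `df`, `p.value`, `mean_a`, `mean_b`.
#' @export
compare_roughness <- function(index_a, index_b,
                              animal_a = seq_along(index_a),
                              animal_b = seq_along(index_b)) {
  a <- tapply(index_a, animal_a, mean)
  b <- tapply(index_b, animal_b, mean)
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 animals per group")
  if (sd(a) == 0 && sd(b) == 0) {
    warning("zero variance in both groups")
    return(list(t = 0, df = length(a) + length(b) - 2,
                p.value = if (mean(a) == mean(b)) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

# Douglas-Peucker polyline simplification (open chain)
rdp_simplify <- function(x, y, tol) {
  n <- length(x)
  keep <- logical(n); keep[c(1, n)] <- TRUE
  recurse <- function(i, j) {
    if (j <= i + 1) return()
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    len <- sqrt(dx^2 + dy^2)
    idx <- (i + 1):(j - 1)
    d <- if (len == 0) sqrt((x[idx] - x[i])^2 + (y[idx] - y[i])^2)
         else abs(dy * (x[idx] - x[i]) - dx * (y[idx] - y[i])) / len
    k <- idx[which.max(d)]
    if (max(d) > tol) {
      keep[k] <<- TRUE
      recurse(i, k); recurse(k, j)
    }
  }
  recurse(1, n)
  list(x = x[keep], y = y[keep])
}

#' Extract a boundary polygon from a binary mask
#'
#' Takes the 0.5-level isocontour of the mask (sub-pixel, via marching
#' squares as implemented by [grDevices::contourLines()]), keeps the contour
#' enclosing the largest area (the outer contour of the largest connected
#' component), and simplifies it with a Douglas-Peucker tolerance so that
#' pixelation does not inflate the measured perimeter. The tolerance applied
#' is recorded as an attribute.
#'
#' @param mask logical or 0/1 matrix.
#' @param spacing physical units per pixel.
#' @param tolerance simplification tolerance in pixels (default 0.5).
#' @return a [boundary_polygon()].
#' @export
mask_to_polygon <- function(mask, spacing = 1, tolerance = 0.5) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) stop("mask is empty")
  pad <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  cl <- contourLines(x = seq_len(nrow(pad)), y = seq_len(ncol(pad)),
                     z = pad, levels = 0.5)
  if (!length(cl)) stop("no contour found")
  areas <- vapply(cl, function(c0) {
    n <- length(c0$x); i2 <- c(2:n, 1)
    abs(sum(c0$x * c0$y[i2] - c0$x[i2] * c0$y)) / 2
  }, numeric(1))
  c0 <- cl[[which.max(areas)]]
  simp <- rdp_simplify(c0$x, c0$y, tolerance)
  out <- boundary_polygon(simp$x, simp$y, spacing = spacing)
  attr(out, "tolerance") <- tolerance
  out
}
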