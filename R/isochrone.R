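#' @include mask.R
NULL

# Least-squares nodal gradients on a triangulation: for each node, fit a
# plane z ~ x + y over the node and its triangulation neighbours. Exact for
# linear fields. Returns an n x 2 matrix.
nodalGradients <- function(x, y, z, tri) {
  n <- length(x)
  nbr <- vector("list", n)
  for (r in seq_len(nrow(tri))) {
    a <- tri[r, 1]; b <- tri[r, 2]; cc <- tri[r, 3]
    nbr[[a]] <- c(nbr[[a]], b, cc)
    nbr[[b]] <- c(nbr[[b]], a, cc)
    nbr[[cc]] <- c(nbr[[cc]], a, b)
  }
  g <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    j <- unique(nbr[[i]])
    dx <- x[j] - x[i]; dy <- y[j] - y[i]; dz <- z[j] - z[i]
    A <- cbind(dx, dy)
    fit <- tryCatch(qr.solve(crossprod(A), crossprod(A, dz)),
      error = function(e) NULL)
    if (!is.null(fit)) g[i, ] <- fit
  }
  g
}

# Evaluate the cubic Bezier triangle interpolant with vertex values z and
# gradients g at barycentric coordinates (u, v, w) of triangle (i, j, k).
# Edge control points follow the vertex gradients; the interior point is
# chosen for quadratic precision. Exact at vertices; reproduces linear
# fields when the gradients do; values stay inside the control-point hull.
bezierTriangleEval <- function(u, v, w, P, z, g) {
  e <- function(a, b) sum(g[a, ] * (P[b, ] - P[a, ])) / 3
  b300 <- z[1]; b030 <- z[2]; b003 <- z[3]
  b210 <- z[1] + e(1, 2); b201 <- z[1] + e(1, 3)
  b120 <- z[2] + e(2, 1); b021 <- z[2] + e(2, 3)
  b102 <- z[3] + e(3, 1); b012 <- z[3] + e(3, 2)
  E <- (b210 + b201 + b120 + b021 + b102 + b012) / 6
  V <- (b300 + b030 + b003) / 3
  b111 <- E + (E - V) / 2
  b300 * u^3 + b030 * v^3 + b003 * w^3 +
    3 * (b210 * u^2 * v + b201 * u^2 * w + b120 * u * v^2 +
         b021 * v^2 * w + b102 * u * w^2 + b012 * v * w^2) +
    6 * b111 * u * v * w
}

# Delaunay cubic interpolation of scattered (x, y, z) at query points; NA
# outside the convex hull. Triangulation by deldir (deterministic, robust
# to the cocircular point groups raster sampling produces).
delaunayCubic <- function(x, y, z, xq, yq) {
  trs <- deldir::triMat(deldir::deldir(x, y, suppressMsge = TRUE))
  g <- nodalGradients(x, y, z, trs)
  out <- rep(NA_real_, length(xq))
  todo <- seq_along(xq)
  eps <- 1e-9
  for (r in seq_len(nrow(trs))) {
    if (!length(todo)) break
    i <- trs[r, 1]; j <- trs[r, 2]; k <- trs[r, 3]
    x1 <- x[i]; y1 <- y[i]; x2 <- x[j]; y2 <- y[j]; x3 <- x[k]; y3 <- y[k]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-12) next
    dx <- xq[todo] - x3; dy <- yq[todo] - y3
    u <- ((y2 - y3) * dx + (x3 - x2) * dy) / det
    v <- ((y3 - y1) * dx + (x1 - x3) * dy) / det
    w <- 1 - u - v
    inside <- u >= -eps & v >= -eps & w >= -eps
    if (!any(inside)) next
    q <- todo[inside]
    out[q] <- bezierTriangleEval(u[inside], v[inside], w[inside],
      rbind(c(x1, y1), c(x2, y2), c(x3, y3)), z[c(i, j, k)], g[c(i, j, k), ])
    todo <- todo[!inside]
  }
  out
}

#' Interpolate scattered activation times to a continuous isochrone map
#'
#' Cubic interpolation on the Delaunay triangulation of the scattered
#' zero-crossing times, evaluated at every mask pixel — the step that turns
#' 150-300 reviewed points into a continuous isochrone pattern over the
#' myocardial mask. Each triangle carries a cubic Bezier patch whose edge
#' control points follow least-squares nodal gradients; the interpolant is
#' exact at the sample points, reproduces linear fields, and (by the Bezier
#' convex-hull property) cannot overshoot beyond the control-point range —
#' important because activation fields of focal sources have a conical
#' minimum that global splines overshoot. Mask pixels outside the convex
#' hull of the samples take the value of the nearest sample and are flagged
#' extrapolated.
#'
#' @param points data.frame with columns x, y (mm) and at (ms); rows with
#'   NA activation times are dropped.
#' @param mask a \linkS4class{MyocardialMask}.
#' @return an \linkS4class{IsochroneMap}.
#' @export
interpolateIsochrones <- function(points, mask) {
  stopifnot(all(c("x", "y", "at") %in% names(points)))
  pts <- points[!is.na(points$at), , drop = FALSE]
  pts <- stats::aggregate(at ~ x + y, data = pts, FUN = mean)  # merge dups
  if (nrow(pts) < 3) stop("need at least 3 points with activation times")
  sv <- svd(cbind(pts$x - mean(pts$x), pts$y - mean(pts$y)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("collinear point set: Delaunay triangulation is degenerate")

  idx <- which(mask@mask)
  co <- maskCoords(mask, idx)
  z <- delaunayCubic(pts$x, pts$y, pts$at, co$x, co$y)

  extra <- is.na(z)
  if (any(extra)) {
    near <- vapply(which(extra), function(i) {
      which.min((pts$x - co$x[i])^2 + (pts$y - co$y[i])^2)
    }, integer(1))
    z[extra] <- pts$at[near]
  }
  at <- matrix(NA_real_, nrow(mask@mask), ncol(mask@mask))
  at[idx] <- z
  ex <- matrix(FALSE, nrow(mask@mask), ncol(mask@mask))
  ex[idx] <- extra
  new("IsochroneMap", at = at, extrapolated = ex, mask = mask,
    method = "delaunay-cubic", offset = 0)
}
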