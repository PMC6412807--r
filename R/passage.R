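## Door passability: the widest disc, centered inside the closed triangle,
## clear of the three vertex atoms' vdW spheres. CVmax is its diameter.
##
## The clearance field f(c) = min_i(||c - p_i|| - r_i) is a minimum of convex
## functions, so over the closed triangle its maximum is attained either at
## a point with equal clearance to all three atoms (additively weighted
## Voronoi vertex, "Apollonius point"), at a point on a triangle edge with
## equal clearance to two atoms, or at a triangle vertex. All candidates are
## closed-form (quadratics); spurious roots are harmless because every
## candidate is simply evaluated through f.

.plane_basis <- function(p1, p2, p3) {
  e1 <- p2 - p1
  n1 <- sqrt(sum(e1^2))
  if (n1 == 0) return(NULL)
  e1 <- e1 / n1
  w <- p3 - p1
  e2 <- w - sum(w * e1) * e1
  n2 <- sqrt(sum(e2^2))
  if (n2 < 1e-12 * max(n1, 1)) return(NULL)
  list(q = rbind(c(0, 0), c(n1, 0), c(sum(w * e1), n2)))
}

.clearance <- function(cx, cy, q, r) {
  pmin(sqrt((cx - q[1, 1])^2 + (cy - q[1, 2])^2) - r[1],
       pmin(sqrt((cx - q[2, 1])^2 + (cy - q[2, 2])^2) - r[2],
            sqrt((cx - q[3, 1])^2 + (cy - q[3, 2])^2) - r[3]))
}

.in_triangle <- function(pt, q, tol = 1e-9) {
  d <- (q[2, 1] - q[1, 1]) * (q[3, 2] - q[1, 2]) -
       (q[3, 1] - q[1, 1]) * (q[2, 2] - q[1, 2])
  if (abs(d) < 1e-300) return(FALSE)
  l1 <- ((q[2, 1] - pt[1]) * (q[3, 2] - pt[2]) -
         (q[3, 1] - pt[1]) * (q[2, 2] - pt[2])) / d
  l2 <- ((q[3, 1] - pt[1]) * (q[1, 2] - pt[2]) -
         (q[1, 1] - pt[1]) * (q[3, 2] - pt[2])) / d
  l3 <- 1 - l1 - l2
  s <- tol * (1 + max(abs(q)))
  l1 >= -s && l2 >= -s && l3 >= -s
}

# points on segment P + s V (s in [0,1]) where clearance to site k equals
# clearance to site l; returns s values (possibly spurious, caller evaluates)
.edge_equal_clearance <- function(P, V, qk, rk, ql, rl) {
  Ak <- sum((P - qk)^2); Bk <- sum(V * (P - qk))
  Al <- sum((P - ql)^2); Bl <- sum(V * (P - ql))
  vv <- sum(V^2)
  delta <- rk - rl
  if (delta == 0) {
    den <- 2 * (Bk - Bl)
    if (abs(den) < 1e-14) return(numeric(0))
    return(-(Ak - Al) / den)
  }
  alpha <- Ak - Al - delta^2
  beta <- 2 * (Bk - Bl)
  # (alpha + beta s)^2 = 4 delta^2 (Al + 2 Bl s + vv s^2)
  a2 <- beta^2 - 4 * delta^2 * vv
  a1 <- 2 * alpha * beta - 8 * delta^2 * Bl
  a0 <- alpha^2 - 4 * delta^2 * Al
  if (abs(a2) < 1e-14) {
    if (abs(a1) < 1e-14) return(numeric(0))
    return(-a0 / a1)
  }
  disc <- a1^2 - 4 * a2 * a0
  if (disc < 0) return(numeric(0))
  sq <- sqrt(disc)
  c((-a1 - sq) / (2 * a2), (-a1 + sq) / (2 * a2))
}

# equal-clearance-to-all-three points (2D); returns matrix of candidates
.apollonius_points <- function(q, r) {
  rhs <- function(i, j) {
    sum(q[j, ]^2) - sum(q[i, ]^2) - r[j]^2 + r[i]^2
  }
  M <- rbind(c(2 * (q[2, 1] - q[1, 1]), 2 * (q[2, 2] - q[1, 2]), 2 * (r[2] - r[1])),
             c(2 * (q[3, 1] - q[1, 1]), 2 * (q[3, 2] - q[1, 2]), 2 * (r[3] - r[1])))
  b <- c(rhs(1, 2), rhs(1, 3))
  A <- M[, 1:2]
  dA <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(dA) < 1e-12 * (1 + max(abs(q)))^2) return(NULL)
  # solve A %*% c(x,y) = b - t * M[,3]  =>  (x,y) = u + t * v
  inv <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2) / dA
  u <- inv %*% b
  v <- inv %*% (-M[, 3])
  # plug into (x - x1)^2 + (y - y1)^2 = (t + r1)^2
  dx0 <- u[1] - q[1, 1]; dy0 <- u[2] - q[1, 2]
  c2 <- v[1]^2 + v[2]^2 - 1
  c1 <- 2 * (dx0 * v[1] + dy0 * v[2]) - 2 * r[1]
  c0 <- dx0^2 + dy0^2 - r[1]^2
  ts <- if (abs(c2) < 1e-14) {
    if (abs(c1) < 1e-14) numeric(0) else -c0 / c1
  } else {
    disc <- c1^2 - 4 * c2 * c0
    if (disc < 0) numeric(0)
    else c((-c1 - sqrt(disc)) / (2 * c2), (-c1 + sqrt(disc)) / (2 * c2))
  }
  if (!length(ts)) return(NULL)
  t(vapply(ts, function(t) c(u[1] + t * v[1], u[2] + t * v[2]),
           numeric(2)))
}

#' Maximum passable ligand thickness through a triangular door
#'
#' Computes CVmax for the door formed by three atoms: the diameter of the
#' largest disc whose center lies in the closed triangle spanned by the
#' atom centers and which clears the three van der Waals spheres,
#' `CVmax = 2 * max(0, max_c min_i(||c - p_i|| - r_i))`. A fully obstructed
#' door (the clearance is negative everywhere) has CVmax 0; so does a
#' degenerate (collinear) triangle.
#'
#' @param p 3 x 3 numeric matrix, one vertex atom center per row (Angstrom).
#' @param r length-3 vdW radii (Angstrom).
#' @return CVmax in Angstrom.
#' @examples
#' s <- 2 * sqrt(3)  # equilateral, circumradius 2
#' p <- rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0))
#' face_cvmax(p, c(0, 0, 0))      # 4
#' face_cvmax(p, c(0.5, 0.5, 0.5))  # 3
#' @export
face_cvmax <- function(p, r) {
  pb <- .plane_basis(p[1, ], p[2, ], p[3, ])
  if (is.null(pb)) return(0)
  q <- pb$q
  cand <- q  # triangle vertices
  edges <- list(c(1, 2), c(2, 3), c(1, 3))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (e in edges) {
    P <- q[e[1], ]; V <- q[e[2], ] - q[e[1], ]
    for (pr in pairs) {
      ss <- .edge_equal_clearance(P, V, q[pr[1], ], r[pr[1]],
                                  q[pr[2], ], r[pr[2]])
      ss <- ss[is.finite(ss) & ss > 0 & ss < 1]
      if (length(ss))
        cand <- rbind(cand, t(vapply(ss, function(s) P + s * V, numeric(2))))
    }
  }
  ap <- .apollonius_points(q, r)
  if (!is.null(ap)) {
    keep <- apply(ap, 1, function(pt) all(is.finite(pt)) && .in_triangle(pt, q))
    if (any(keep)) cand <- rbind(cand, ap[keep, , drop = FALSE])
  }
  best <- max(.clearance(cand[, 1], cand[, 2], q, r))
  2 * max(0, best)
}

#' Brute-force grid oracle for door width
#'
#' Maximizes the clearance `min_i(||c - p_i|| - r_i)` over a regular grid of
#' pitch at most `step` covering the closed triangle (interior lattice plus
#' sampled edges). Because the clearance field is 1-Lipschitz, the result is
#' within O(`step`) of [face_cvmax()]; it serves as an independent check of
#' the closed-form construction.
#'
#' @inheritParams face_cvmax
#' @param step grid pitch in Angstrom.
#' @return CVmax estimate in Angstrom.
#' @export
cvmax_oracle <- function(p, r, step = 1e-3) {
  stopifnot(step > 0)
  pb <- .plane_basis(p[1, ], p[2, ], p[3, ])
  if (is.null(pb)) return(0)
  q <- pb$q
  h <- step / sqrt(2)
  xr <- range(q[, 1]); yr <- range(q[, 2])
  gx <- seq(xr[1], xr[2], by = h)
  gy <- seq(yr[1], yr[2], by = h)
  best <- -Inf
  # chunk rows of the lattice to bound memory
  chunk <- max(1L, floor(2e6 / length(gx)))
  d <- (q[2, 1] - q[1, 1]) * (q[3, 2] - q[1, 2]) -
       (q[3, 1] - q[1, 1]) * (q[2, 2] - q[1, 2])
  for (i0 in seq(1, length(gy), by = chunk)) {
    yy <- gy[i0:min(i0 + chunk - 1, length(gy))]
    cx <- rep(gx, times = length(yy))
    cy <- rep(yy, each = length(gx))
    l1 <- ((q[2, 1] - cx) * (q[3, 2] - cy) - (q[3, 1] - cx) * (q[2, 2] - cy)) / d
    l2 <- ((q[3, 1] - cx) * (q[1, 2] - cy) - (q[1, 1] - cx) * (q[3, 2] - cy)) / d
    inside <- l1 >= 0 & l2 >= 0 & (1 - l1 - l2) >= 0
    if (any(inside)) {
      v <- .clearance(cx[inside], cy[inside], q, r)
      best <- max(best, max(v))
    }
  }
  for (e in list(c(1, 2), c(2, 3), c(1, 3))) {
    P <- q[e[1], ]; V <- q[e[2], ] - q[e[1], ]
    n <- max(2L, ceiling(sqrt(sum(V^2)) / h))
    s <- seq(0, 1, length.out = n + 1)
    best <- max(best, max(.clearance(P[1] + s * V[1], P[2] + s * V[2], q, r)))
  }
  2 * max(0, best)
}

#' Annotate every face of a tessellation with its CVmax
#'
#' @param tess a [triangulate()] result whose atoms carry vdW radii.
#' @return the tessellation with `faces$cvmax` filled (hull faces included).
#' @export
annotate_cvmax <- function(tess) {
  stopifnot(inherits(tess, "tessellation"))
  f <- tess$faces
  xyz <- tess$xyz; radii <- tess$radii
  if (all(radii == 0) && is.null(tess$atoms$vdw_radius))
    warning("all radii are zero; doors reflect bare geometry")
  n <- nrow(f)
  cv <- numeric(n)
  for (i in seq_len(n)) {
    idx <- c(f$v1[i], f$v2[i], f$v3[i])
    cv[i] <- face_cvmax(xyz[idx, , drop = FALSE], radii[idx])
  }
  tess$faces$cvmax <- cv
  tess
}
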