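# Small-scale Delaunay triangulation (Bowyer-Watson) and piecewise-linear
# scattered interpolation. Anchor sets here are tiny (8-17 saccade
# end-positions), so brute-force searches are fine. Symmetric layouts
# contain exactly cocircular quadruples, which make the incircle predicate
# degenerate; a deterministic jitter of ~1e-7 x the point scale is applied
# to the copies used for triangulation only, which perturbs interpolation
# weights by a comparable (negligible) amount.

triangulate_points <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 anchor points")
  scale <- max(apply(xy, 2, function(c) diff(range(c))), 1e-9)
  # collinearity check: max doubled triangle area over all triples
  max_area <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a2 <- abs((xy[j, 1] - xy[i, 1]) * (xy[k, 2] - xy[i, 2]) -
                (xy[k, 1] - xy[i, 1]) * (xy[j, 2] - xy[i, 2]))
    if (a2 > max_area) max_area <- a2
  }
  if (max_area < 1e-10 * scale^2) stop("anchor points are collinear")

  # deterministic symmetry-breaking jitter
  ang <- (seq_len(n) * 2654435761) %% 360
  jit <- 1e-7 * scale * cbind(cos(ang), sin(ang))
  p <- xy + jit

  cx <- mean(range(p[, 1])); cy <- mean(range(p[, 2]))
  r <- 20 * scale
  super <- rbind(c(cx - 2 * r, cy - r), c(cx + 2 * r, cy - r), c(cx, cy + 2 * r))
  pts <- rbind(p, super)
  tris <- matrix(n + c(1L, 2L, 3L), ncol = 3)

  circum <- function(tri) {
    a <- pts[tri[1], ]; b <- pts[tri[2], ]; c_ <- pts[tri[3], ]
    d <- 2 * (a[1] * (b[2] - c_[2]) + b[1] * (c_[2] - a[2]) +
                c_[1] * (a[2] - b[2]))
    ux <- ((a[1]^2 + a[2]^2) * (b[2] - c_[2]) +
             (b[1]^2 + b[2]^2) * (c_[2] - a[2]) +
             (c_[1]^2 + c_[2]^2) * (a[2] - b[2])) / d
    uy <- ((a[1]^2 + a[2]^2) * (c_[1] - b[1]) +
             (b[1]^2 + b[2]^2) * (a[1] - c_[1]) +
             (c_[1]^2 + c_[2]^2) * (b[1] - a[1])) / d
    c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
  }
  cc <- t(apply(tris, 1, circum))

  for (ip in seq_len(n)) {
    px <- pts[ip, 1]; py <- pts[ip, 2]
    bad <- which((px - cc[, 1])^2 + (py - cc[, 2])^2 < cc[, 3] * (1 - 1e-12))
    if (!length(bad)) next
    # boundary of the cavity: edges that appear exactly once
    edges <- do.call(rbind, lapply(bad, function(b) {
      tr <- tris[b, ]
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    keep <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    new_tris <- cbind(keep, ip)
    tris <- rbind(tris, new_tris)
    cc <- rbind(cc, t(apply(new_tris, 1, circum)))
  }
  in_super <- apply(tris, 1, function(tr) any(tr > n))
  tris <- tris[!in_super, , drop = FALSE]
  list(points = p, triangles = tris)
}

#' Piecewise-linear interpolation weights for scattered anchors
#'
#' Builds the weight matrix `W` (queries x anchors) such that
#' `W %*% values` linearly interpolates anchor values on the Delaunay
#' triangulation of the anchors. Queries inside the convex hull get
#' barycentric weights of their containing triangle; queries outside the
#' hull get weight 1 on the nearest anchor (next-neighbor extrapolation,
#' chosen to not overestimate activity outside the sampled area).
#'
#' @param anchor_xy n x 2 matrix of anchor positions (>= 3, non-collinear).
#' @param qx,qy Query coordinates (equal-length vectors).
#' @return A list: `W` (dense weight matrix), `outside` (logical per query).
#' @export
interp_weights <- function(anchor_xy, qx, qy) {
  anchor_xy <- as.matrix(anchor_xy)
  tri <- triangulate_points(anchor_xy)
  p <- tri$points
  nq <- length(qx)
  na <- nrow(p)
  W <- matrix(0, nq, na)
  unassigned <- rep(TRUE, nq)
  eps <- -1e-9
  for (k in seq_len(nrow(tri$triangles))) {
    if (!any(unassigned)) break
    tr <- tri$triangles[k, ]
    a <- p[tr[1], ]; b <- p[tr[2], ]; c_ <- p[tr[3], ]
    det <- (b[2] - c_[2]) * (a[1] - c_[1]) + (c_[1] - b[1]) * (a[2] - c_[2])
    idx <- which(unassigned)
    l1 <- ((b[2] - c_[2]) * (qx[idx] - c_[1]) +
             (c_[1] - b[1]) * (qy[idx] - c_[2])) / det
    l2 <- ((c_[2] - a[2]) * (qx[idx] - c_[1]) +
             (a[1] - c_[1]) * (qy[idx] - c_[2])) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= eps & l2 >= eps & l3 >= eps
    if (any(inside)) {
      ii <- idx[inside]
      W[cbind(ii, tr[1])] <- l1[inside]
      W[cbind(ii, tr[2])] <- l2[inside]
      W[cbind(ii, tr[3])] <- l3[inside]
      unassigned[ii] <- FALSE
    }
  }
  outside <- unassigned
  if (any(unassigned)) {
    idx <- which(unassigned)
    d2 <- outer(qx[idx], p[, 1], "-")^2 + outer(qy[idx], p[, 2], "-")^2
    nn <- max.col(-d2, ties.method = "first")
    W[cbind(idx, nn)] <- 1
  }
  list(W = W, outside = outside)
}
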