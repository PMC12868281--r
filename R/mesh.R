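#' @importFrom Matrix sparseMatrix Diagonal forceSymmetric Cholesky solve
#'   bdiag crossprod t diag colSums rowSums
NULL

# ---- Delaunay triangulation (Bowyer-Watson) --------------------------------

circumcircle <- function(P, tri) {
  a <- P[tri[, 1], , drop = FALSE]
  b <- P[tri[, 2], , drop = FALSE]
  c <- P[tri[, 3], , drop = FALSE]
  d <- 2 * (a[, 1] * (b[, 2] - c[, 2]) + b[, 1] * (c[, 2] - a[, 2]) +
              c[, 1] * (a[, 2] - b[, 2]))
  a2 <- rowSums(a^2); b2 <- rowSums(b^2); c2 <- rowSums(c^2)
  ux <- (a2 * (b[, 2] - c[, 2]) + b2 * (c[, 2] - a[, 2]) +
           c2 * (a[, 2] - b[, 2])) / d
  uy <- (a2 * (c[, 1] - b[, 1]) + b2 * (a[, 1] - c[, 1]) +
           c2 * (b[, 1] - a[, 1])) / d
  r2 <- (a[, 1] - ux)^2 + (a[, 2] - uy)^2
  bad <- !is.finite(ux) | !is.finite(uy) | abs(d) < 1e-12
  r2[bad] <- Inf; ux[bad] <- 0; uy[bad] <- 0
  cbind(ux, uy, r2)
}

# Bowyer-Watson incremental Delaunay over the rows of P (no duplicates).
delaunay <- function(P) {
  n <- nrow(P)
  ctr <- colMeans(P)
  R <- max(sqrt(rowSums(sweep(P, 2, ctr)^2)), 1)
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  super <- cbind(ctr[1] + 40 * R * cos(ang), ctr[2] + 40 * R * sin(ang))
  Pa <- rbind(P, super)
  tri <- matrix(n + 1:3, 1, 3)
  cc <- circumcircle(Pa, tri)
  for (i in seq_len(n)) {
    px <- Pa[i, 1]; py <- Pa[i, 2]
    inside <- (px - cc[, 1])^2 + (py - cc[, 2])^2 < cc[, 3] * (1 + 1e-12)
    bad <- which(inside)
    if (!length(bad)) stop("triangulation failure: point outside all circumcircles")
    # boundary of the cavity: edges of bad triangles appearing exactly once
    bt <- tri[bad, , drop = FALSE]
    e1 <- cbind(bt[, 1], bt[, 2]); e2 <- cbind(bt[, 2], bt[, 3])
    e3 <- cbind(bt[, 3], bt[, 1])
    edges <- rbind(e1, e2, e3)
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    once <- key %in% names(which(table(key) == 1L))
    boundary <- edges[once, , drop = FALSE]
    newtri <- cbind(boundary, i)
    tri <- rbind(tri[-bad, , drop = FALSE], newtri)
    cc <- rbind(cc[-bad, , drop = FALSE], circumcircle(Pa, newtri))
  }
  keep <- rowSums(tri > n) == 0
  tri <- tri[keep, , drop = FALSE]
  # orient counterclockwise
  ax <- Pa[tri[, 1], 1]; ay <- Pa[tri[, 1], 2]
  bx <- Pa[tri[, 2], 1]; by <- Pa[tri[, 2], 2]
  cx <- Pa[tri[, 3], 1]; cy <- Pa[tri[, 3], 2]
  cross <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  flip <- cross < 0
  tmp <- tri[flip, 2]; tri[flip, 2] <- tri[flip, 3]; tri[flip, 3] <- tmp
  tri
}

dedupe_points <- function(P, digits = 8) {
  key <- paste(round(P[, 1], digits), round(P[, 2], digits))
  P[!duplicated(key), , drop = FALSE]
}

#' Build a finite-element mesh with SPDE matrices
#'
#' Constructs a Delaunay triangulation over the county centroids plus a
#' jittered ring of boundary points at distance `boundary_extension`
#' (extending the field's domain avoids boundary inflation of the Matern
#' variance), refines edges longer than `max_edge` by midpoint insertion,
#' and assembles the standard piecewise-linear finite-element matrices:
#' the lumped (diagonal) mass matrix `C`, the stiffness matrix `G`, and
#' the projector `A` whose row for each centroid holds its barycentric
#' coordinates in the containing triangle.
#'
#' @param centroids two-column matrix of planar coordinates.
#' @param max_edge target maximum triangle edge length.
#' @param boundary_extension distance of the enclosing boundary ring.
#' @return list of class `mesh_spde`: `vertices`, `triangles`, `C`, `G`,
#'   `A`, `n_vertices`.
#' @export
build_mesh <- function(centroids, max_edge, boundary_extension) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 3) stop("need at least 3 centroids", call. = FALSE)
  stop_if_not_positive(max_edge, "max_edge")
  stop_if_not_positive(boundary_extension, "boundary_extension")
  # collinearity: rank of centered coordinates
  ctr <- sweep(centroids, 2, colMeans(centroids))
  sv <- svd(ctr)$d
  if (sv[2] < 1e-10 * max(sv[1], 1)) {
    stop("centroids are collinear; cannot triangulate", call. = FALSE)
  }

  center <- colMeans(centroids)
  R <- max(sqrt(rowSums(sweep(centroids, 2, center)^2))) + boundary_extension
  n_ring <- max(8L, ceiling(2 * pi * R / max_edge))
  th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  # deterministic radial wobble breaks exact cocircularity of the ring
  wob <- 1 + 0.015 * sin(7.3 * seq_len(n_ring))
  ring <- cbind(center[1] + R * wob * cos(th), center[2] + R * wob * sin(th))

  pts <- dedupe_points(rbind(centroids, ring))
  for (pass in 1:12) {
    tri <- delaunay(pts)
    e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
    e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    len <- sqrt(rowSums((pts[e[, 1], , drop = FALSE] -
                           pts[e[, 2], , drop = FALSE])^2))
    long <- which(len > max_edge)
    if (!length(long)) break
    mids <- (pts[e[long, 1], , drop = FALSE] + pts[e[long, 2], , drop = FALSE]) / 2
    pts <- dedupe_points(rbind(pts, mids))
  }

  V <- nrow(pts)
  # FEM assembly
  i1 <- tri[, 1]; i2 <- tri[, 2]; i3 <- tri[, 3]
  x1 <- pts[i1, 1]; y1 <- pts[i1, 2]
  x2 <- pts[i2, 1]; y2 <- pts[i2, 2]
  x3 <- pts[i3, 1]; y3 <- pts[i3, 2]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  if (any(area <= 0)) stop("degenerate triangle in mesh assembly")
  bb <- cbind(y2 - y3, y3 - y1, y1 - y2) / (2 * area)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / (2 * area)
  ii <- jj <- vv <- vector("list", 9)
  k <- 0
  idx <- cbind(i1, i2, i3)
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- idx[, a]; jj[[k]] <- idx[, b]
    vv[[k]] <- area * (bb[, a] * bb[, b] + cc[, a] * cc[, b])
  }
  G <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                    dims = c(V, V))
  G <- forceSymmetric((G + Matrix::t(G)) / 2)
  Cdiag <- as.numeric(sparseMatrix(i = as.vector(idx),
                                   j = rep(1L, 3 * nrow(tri)),
                                   x = rep(area / 3, 3), dims = c(V, 1)))
  C <- Diagonal(V, Cdiag)

  A <- projector_matrix(pts, tri, centroids)
  structure(list(vertices = pts, triangles = tri, C = C, G = G, A = A,
                 n_vertices = V),
            class = "mesh_spde")
}

# Barycentric projector rows for `points` over triangulation (pts, tri).
projector_matrix <- function(pts, tri, points) {
  n <- nrow(points); V <- nrow(pts)
  x1 <- pts[tri[, 1], 1]; y1 <- pts[tri[, 1], 2]
  x2 <- pts[tri[, 2], 1]; y2 <- pts[tri[, 2], 2]
  x3 <- pts[tri[, 3], 1]; y3 <- pts[tri[, 3], 2]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  ai <- integer(0); aj <- integer(0); av <- numeric(0)
  for (p in seq_len(n)) {
    px <- points[p, 1]; py <- points[p, 2]
    # exact vertex hit first
    hit <- which(abs(pts[, 1] - px) < 1e-9 & abs(pts[, 2] - py) < 1e-9)
    if (length(hit)) {
      ai <- c(ai, p); aj <- c(aj, hit[1]); av <- c(av, 1)
      next
    }
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
    l3 <- 1 - l1 - l2
    ok <- which(l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9)
    if (!length(ok)) stop(sprintf("point %d outside mesh hull", p))
    t <- ok[1]
    lam <- c(l1[t], l2[t], l3[t]); lam <- pmax(lam, 0); lam <- lam / sum(lam)
    ai <- c(ai, rep(p, 3)); aj <- c(aj, tri[t, ]); av <- c(av, lam)
  }
  sparseMatrix(i = ai, j = aj, x = av, dims = c(n, V))
}

#' @export
print.mesh_spde <- function(x, ...) {
  cat(sprintf("mesh_spde: %d vertices, %d triangles, projector %d x %d\n",
              x$n_vertices, nrow(x$triangles), nrow(x$A), ncol(x$A)))
  invisible(x)
}

#' Matern hyperparameters under the alpha = 2 SPDE convention
#'
#' `range` is the distance at which the Matern (nu = 1) correlation falls
#' to about 0.1; `sigma` the marginal standard deviation. Internally
#' `kappa = sqrt(8) / range` and `tau = 1 / (sigma * kappa * sqrt(4 pi))`.
#'
#' @param range correlation range (> 0), in coordinate units.
#' @param sigma marginal standard deviation (> 0).
#' @return list of class `spde_hyper` with `range`, `sigma`, `kappa`, `tau`.
#' @export
spde_hyper <- function(range, sigma) {
  if (!is.finite(range) || range <= 0 || !is.finite(sigma) || sigma <= 0) {
    stop("`range` and `sigma` must be finite and positive", call. = FALSE)
  }
  kappa <- sqrt(8) / range
  tau <- 1 / (sigma * kappa * sqrt(4 * pi))
  structure(list(range = range, sigma = sigma, kappa = kappa, tau = tau),
            class = "spde_hyper")
}

#' Sparse SPDE precision matrix of the latent field
#'
#' The alpha = 2 finite-element precision
#' `Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G)` with lumped mass `C`,
#' yielding a Gaussian Markov random field whose continuous limit is a
#' Matern (nu = 1) field with the requested range and marginal sd.
#'
#' @param mesh a [build_mesh()] result.
#' @param hyper a [spde_hyper()].
#' @return sparse symmetric positive-definite precision matrix.
#' @export
spde_precision <- function(mesh, hyper) {
  if (!inherits(hyper, "spde_hyper")) stop("`hyper` must be an spde_hyper")
  k2 <- hyper$kappa^2
  Cinv <- Diagonal(mesh$n_vertices, 1 / Matrix::diag(mesh$C))
  Q <- hyper$tau^2 * (k2^2 * mesh$C + 2 * k2 * mesh$G +
                        mesh$G %*% Cinv %*% mesh$G)
  forceSymmetric(Q)
}

#' Sample zero-mean Gaussian fields with a given sparse precision
#'
#' @param Q sparse SPD precision matrix.
#' @param n number of samples.
#' @return matrix (dim(Q) x n) of samples; uses the current RNG stream.
#' @export
sample_gmrf <- function(Q, n = 1) {
  ch <- Cholesky(forceSymmetric(Q), LDL = FALSE, perm = TRUE)
  z <- matrix(rnorm(nrow(Q) * n), nrow(Q), n)
  x <- solve(ch, solve(ch, z, system = "Lt"), system = "Pt")
  as.matrix(x)
}
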