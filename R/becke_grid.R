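#' Atom-centered molecular quadrature grid with Becke partitioning
#'
#' Standard molecular integration grid: per-atom spherical product grids
#' (Gauss-Legendre radial nodes mapped to (0, Inf) by `r = rm (1+x)/(1-x)`,
#' Gauss-Legendre nodes in cos(theta) and a uniform trapezoid in phi) glued
#' together by Becke's fuzzy-cell partition of unity (cutoff polynomial
#' `f(mu) = 1.5 mu - 0.5 mu^3` iterated three times). Ghost centers may be
#' included: they carry grid points (for counterpoise-consistent quadrature)
#' but no nuclear charge.
#'
#' @param centers m x 3 matrix of atomic (and ghost) positions in bohr.
#' @param nr radial nodes per center.
#' @param ntheta,nphi angular nodes per center.
#' @param rm radial mapping scale (bohr).
#' @return List with `points` (N x 3) and `weights` (length N); weights sum to
#'   the full-space quadrature including the partition of unity.
#' @export
molecular_grid <- function(centers, nr = 35L, ntheta = 8L, nphi = 16L, rm = 1.0) {
  centers <- matrix(as.numeric(centers), ncol = 3L)
  m <- nrow(centers)
  glr <- pracma::gaussLegendre(as.integer(nr), -1, 1)
  r <- rm * (1 + glr$x) / (1 - glr$x)
  wr <- glr$w * 2 * rm / (1 - glr$x)^2 * r^2
  glt <- pracma::gaussLegendre(as.integer(ntheta), -1, 1)
  phi <- 2 * pi * (seq_len(nphi) - 1L) / nphi
  wphi <- 2 * pi / nphi
  ang <- expand.grid(it = seq_len(ntheta), ip = seq_len(nphi))
  ct <- glt$x[ang$it]
  st <- sqrt(pmax(1 - ct^2, 0))
  dirs <- cbind(st * cos(phi[ang$ip]), st * sin(phi[ang$ip]), ct)
  wang <- glt$w[ang$it] * wphi

  shell <- expand.grid(ir = seq_along(r), ia = seq_len(nrow(dirs)))
  pts0 <- dirs[shell$ia, , drop = FALSE] * r[shell$ir]
  w0 <- wr[shell$ir] * wang[shell$ia]

  all_pts <- NULL
  all_w <- NULL
  fcut <- function(mu) {
    for (k in 1:3) mu <- 1.5 * mu - 0.5 * mu^3
    mu
  }
  for (a in seq_len(m)) {
    pts <- sweep(pts0, 2L, centers[a, ], `+`)
    if (m > 1L) {
      # Becke partition of unity
      dist_to <- vapply(seq_len(m), function(b) {
        sqrt(rowSums(sweep(pts, 2L, centers[b, ], `-`)^2))
      }, numeric(nrow(pts)))
      P <- matrix(1, nrow(pts), m)
      for (i in seq_len(m)) for (j in seq_len(m)) {
        if (i == j) next
        Rij <- sqrt(sum((centers[i, ] - centers[j, ])^2))
        mu <- (dist_to[, i] - dist_to[, j]) / Rij
        P[, i] <- P[, i] * 0.5 * (1 - fcut(mu))
      }
      wB <- P[, a] / rowSums(P)
    } else {
      wB <- rep(1, nrow(pts))
    }
    all_pts <- rbind(all_pts, pts)
    all_w <- c(all_w, w0 * wB)
  }
  keep <- all_w > 1e-16
  list(points = all_pts[keep, , drop = FALSE], weights = all_w[keep])
}
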