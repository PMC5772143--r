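#' Real even-order spherical harmonic basis
#'
#' Orthonormal real spherical harmonics restricted to even degrees
#' (antipodally symmetric functions, as required for fibre orientation
#' distributions). Coefficient ordering is fixed throughout the package:
#' degrees l = 0, 2, ..., lmax in ascending order, and within each degree
#' orders m = -l, ..., l; negative m maps to sin(|m| phi) terms, positive
#' m to cos(m phi) terms, both scaled by sqrt(2).
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @param lmax maximum (even) harmonic degree.
#' @return n x ((lmax+1)(lmax+2)/2) design matrix of basis values.
#' @export
sh_basis <- function(dirs, lmax = 8L) {
  if (lmax %% 2L != 0L) stop("lmax must be even")
  dirs <- matrix(dirs, ncol = 3L)
  ct <- pmin(1, pmax(-1, dirs[, 3]))           # cos(theta)
  phi <- atan2(dirs[, 2], dirs[, 1])
  P <- assoc_legendre(lmax, ct)                # list [[l]][[m+1]] vectors
  n <- nrow(dirs)
  out <- matrix(0, n, sh_ncoef(lmax))
  col <- 1L
  for (l in seq(0L, lmax, by = 2L)) {
    for (m in (-l):l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      p <- P[[l + 1L]][[am + 1L]]
      out[, col] <-
        if (m == 0) nrm * p
        else if (m > 0) sqrt(2) * nrm * p * cos(m * phi)
        else sqrt(2) * nrm * p * sin(am * phi)
      col <- col + 1L
    }
  }
  out
}

#' Number of even-degree SH coefficients up to lmax
#' @param lmax even maximum degree.
#' @export
sh_ncoef <- function(lmax) as.integer((lmax + 1) * (lmax + 2) / 2)

#' Degree l of each coefficient in the package's SH ordering
#' @param lmax even maximum degree.
#' @return integer vector of length [sh_ncoef()].
#' @export
sh_degrees <- function(lmax) {
  unlist(lapply(seq(0L, lmax, by = 2L), function(l) rep(l, 2L * l + 1L)))
}

# Associated Legendre P_l^m (Condon-Shortley phase) for all l <= lmax,
# m = 0..l, evaluated at vector x. Returns nested list [[l+1]][[m+1]].
assoc_legendre <- function(lmax, x) {
  s <- sqrt(pmax(0, 1 - x^2))
  P <- vector("list", lmax + 1L)
  for (l in 0:lmax) P[[l + 1L]] <- vector("list", l + 1L)
  P[[1L]][[1L]] <- rep(1, length(x))
  for (m in 0:lmax) {
    if (m > 0) {
      P[[m + 1L]][[m + 1L]] <-
        (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * s^m
    }
    if (m < lmax) {
      P[[m + 2L]][[m + 1L]] <- (2 * m + 1) * x * P[[m + 1L]][[m + 1L]]
      if (m + 2L <= lmax) {
        for (l in (m + 2L):lmax) {
          P[[l + 1L]][[m + 1L]] <-
            ((2 * l - 1) * x * P[[l]][[m + 1L]] -
               (l + m - 1) * P[[l - 1L]][[m + 1L]]) / (l - m)
        }
      }
    }
  }
  P
}

#' Zonal (m = 0) SH coefficients of an axially symmetric kernel
#'
#' Projects a function of the polar angle onto the m = 0 even-degree
#' harmonics by least squares on a dense latitude grid.
#'
#' @param fn function of cos(theta) returning kernel values.
#' @param lmax even maximum degree.
#' @param n_theta quadrature grid size.
#' @return numeric vector r_l, one value per even degree 0..lmax.
#' @export
zonal_coefficients <- function(fn, lmax = 8L, n_theta = 512L) {
  ct <- seq(-1, 1, length.out = n_theta)
  dirs <- cbind(sqrt(pmax(0, 1 - ct^2)), 0, ct)
  B <- sh_basis(dirs, lmax)
  m0 <- which(sh_m_orders(lmax) == 0L)
  stats::lm.fit(B[, m0, drop = FALSE], fn(ct))$coefficients
}

#' Order m of each coefficient in the package's SH ordering
#' @param lmax even maximum degree.
#' @export
sh_m_orders <- function(lmax) {
  unlist(lapply(seq(0L, lmax, by = 2L), function(l) (-l):l))
}

#' Per-coefficient convolution factors for an axially symmetric kernel
#'
#' By the spherical convolution theorem, convolving an FOD with a zonal
#' kernel multiplies each degree-l coefficient by
#' sqrt(4*pi/(2l+1)) * r_l.
#'
#' @param r_l zonal coefficients (one per even degree, from
#'   [zonal_coefficients()]).
#' @param lmax even maximum degree.
#' @return numeric vector of length [sh_ncoef()].
#' @export
convolution_factors <- function(r_l, lmax = 8L) {
  l <- sh_degrees(lmax)
  lev <- seq(0L, lmax, by = 2L)
  sqrt(4 * pi / (2 * l + 1)) * r_l[match(l, lev)]
}
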