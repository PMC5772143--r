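#' Subdivided-icosahedron unit sphere tessellation
#'
#' Returns an approximately uniform, centrally symmetric set of unit
#' vectors by subdividing the icosahedron `n_subdiv` times and projecting
#' onto the sphere (12, 42, 162, 642, ... vertices). Used as the dense
#' direction set for FOD amplitude evaluation, non-negativity constraints,
#' peak finding and probabilistic direction sampling.
#'
#' @param n_subdiv number of 4-fold face subdivisions (default 3, 642
#'   vertices).
#' @return list with `vertices` (V x 3 unit vectors) and `faces`
#'   (F x 3, 1-based vertex indices).
#' @export
icosphere <- function(n_subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(n_subdiv)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mid <- new.env(parent = emptyenv())
    get_mid <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
      nf[(i - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  list(vertices = v, faces = f)
}

#' Cached default direction set (642 vertices)
#' @keywords internal
default_sphere <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- icosphere(3L)
    cache
  }
})

#' Restrict a centrally symmetric direction set to one hemisphere
#'
#' Keeps directions whose first nonzero component (x, then y, then z) is
#' positive, i.e. one member of each antipodal pair.
#' @param vertices V x 3 unit vectors.
#' @return logical vector marking the retained member of each pair.
#' @keywords internal
hemisphere_mask <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]; z <- vertices[, 3]
  (x > 1e-8) | (abs(x) <= 1e-8 & y > 1e-8) |
    (abs(x) <= 1e-8 & abs(y) <= 1e-8 & z > 0)
}

#' Canonicalise unit vectors to a fixed hemisphere
#'
#' Flips each vector so its first nonzero component (x, then y, then z) is
#' positive, making antipodally equivalent directions comparable.
#' @param dirs n x 3 matrix.
#' @return n x 3 matrix.
#' @export
canonical_direction <- function(dirs) {
  dirs <- matrix(dirs, ncol = 3L)
  flip <- !hemisphere_mask(dirs)
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  dirs
}

#' Angle in degrees between unit vectors, ignoring sign (fibre convention)
#' @param a,b n x 3 matrices or single vectors (recycled).
#' @return numeric vector of angles between 0 and 90 degrees.
#' @export
fiber_angle <- function(a, b) {
  a <- matrix(a, ncol = 3L); b <- matrix(b, ncol = 3L)
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  d <- abs(rowSums(a * b)) /
    (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  acos(pmin(1, d)) * 180 / pi
}
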