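#' Diffusion gradient table
#'
#' Holds b-values (s/mm^2) and unit gradient directions. Directions with
#' b > 0 must be unit vectors (tolerance 1e-4); at least one b = 0 entry is
#' required so signals can be normalised.
#'
#' @param bvals numeric vector of b-values.
#' @param bvecs n x 3 matrix of gradient directions.
#' @return Object of class `gradient_table` with fields `bvals`, `bvecs`,
#'   `b0` (logical mask of b = 0 entries).
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- matrix(as.numeric(bvecs), ncol = 3L)
  if (length(bvals) != nrow(bvecs))
    stop("bvals and bvecs lengths differ")
  if (any(bvals < 0)) stop("negative b-value")
  nz <- bvals > 0
  if (any(nz)) {
    nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-4))
      stop("diffusion-weighted directions must be unit vectors (|norm - 1| <= 1e-4)")
  }
  if (!any(!nz))
    stop("gradient table needs at least one b = 0 entry")
  structure(list(bvals = bvals, bvecs = bvecs, b0 = !nz),
            class = "gradient_table")
}

#' @exportS3Method
print.gradient_table <- function(x, ...) {
  cat("gradient_table:", length(x$bvals), "entries (",
      sum(x$b0), "b=0,", sum(!x$b0), "weighted ), b =",
      paste(sort(unique(x$bvals[!x$b0])), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' Read / write FSL-dialect bvals/bvecs files
#'
#' `bvals` is one whitespace-separated row of b-values; `bvecs` is three
#' rows holding the x, y and z components.
#'
#' @param bvals_path,bvecs_path file paths.
#' @param gtab a [gradient_table()] for writing.
#' @return `read_gradient_table` returns a [gradient_table()].
#' @export
read_gradient_table <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE)
  comp <- strsplit(trimws(readLines(bvecs_path, warn = FALSE)), "\\s+")
  comp <- comp[vapply(comp, length, 1L) > 0L]
  if (length(comp) != 3L) stop("bvecs file must have three rows")
  vec <- lapply(comp, as.numeric)
  if (length(unique(vapply(vec, length, 1L))) != 1L ||
      length(vec[[1]]) != length(bvals))
    stop("bvals/bvecs length mismatch")
  gradient_table(bvals, cbind(vec[[1]], vec[[2]], vec[[3]]))
}

#' @rdname read_gradient_table
#' @export
write_gradient_table <- function(gtab, bvals_path, bvecs_path) {
  writeLines(paste(format(gtab$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bvals_path)
  rows <- apply(t(gtab$bvecs), 1L, function(r)
    paste(sprintf("%.10g", r), collapse = " "))
  writeLines(rows, bvecs_path)
  invisible(NULL)
}

#' Two-session single-shell acquisition scheme
#'
#' Builds the default acquisition emulated throughout the package: 64
#' approximately uniform diffusion directions at one b-value plus two
#' b = 0 volumes.
#'
#' @param n_dirs number of diffusion-weighted directions.
#' @param bval shell b-value (s/mm^2).
#' @param n_b0 number of unweighted volumes (prepended).
#' @return A [gradient_table()] of length `n_b0 + n_dirs`.
#' @export
default_gradient_table <- function(n_dirs = 64L, bval = 1000, n_b0 = 2L) {
  dirs <- fibonacci_sphere(n_dirs)
  gradient_table(c(rep(0, n_b0), rep(bval, n_dirs)),
                 rbind(matrix(0, n_b0, 3L), dirs))
}

#' Approximately uniform unit vectors by the Fibonacci spiral
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
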