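#' Tractogram: a set of streamlines in scanner (mm) space
#'
#' Streamlines are ordered 3D point sequences (n_i x 3 matrices, mm).
#' `provenance` records how they were generated (step size, angular
#' threshold, stop amplitude, seed count, RNG seed, ...).
#'
#' @param streamlines list of n x 3 numeric matrices, each with >= 2 rows.
#' @param provenance named list of generation parameters.
#' @return Object of class `tractogram`.
#' @export
tractogram <- function(streamlines = list(), provenance = list()) {
  streamlines <- lapply(streamlines, function(s) {
    s <- matrix(as.numeric(s), ncol = 3L)
    if (nrow(s) < 2L) stop("each streamline needs >= 2 points")
    s
  })
  structure(list(streamlines = streamlines, provenance = provenance),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @exportS3Method
print.tractogram <- function(x, ...) {
  n <- length(x)
  cat("tractogram:", n, "streamlines")
  if (n) {
    len <- streamline_lengths(x)
    cat(sprintf("; length %.1f-%.1f mm (mean %.1f)",
                min(len), max(len), mean(len)))
  }
  cat("\n")
  invisible(x)
}

#' Subset a tractogram, keeping provenance
#' @param x a [tractogram()]; @param idx integer or logical index.
#' @export
subset_tractogram <- function(x, idx) {
  tractogram(x$streamlines[idx], x$provenance)
}

#' Arc lengths of all streamlines (mm)
#' @param x a [tractogram()] or list of point matrices.
#' @return numeric vector of polyline arc lengths.
#' @export
streamline_lengths <- function(x) {
  sl <- if (inherits(x, "tractogram")) x$streamlines else x
  vapply(sl, function(s) sum(sqrt(rowSums(diff(s)^2))), numeric(1))
}

#' Terminal points of every streamline
#' @param x a [tractogram()].
#' @return (2n) x 3 matrix: first and last point of each streamline.
#' @export
streamline_endpoints <- function(x) {
  sl <- x$streamlines
  if (!length(sl)) return(matrix(numeric(0), ncol = 3L))
  do.call(rbind, lapply(sl, function(s) s[c(1L, nrow(s)), , drop = FALSE]))
}

#' Resample a polyline to n equidistant nodes by arc length
#' @param s n x 3 matrix; @param n number of output nodes.
#' @return n x 3 matrix with the same endpoints.
#' @export
resample_streamline <- function(s, n = 100L) {
  d <- c(0, cumsum(sqrt(rowSums(diff(s)^2))))
  total <- d[length(d)]
  if (total <= 0) return(matrix(rep(s[1L, ], n), ncol = 3L, byrow = TRUE))
  at <- seq(0, total, length.out = n)
  apply(s, 2L, function(col) stats::approx(d, col, xout = at)$y)
}

# ---- TCK ------------------------------------------------------------------

#' Read / write MRtrix TCK streamline files
#'
#' TCK is the canonical streamline format here: a text header followed by
#' little-endian Float32 triplets in scanner (mm) space, streamlines
#' separated by NaN triplets and the file terminated by an Inf triplet.
#' An empty file (zero streamlines) reads as an empty tractogram with a
#' warning.
#'
#' @param path file path.
#' @param tract a [tractogram()] for writing.
#' @return `read_tck` returns a [tractogram()].
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!grepl("^mrtrix tracks", first)) stop("not a TCK file: ", path)
  offset <- NULL
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || ln == "END") break
    if (grepl("^file:", ln))
      offset <- as.integer(sub("^file:\\s*\\.\\s*", "", ln))
    if (grepl("^datatype:", ln) &&
        trimws(sub("^datatype:", "", ln)) != "Float32LE")
      stop("unsupported TCK datatype: ", ln)
  }
  if (is.null(offset)) stop("TCK header lacks file offset")
  seek(con, offset)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L,
                 endian = "little")
  pts <- matrix(raw, ncol = 3L, byrow = TRUE)
  streamlines <- list()
  fin <- rowSums(is.finite(pts)) < 3L
  breaks <- which(fin)
  start <- 1L
  for (b in breaks) {
    if (b > start) streamlines[[length(streamlines) + 1L]] <-
        pts[start:(b - 1L), , drop = FALSE]
    if (any(is.infinite(pts[b, ]))) break
    start <- b + 1L
  }
  if (!length(streamlines)) {
    warning("TCK file contains zero streamlines")
    return(tractogram())
  }
  tractogram(streamlines)
}

#' @rdname read_tck
#' @export
write_tck <- function(tract, path) {
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           paste0("count: ", length(tract)),
           "file: . OFFSET",
           "END")
  # compute byte offset with the placeholder replaced by its final width
  fix <- function(off) sub("OFFSET", off, hdr, fixed = TRUE)
  off <- sum(nchar(fix(0L), type = "bytes") + 1L)
  repeat {
    off2 <- sum(nchar(fix(off), type = "bytes") + 1L)
    if (off2 == off) break
    off <- off2
  }
  hdr <- fix(off)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  nan3 <- rep(NaN, 3L)
  for (s in tract$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(nan3, con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

# ---- TRK (read-only) ------------------------------------------------------

#' Read a TrackVis TRK file (read-only support)
#'
#' Points are converted from TRK's corner-origin "voxmm" convention to
#' scanner mm via the stored voxel-to-RAS matrix (identity scaling if the
#' header carries none). Scalars and properties are discarded.
#'
#' @param path file path.
#' @return A [tractogram()].
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, "raw", 5L))
  readBin(con, "raw", 1L)
  if (!identical(id, "TRACK")) stop("not a TRK file: ", path)
  dim3 <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  voxel_size <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")  # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  m <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
              4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 6L * 4L + 2L + 6L)
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # n_count
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # version
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L) stop("unexpected TRK header size: ", hdr_size)
  if (all(m == 0)) m <- diag(c(voxel_size, 1))
  streamlines <- list()
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(npts)) break
    vals <- readBin(con, "numeric", npts * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_props > 0L) readBin(con, "numeric", n_props, size = 4L,
                              endian = "little")
    p <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(p, 2L, voxel_size, "/") - 0.5  # center-based voxel index
    ras <- t(m[1:3, 1:3] %*% t(vox) + m[1:3, 4])
    streamlines[[length(streamlines) + 1L]] <- ras
  }
  if (!length(streamlines)) {
    warning("TRK file contains zero streamlines")
    return(tractogram())
  }
  tractogram(streamlines)
}
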