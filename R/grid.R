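#' Image grid: shape, voxel size and voxel-to-mm affine
#'
#' An `image_grid` ties a 3D voxel lattice to scanner (mm) space. Voxel
#' indices are 0-based and a voxel's mm position is its *center* under the
#' affine, matching the TCK streamline convention so that point-to-voxel
#' distances are well defined.
#'
#' @param shape integer vector of 3 positive extents (voxels).
#' @param voxel_size numeric scalar or length-3 vector, mm per axis.
#' @param affine optional 4x4 voxel-index-to-mm matrix; defaults to a
#'   diagonal scaling by `voxel_size` with zero origin.
#' @return An object of class `image_grid` with fields `shape`, `voxel_size`
#'   and `affine`.
#' @export
image_grid <- function(shape, voxel_size = 1, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L))
    stop("`shape` must be 3 positive integers")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be positive (scalar or length 3)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("`affine` must be an invertible 4x4 matrix")
  cn <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (max(abs(cn - voxel_size)) > 1e-6 * max(voxel_size))
    stop("`voxel_size` inconsistent with affine column norms")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 affine = affine),
            class = "image_grid")
}

#' @exportS3Method
print.image_grid <- function(x, ...) {
  cat("image_grid:", paste(x$shape, collapse = " x "),
      "voxels,", paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Map 0-based voxel indices to mm coordinates (voxel centers)
#'
#' @param grid an [image_grid()].
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  t(grid$affine[1:3, 1:3] %*% t(ijk) + grid$affine[1:3, 4])
}

#' Map mm coordinates to (fractional) 0-based voxel indices
#'
#' @inheritParams voxel_to_mm
#' @param xyz n x 3 matrix of mm coordinates.
#' @export
mm_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  inv <- solve(grid$affine)
  t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4])
}

#' mm coordinates of every voxel center of a grid
#' @param grid an [image_grid()].
#' @return (prod(shape)) x 3 matrix in array (column-major) voxel order.
#' @export
grid_centers <- function(grid) {
  idx <- as.matrix(expand.grid(i = 0:(grid$shape[1] - 1L),
                               j = 0:(grid$shape[2] - 1L),
                               k = 0:(grid$shape[3] - 1L)))
  voxel_to_mm(grid, idx)
}

#' Scalar, vector-valued or 4D volume on an image grid
#'
#' @param grid an [image_grid()].
#' @param data array whose first three dimensions equal `grid$shape`
#'   (a 3D array, or 4D with a trailing signal/series axis).
#' @return Object of class `volume`.
#' @export
volume <- function(grid, data) {
  data <- as.array(data)
  d <- dim(data)
  if (length(d) < 3L || !all(d[1:3] == grid$shape))
    stop("data leading dimensions must equal grid shape")
  structure(list(grid = grid, data = data), class = "volume")
}

#' @exportS3Method
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat("volume:", paste(d, collapse = " x "), "\n")
  invisible(x)
}

#' Integer label volume with a label-name map
#'
#' @param grid an [image_grid()].
#' @param labels 3D array of non-negative integer labels.
#' @param names named character vector or list mapping label value
#'   (as character) to region name; every nonzero label must be named.
#' @return Object of class `label_volume` (also a `volume`).
#' @export
label_volume <- function(grid, labels, names = NULL) {
  labels <- array(as.integer(labels), dim = dim(as.array(labels)))
  if (any(labels < 0L)) stop("labels must be non-negative")
  v <- volume(grid, labels)
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (is.null(names)) names <- stats::setNames(as.character(present), present)
  nm <- unlist(names)
  missing <- setdiff(as.character(present), base::names(nm))
  if (length(missing))
    stop("unnamed labels: ", paste(missing, collapse = ", "))
  structure(list(grid = grid, data = v$data, names = nm),
            class = c("label_volume", "volume"))
}

#' mm centers of the voxels carrying a given label (or any nonzero label)
#'
#' @param lab a [label_volume()].
#' @param which label value(s) to select; `NULL` selects all nonzero voxels.
#' @return n x 3 matrix of voxel-center mm coordinates.
#' @export
label_centers <- function(lab, which = NULL) {
  m <- if (is.null(which)) lab$data != 0L else array(lab$data %in% which, dim = dim(lab$data))
  idx <- which(m, arr.ind = TRUE) - 1
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 3L))
  voxel_to_mm(lab$grid, idx)
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers over RNifti preserving data and the voxel-to-mm affine.
#' The stored affine maps 0-based voxel indices to mm.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol a [volume()] (or [label_volume()]) for writing.
#' @return `read_volume` returns a [volume()]; `write_volume` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  aff <- rbind(cbind(aff[1:3, 1:3], aff[1:3, 4]), c(0, 0, 0, 1))
  if (abs(det(aff)) < 1e-12) stop("volume has a singular affine")
  d <- dim(img)
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  g <- image_grid(d[1:3], vs, aff)
  volume(g, array(as.numeric(img), dim = d))
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$grid$voxel_size
  RNifti::sform(img) <- structure(vol$grid$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a 4x4 affine as plain text
#'
#' Four whitespace-separated numbers per row; used for subject-to-template
#' normalisation matrices.
#' @param path file path.
#' @param affine 4x4 matrix for writing.
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(4L, 4L))) stop("affine file must be 4x4")
  m
}

#' @rdname read_affine
#' @export
write_affine <- function(affine, path) {
  utils::write.table(affine, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
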