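#' Voxel grid container
#'
#' A 3-D scalar field on a regular grid, ordered `(slice, row, col)` with
#' spacing in millimetres. Slice index increases superior to inferior, row
#' index anterior to posterior; this orientation convention is fixed for the
#' whole package. Grids carry structure masks (0/1 values), distance maps
#' (mm) and dose maps (fraction of the prescription dose, 1.0 = 70 Gy).
#'
#' @param values numeric 3-D array, dimension `(n_slices, n_rows, n_cols)`.
#' @param spacing numeric length-3, `(slice_mm, row_mm, col_mm)`, all > 0.
#' @return an object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 16, 16)), spacing = c(3, 3, 3))
#' dim(g$values)
#' @export
voxel_grid <- function(values, spacing = c(3, 3, 3)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_validation("values must be a 3-D array (slice, row, col)")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_validation("spacing must be 3 strictly positive numbers (mm)")
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d slices x %d rows x %d cols, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

grid_dim <- function(g) dim(g$values)

# matrix (rows x cols) for one slice
grid_slice <- function(g, s) g$values[s, , , drop = TRUE]

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol)
}

# full 3-D diagonal length in mm; cap for undefined distances
grid_diagonal <- function(g) {
  d <- dim(g$values)
  sqrt(sum((d * g$spacing)^2))
}

#' Write a voxel grid to a NIfTI-1 file
#'
#' Grids are stored with on-disk axis order `(row, col, slice)` (the NIfTI
#' in-plane dimensions first) and spacing preserved in the header `pixdim`.
#' `read_grid()` restores the package's `(slice, row, col)` internal order.
#'
#' @param grid a [voxel_grid].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_grid <- function(grid, path) {
  if (!is_voxel_grid(grid)) stop_validation("grid must be a voxel_grid")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write grid: directory does not exist: ", dir)
  disk <- aperm(grid$values, c(2, 3, 1))
  img <- RNifti::asNifti(disk)
  RNifti::pixdim(img) <- grid$spacing[c(2, 3, 1)]
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a voxel grid from a NIfTI-1 file
#'
#' @param path NIfTI-1 file written by [write_grid()] (or any 3-D NIfTI with
#'   in-plane dimensions first).
#' @param in_plane expected `(rows, cols)` shape; the default enforces the
#'   model's 128 x 128 transverse resolution. Pass `NULL` to accept any
#'   in-plane shape (used for reduced-resolution studies).
#' @return a [voxel_grid].
#' @export
read_grid <- function(path, in_plane = c(128, 128)) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to parse NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop_validation("expected a 3-D NIfTI volume, got ", length(dim(a)), "-D")
  if (!is.null(in_plane) && !all(dim(a)[1:2] == in_plane))
    stop_validation(sprintf("in-plane shape %dx%d does not match expected %dx%d",
                            dim(a)[1], dim(a)[2], in_plane[1], in_plane[2]))
  pd <- RNifti::pixdim(img)[1:3]
  voxel_grid(aperm(a, c(3, 1, 2)), spacing = pd[c(3, 1, 2)])
}
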