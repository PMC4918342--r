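#' 3D image stacks with physical voxel calibration
#'
#' An `image_stack` wraps a 3D array of nonnegative intensities indexed
#' `[x, y, z]` together with its voxel size in nm. The physical center of
#' voxel `i` along an axis with voxel size `v` is `(i - 0.5) * v` (1-based
#' indices), so coordinates are continuous nm positions within the field.
#'
#' @param data numeric 3D array, dimensions (nx, ny, nz).
#' @param voxel_nm numeric length-3 voxel size (dx, dy, dz) in nm;
#'   dx must equal dy (square pixels), defaults 56, 56, 200.
#' @param channel channel label.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_nm = c(56, 56, 200), channel = "ch1") {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (any(dim(data) < 1L)) stop("zero-size stack")
  stopifnot(length(voxel_nm) == 3L, all(voxel_nm > 0))
  if (abs(voxel_nm[1] - voxel_nm[2]) > 1e-9)
    stop("pixels must be square in XY (dx == dy)")
  structure(list(data = data, voxel_nm = as.numeric(voxel_nm),
                 channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack '%s': %d x %d x %d voxels @ (%g, %g, %g) nm\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_nm[1], x$voxel_nm[2], x$voxel_nm[3]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Physical voxel-center coordinates of a stack axis
#' @param stack an `image_stack`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of nm center positions.
#' @export
voxel_centers <- function(stack, axis) {
  (seq_len(dim(stack$data)[axis]) - 0.5) * stack$voxel_nm[axis]
}

#' Write / read a stack as multi-page TIFF
#'
#' Pages are z-planes; intensities are stored as 32-bit floats. Voxel
#' calibration is not carried by the file and must be supplied on read.
#'
#' @param stack an `image_stack`.
#' @param path file path.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  mx <- max(stack$data, 1)
  ## tiff::writeTIFF wants [row, col] = [y, x] in 0..1 for float storage
  pages <- lapply(seq_len(d[3]), function(z) t(stack$data[, , z]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  ## store the scale so read_stack_tiff can undo the normalization
  writeLines(as.character(mx), paste0(path, ".scale"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param voxel_nm voxel size to attach on read.
#' @param channel channel label to attach on read.
#' @export
read_stack_tiff <- function(path, voxel_nm = c(56, 56, 200), channel = "ch1") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mx <- 1
  sc <- paste0(path, ".scale")
  if (file.exists(sc)) mx <- as.numeric(readLines(sc)[1])
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]]) * mx
  image_stack(arr, voxel_nm = voxel_nm, channel = channel)
}
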