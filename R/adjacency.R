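#' Voxel adjacency graph of a grid or mask
#'
#' Builds the neighbor structure used by the spatially constrained
#' clustering routines: voxels are adjacent when they differ by one along
#' exactly one axis (4-connectivity in 2D, 6-connectivity in 3D) and both
#' fall inside the mask.
#'
#' @param grid_shape integer vector of image dimensions (used when `mask`
#'   is missing; all cells are then in-mask).
#' @param mask optional logical array; voxels are its `TRUE` cells, indexed
#'   in column-major order.
#'
#' @return An object of class `parcel_adjacency`: a list with `edges`
#'   (E x 2 integer matrix, first column < second column), `n_vertices`,
#'   `coords` (voxel array indices) and `dims`.
#' @export
#' @examples
#' grid_adjacency(c(3, 3))$edges  # 12 edges
grid_adjacency <- function(grid_shape = NULL, mask = NULL) {
  if (is.null(mask)) {
    if (is.null(grid_shape))
      stop_bad_arg("provide `grid_shape` or `mask`")
    mask <- array(TRUE, dim = as.integer(grid_shape))
  }
  dims <- dim(mask)
  if (is.null(dims)) dims <- length(mask)
  vox <- which(mask)
  if (length(vox) == 0L) stop_bad_arg("mask is empty")
  idx_of <- array(0L, dim = dims)
  idx_of[vox] <- seq_along(vox)

  stride <- cumprod(c(1L, dims[-length(dims)]))
  edges <- vector("list", length(dims))
  for (a in seq_along(dims)) {
    ok <- which(slice.index(mask, a) < dims[a] & mask)
    partner <- ok + stride[a]
    keep <- mask[partner]
    edges[[a]] <- cbind(idx_of[ok[keep]], idx_of[partner[keep]])
  }
  edges <- do.call(rbind, edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  structure(
    list(edges = edges, n_vertices = length(vox),
         coords = arrayInd(vox, dims), dims = dims),
    class = "parcel_adjacency"
  )
}

#' @export
print.parcel_adjacency <- function(x, ...) {
  cat(sprintf("<parcel_adjacency> %d voxels, %d edges (%s grid)\n",
              x$n_vertices, nrow(x$edges),
              paste(x$dims, collapse = " x ")))
  invisible(x)
}

# Adjacency matching a signal's grid (2D/3D full grid).
default_adjacency <- function(signal) {
  if (is.null(signal$grid_shape))
    stop_bad_arg("signal has no grid_shape; supply `adjacency` explicitly")
  grid_adjacency(signal$grid_shape)
}
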