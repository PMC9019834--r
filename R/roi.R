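#' Default mentalizing + reward ROI set
#'
#' Fourteen 5 mm spheres in MNI space: seven mentalizing-network nodes
#' (dmPFC, vmPFC, precuneus, bilateral TPJ, bilateral ATL) and seven
#' reward-network nodes (left OFC, right vmPFC, ACC, bilateral ventral
#' striatum, bilateral amygdala), all spatially non-overlapping.
#'
#' @return Data frame: name, network, x, y, z (mm), radius (mm).
#' @export
default_rois <- function() {
  df <- data.frame(
    name = c("dmPFC", "vmPFC", "PC", "L TPJ", "R TPJ", "L ATL", "R ATL",
             "L OFC", "R vmPFC", "ACC", "L VS", "R VS",
             "L Amygdala", "R Amygdala"),
    network = rep(c("mentalizing", "reward"), each = 7),
    x = c(0, 0, 0, -48, 48, -53, 53, -22, 2, 2, -12, 12, -20, 24),
    y = c(53, 48, -54, -56, -56, -12, -12, 36, 58, 32, 10, 10, -2, -2),
    z = c(30, -18, 44, 23, 23, -16, -16, -14, -8, 16, -8, -8, -14, -18),
    radius = 5,
    stringsAsFactors = FALSE
  )
  validate_rois(df)
}

#' Validate an ROI specification table
#'
#' Checks required columns, unique names, and pairwise sphere
#' non-overlap (center distance > 2 * radius) within the node set;
#' overlaps raise a warning unless `strict`.
#'
#' @param rois Data frame with columns name, network, x, y, z, radius.
#' @param strict If `TRUE`, overlapping spheres are an error.
#' @return The validated table, invisibly unchanged.
#' @export
validate_rois <- function(rois, strict = FALSE) {
  need <- c("name", "network", "x", "y", "z", "radius")
  if (!all(need %in% names(rois)))
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(rois$name)) stop("ROI names must be unique")
  xyz <- as.matrix(rois[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  lim <- outer(rois$radius, rois$radius, `+`)
  bad <- which(d <= lim & upper.tri(d), arr.ind = TRUE)
  if (nrow(bad)) {
    msg <- paste0("overlapping ROI spheres: ",
                  paste(rois$name[bad[, 1]], "/", rois$name[bad[, 2]],
                        collapse = "; "))
    if (strict) stop(msg) else warning(msg)
  }
  rois
}

#' Build a regular voxel grid covering a set of ROI spheres
#'
#' Axis-aligned grid of voxel centers (default 2 mm isotropic) covering
#' all spheres with a margin; used by the optional voxel-level mode.
#'
#' @param rois ROI table.
#' @param spacing Voxel size, mm (default 2).
#' @param margin Margin beyond sphere extents, mm.
#' @return Matrix of voxel center coordinates `n_voxels x 3`, restricted
#'   to voxels inside at least one sphere.
#' @export
roi_voxel_grid <- function(rois, spacing = 2, margin = 2) {
  rng <- function(v, r) c(min(v - r) - margin, max(v + r) + margin)
  gx <- seq(rng(rois$x, rois$radius)[1], rng(rois$x, rois$radius)[2], spacing)
  gy <- seq(rng(rois$y, rois$radius)[1], rng(rois$y, rois$radius)[2], spacing)
  gz <- seq(rng(rois$z, rois$radius)[1], rng(rois$z, rois$radius)[2], spacing)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  keep <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(rois))) {
    d2 <- (grid[, 1] - rois$x[i])^2 + (grid[, 2] - rois$y[i])^2 +
      (grid[, 3] - rois$z[i])^2
    keep <- keep | d2 <= rois$radius[i]^2
  }
  grid[keep, , drop = FALSE]
}

#' Average voxel time series within ROI spheres
#'
#' Means over the voxels whose centers lie within each ROI's radius
#' (Euclidean distance) of its center.
#'
#' @param voxel_data Matrix `n_voxels x time` (or `time x n_voxels` with
#'   `time_in_rows = TRUE`).
#' @param coords Matrix `n_voxels x 3` of voxel center coordinates, mm.
#' @param rois ROI table (see [default_rois()]).
#' @param time_in_rows Set `TRUE` when `voxel_data` is time x voxels.
#' @return Matrix `time x n_rois` with ROI names as columns.
#' @export
extract_roi_series <- function(voxel_data, coords, rois,
                               time_in_rows = FALSE) {
  voxel_data <- as.matrix(voxel_data)
  if (time_in_rows) voxel_data <- t(voxel_data)
  if (nrow(voxel_data) != nrow(coords))
    stop("voxel_data and coords disagree on the number of voxels")
  out <- matrix(NA_real_, ncol(voxel_data), nrow(rois),
                dimnames = list(NULL, rois$name))
  for (i in seq_len(nrow(rois))) {
    d2 <- (coords[, 1] - rois$x[i])^2 + (coords[, 2] - rois$y[i])^2 +
      (coords[, 3] - rois$z[i])^2
    inside <- d2 <= rois$radius[i]^2
    if (!any(inside))
      stop("empty sphere: no voxel centers within ", rois$radius[i],
           " mm of ROI '", rois$name[i], "'")
    out[, i] <- colMeans(voxel_data[inside, , drop = FALSE])
  }
  out
}
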