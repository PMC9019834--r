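na_chr <- function(x) ifelse(is.na(x), "n/a", x)

#' Write / read BIDS-style events tables
#'
#' One row per Guess or Feedback event with columns onset, duration,
#' trial_type, response_time (seconds, 3 decimals, `n/a` for missing) and
#' accuracy (0/1 for Guess rows).
#'
#' @param events Event table (one run) with optional `accuracy`.
#' @param path Output .tsv path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(
    onset = sprintf("%.3f", events$onset),
    duration = sprintf("%.3f", events$duration),
    trial_type = events$trial_type,
    response_time = na_chr(sprintf("%.3f", events$response_time)),
    stringsAsFactors = FALSE
  )
  out$response_time[is.na(events$response_time)] <- "n/a"
  if (!is.null(events$accuracy))
    out$accuracy <- na_chr(as.character(as.integer(events$accuracy)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, na.strings = "n/a"),
    error = function(e) stop("parse error in events file ", path, ": ",
                             conditionMessage(e)))
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("parse error in events file ", path, ": missing columns ",
         paste(setdiff(need, names(ev)), collapse = ", "))
  for (col in c("onset", "duration", "response_time")) {
    if (!col %in% names(ev)) next
    v <- suppressWarnings(as.numeric(ev[[col]]))
    bad <- which(is.na(v) & !is.na(ev[[col]]))
    if (length(bad))
      stop("parse error in events file ", path, ", line ", bad[1] + 1,
           ": non-numeric ", col)
    ev[[col]] <- v
  }
  ev
}

#' Write / read 6-column motion parameter files
#'
#' Whitespace-delimited text, one row per volume: x/y/z translations (mm)
#' then three rotations (radians).
#'
#' @param motion Matrix `volumes x 6`.
#' @param path Output path.
#' @return `path` (write) or the motion matrix (read).
#' @export
write_motion_txt <- function(motion, path) {
  write.table(format(motion, digits = 8, scientific = FALSE), path,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_txt
#' @export
read_motion_txt <- function(path) {
  m <- as.matrix(read.table(path))
  if (ncol(m) != 6) stop("motion file ", path, " must have 6 columns")
  dimnames(m) <- list(NULL, c("trans_x", "trans_y", "trans_z",
                              "rot_x", "rot_y", "rot_z"))
  m
}

#' Write / read ROI BOLD as TSV (rows = volumes, columns = ROI labels)
#'
#' @param bold Matrix `volumes x ROI`.
#' @param path Output path.
#' @return `path` (write) or the matrix (read).
#' @export
write_bold_tsv <- function(bold, path) {
  write.table(bold, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bold_tsv
#' @export
read_bold_tsv <- function(path) {
  as.matrix(read.delim(path, check.names = FALSE))
}

#' Write voxel BOLD as NIfTI-1 volumes (optional voxel mode)
#'
#' Rasterizes sphere voxels onto their bounding grid and writes a 4D
#' NIfTI image per run. Requires the RNifti package.
#'
#' @param voxel Voxel data from [generate_bold()] (`data`, `coords`).
#' @param path Output .nii path (one run).
#' @param run Run index into `voxel$data`.
#' @param spacing Grid spacing in mm (default 2).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(voxel, path, run = 1, spacing = 2) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("voxel NIfTI output requires the RNifti package")
  co <- voxel$coords
  mins <- apply(co, 2, min)
  ijk <- sweep(co, 2, mins) / spacing + 1
  dims <- apply(ijk, 2, max)
  nt <- ncol(voxel$data[[run]])
  arr <- array(0, c(dims, nt))
  for (v in seq_len(nrow(ijk)))
    arr[ijk[v, 1], ijk[v, 2], ijk[v, 3], ] <- voxel$data[[run]][v, ]
  img <- RNifti::asNifti(arr, pixdim = c(rep(spacing, 3), 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ROI configuration table
#'
#' Tab- or comma-separated file with columns name, network, x, y, z,
#' radius (radius optional, default 5 mm).
#'
#' @param path File path.
#' @return Validated ROI table.
#' @export
read_roi_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (is.null(df$radius)) df$radius <- 5
  validate_rois(df)
}
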