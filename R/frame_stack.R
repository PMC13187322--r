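#' Multi-channel time-lapse image stack
#'
#' The central data container of the pipeline: a non-negative intensity
#' array indexed `(frame, channel, y, x)` together with the biological role
#' of each channel and the physical calibration of the acquisition.
#'
#' Channel roles name what each channel images:
#' * `membrane_reference` -- an evenly distributed plasma-membrane marker
#'   (SNAP-CAAX) used as the normalisation reference,
#' * `receptor` -- the chimeric antigen receptor (HER2-CAR-GFP) whose
#'   clustering is quantified,
#' * `protein` -- a Halo-tagged protein of interest (e.g. ZAP-70, LAT, CD45),
#' * `target` -- the target-cell stain (CellMaskOrange on SK-BR-3 cells).
#'
#' @param data numeric array. A 4-D array `(frame, channel, y, x)`; a matrix
#'   is promoted to a single-frame single-channel stack.
#' @param channel_roles named integer vector mapping role name to 1-based
#'   channel index, e.g. `c(membrane_reference = 1, receptor = 2)`. Roles and
#'   indices must be unique and within range.
#' @param pixel_size_nm physical pixel pitch in nanometres (default 70, the
#'   confocal calibration of the study design this pipeline targets).
#' @param frame_interval_s seconds between frames (4 or 15 in typical use).
#' @return An object of class `"frame_stack"`.
#' @export
frame_stack <- function(data, channel_roles, pixel_size_nm = 70,
                        frame_interval_s = 4) {
  if (is.matrix(data)) {
    dim(data) <- c(1L, 1L, nrow(data), ncol(data))
  }
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("data must be a 4-D array (frame, channel, y, x) or a matrix")
  if (any(!is.finite(data))) stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be >= 0")
  nc <- dim(data)[2]
  roles <- validate_roles(channel_roles, nc)
  stopifnot(is.numeric(pixel_size_nm), pixel_size_nm > 0,
            is.numeric(frame_interval_s), frame_interval_s > 0)
  structure(list(data = data, channel_roles = roles,
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s),
            class = "frame_stack")
}

validate_roles <- function(channel_roles, n_channels) {
  if (is.null(names(channel_roles)) || any(names(channel_roles) == ""))
    stop("channel_roles must be a named vector (role = channel index)")
  roles <- vapply(channel_roles, as.integer, 1L)
  known <- c("membrane_reference", "receptor", "protein", "target")
  bad <- setdiff(names(roles), known)
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(roles)) || anyDuplicated(roles))
    stop("channel roles and channel indices must be unique")
  if (any(roles < 1L) || any(roles > n_channels))
    stop("channel role maps to channel ", paste(roles[roles > n_channels],
         collapse = ","), " but the stack has ", n_channels, " channel(s)")
  roles
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("frame_stack: %d frame(s), %d channel(s), %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  pixel size %g nm, frame interval %g s\n",
              x$pixel_size_nm, x$frame_interval_s))
  cat("  roles:", paste(sprintf("%s=%d", names(x$channel_roles),
                                x$channel_roles), collapse = ", "), "\n")
  invisible(x)
}

#' @export
n_frames <- function(stack) dim(stack$data)[1]

#' @export
n_channels <- function(stack) dim(stack$data)[2]

#' Extract one channel plane of one frame
#'
#' @param stack a [frame_stack].
#' @param role channel role name.
#' @param frame 1-based frame index.
#' @return numeric matrix `[y, x]`.
#' @export
get_channel <- function(stack, role, frame = 1L) {
  if (!role %in% names(stack$channel_roles))
    stop("stack has no channel with role '", role, "'")
  ch <- stack$channel_roles[[role]]
  stack$data[frame, ch, , , drop = TRUE]
}

#' Pixelwise average of selected channels
#'
#' The segmentation image of the pipeline is the mean of the membrane
#' reference and receptor channels; with a single role the corresponding
#' channel is returned verbatim (segmenting on the receptor channel alone).
#'
#' @param stack a [frame_stack].
#' @param roles character vector of roles to average (non-empty).
#' @param frame 1-based frame index.
#' @return numeric matrix `[y, x]`.
#' @export
average_channels <- function(stack, roles, frame = 1L) {
  if (length(roles) == 0L) stop("roles must be non-empty")
  missing_roles <- setdiff(roles, names(stack$channel_roles))
  if (length(missing_roles))
    stop("unknown role(s): ", paste(missing_roles, collapse = ", "))
  acc <- NULL
  for (r in roles) {
    p <- get_channel(stack, r, frame)
    acc <- if (is.null(acc)) p else acc + p
  }
  acc / length(roles)
}

#' Read a TIFF file into a frame stack
#'
#' Pages are interpreted channel-fastest (`frame 1 channel 1, frame 1
#' channel 2, ..., frame 2 channel 1, ...`), the layout produced by
#' decomposing an ImageJ hyperstack.
#'
#' @param path multi-page TIFF path.
#' @param channel_roles named integer vector, see [frame_stack()].
#' @param n_channels number of channels in the file; defaults to the
#'   largest declared channel index.
#' @param pixel_size_nm,frame_interval_s physical calibration.
#' @return A [frame_stack].
#' @export
read_stack <- function(path, channel_roles,
                       n_channels = max(as.integer(channel_roles)),
                       pixel_size_nm = 70, frame_interval_s = 4) {
  pages <- read_tiff(path)
  roles <- validate_roles(channel_roles, n_channels)
  np <- length(pages)
  if (np %% n_channels != 0L)
    stop("page count (", np, ") is not a multiple of the declared channel ",
         "count (", n_channels, ")")
  nf <- np %/% n_channels
  dims <- vapply(pages, dim, c(0L, 0L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all TIFF pages must share identical spatial dimensions")
  arr <- array(0, dim = c(nf, n_channels, dims[1, 1], dims[2, 1]))
  for (f in seq_len(nf))
    for (ch in seq_len(n_channels))
      arr[f, ch, , ] <- pages[[(f - 1L) * n_channels + ch]]
  frame_stack(arr, roles, pixel_size_nm, frame_interval_s)
}

#' Write a frame stack to a multi-page float TIFF
#'
#' Pages are written channel-fastest, the layout [read_stack()] consumes.
#'
#' @param stack a [frame_stack].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (f in seq_len(d[1]))
    for (ch in seq_len(d[2])) {
      k <- k + 1L
      pages[[k]] <- stack$data[f, ch, , , drop = TRUE]
    }
  write_tiff(pages, path, dtype = "float")
}

#' Write binary masks as an 8-bit TIFF (0/255)
#'
#' @param masks a logical matrix or list of logical matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(masks, path) {
  if (is.matrix(masks)) masks <- list(masks)
  pages <- lapply(masks, function(m) {
    storage.mode(m) <- "numeric"
    m * 255
  })
  write_tiff(pages, path, dtype = "uint8")
}
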