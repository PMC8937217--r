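#' Generate ROI masks for a synthetic field of view
#'
#' Places one small disk mask per ROI at random positions, keeping a margin
#' from the border so masks always fit inside the field of view.
#'
#' @param config a \code{\link{sim_config}}.
#' @param radius_px mask radius in pixels.
#' @param seed optional integer overriding \code{config$seed + 2}.
#' @return a \code{roi_mask_set}: named list of integer matrices with
#'   columns \code{row}, \code{col} (1-based pixel coordinates), one per
#'   ROI, plus a \code{centroids} attribute.
#' @export
make_roi_masks <- function(config, radius_px = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed) else set.seed(config$seed + 2L)
  h <- config$fov_shape[1]; w <- config$fov_shape[2]
  n_roi <- config$n_axons * config$branches_per_axon
  margin <- radius_px + ceiling(config$max_shift_px) + 4
  if (2 * margin >= min(h, w)) stop("FOV too small for masks with margin")
  roi_ids <- as.vector(t(outer(seq_len(config$n_axons),
                               seq_len(config$branches_per_axon),
                               function(a, b) sprintf("ax%02d_b%d", a, b))))
  cy <- sample(seq(margin, h - margin), n_roi, replace = TRUE)
  cx <- sample(seq(margin, w - margin), n_roi, replace = TRUE)
  offs <- expand.grid(dr = -radius_px:radius_px, dc = -radius_px:radius_px)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_px^2, ]
  masks <- lapply(seq_len(n_roi), function(i) {
    cbind(row = cy[i] + offs$dr, col = cx[i] + offs$dc)
  })
  names(masks) <- roi_ids
  attr(masks, "centroids") <- cbind(row = cy, col = cx)
  attr(masks, "fov_shape") <- c(h, w)
  class(masks) <- "roi_mask_set"
  masks
}

# apply an integer rigid shift (content moves dr rows down, dc cols right),
# filling exposed pixels with `fill`
shift_frame <- function(frame, dr, dc, fill = 0) {
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dr
  src_c <- seq_len(w) - dc
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

#' Render synthetic imaging frames from ROI traces
#'
#' Each frame is a sum of Gaussian blobs centred on the ROI centroids and
#' scaled by that frame's fluorescence value, to which a rigid integer
#' shift is applied. Shifts follow a piecewise-constant random walk
#' (re-drawn every \code{block_frames} frames, clipped to
#' \code{config$max_shift_px}) emulating slow animal-motion drift.
#'
#' @param traces a \code{trace_matrix}.
#' @param masks a \code{roi_mask_set} (must fit inside the FOV).
#' @param config a \code{\link{sim_config}}.
#' @param blob_sigma_px Gaussian blob SD in pixels.
#' @param block_frames length of each constant-shift block.
#' @param n_frames optional cap on the number of rendered frames (frames
#'   are taken from the start of the session); rendering full sessions at
#'   512 x 512 is rarely needed for testing.
#' @param seed optional integer overriding \code{config$seed + 3}.
#' @return a list with \code{stack} (a \code{frame_stack}: \code{frames}
#'   array time x height x width, \code{frame_rate}, \code{frame_times})
#'   and \code{shift_series} (data.frame frame_index, dx, dy; dx = column
#'   shift, dy = row shift).
#' @export
simulate_frames <- function(traces, masks, config, blob_sigma_px = 1.5,
                            block_frames = 30, n_frames = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed) else set.seed(config$seed + 3L)
  h <- config$fov_shape[1]; w <- config$fov_shape[2]
  cent <- attr(masks, "centroids")
  if (any(cent[, "row"] < 1 | cent[, "row"] > h |
          cent[, "col"] < 1 | cent[, "col"] > w)) {
    stop("mask centroid outside field of view")
  }
  for (m in masks) {
    if (any(m[, "row"] < 1 | m[, "row"] > h | m[, "col"] < 1 |
            m[, "col"] > w)) stop("mask pixels outside field of view")
  }
  nt <- if (is.null(n_frames)) ncol(traces$values) else
    min(n_frames, ncol(traces$values))
  n_roi <- length(traces$roi_ids)

  # per-ROI blob rendered once on the full FOV (small local support)
  half <- ceiling(4 * blob_sigma_px)
  gg <- expand.grid(dr = -half:half, dc = -half:half)
  gv <- exp(-(gg$dr^2 + gg$dc^2) / (2 * blob_sigma_px^2))
  blob_idx <- vector("list", n_roi)
  blob_val <- vector("list", n_roi)
  for (r in seq_len(n_roi)) {
    rr <- cent[r, "row"] + gg$dr
    cc <- cent[r, "col"] + gg$dc
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    blob_idx[[r]] <- cbind(rr[ok], cc[ok])
    blob_val[[r]] <- gv[ok]
  }

  # piecewise-constant integer shifts
  n_blocks <- ceiling(nt / block_frames)
  ms <- floor(config$max_shift_px)
  bdy <- if (ms > 0) sample(-ms:ms, n_blocks, replace = TRUE) else
    integer(n_blocks)
  bdx <- if (ms > 0) sample(-ms:ms, n_blocks, replace = TRUE) else
    integer(n_blocks)
  dy <- rep(bdy, each = block_frames)[seq_len(nt)]
  dx <- rep(bdx, each = block_frames)[seq_len(nt)]

  frames <- array(0, dim = c(nt, h, w))
  for (t in seq_len(nt)) {
    img <- matrix(0, h, w)
    for (r in seq_len(n_roi)) {
      img[blob_idx[[r]]] <- img[blob_idx[[r]]] +
        traces$values[r, t] * blob_val[[r]]
    }
    frames[t, , ] <- if (dy[t] != 0 || dx[t] != 0)
      shift_frame(img, dy[t], dx[t], fill = 0) else img
  }
  stack <- structure(list(frames = frames,
                          frame_rate = traces$frame_rate,
                          frame_times = traces$frame_times[seq_len(nt)]),
                     class = "frame_stack")
  list(stack = stack,
       shift_series = data.frame(frame_index = seq_len(nt), dx = dx,
                                 dy = dy))
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Frame stack: %d frames of %d x %d px at %g Hz\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}

#' Write / read a frame stack as a multi-page TIFF
#'
#' Values are stored as 32-bit floats after division by \code{scale}
#' (default: stack maximum), which is returned as an attribute on read
#' input via the companion \code{*_scale.txt} sidecar.
#'
#' @param stack a \code{frame_stack}.
#' @param path TIFF file path.
#' @param scale divisor applied before writing.
#' @return \code{read_frames_tiff} returns a \code{frame_stack}.
#' @export
write_frames_tiff <- function(stack, path, scale = NULL) {
  if (is.null(scale)) scale <- max(stack$frames, 1e-12)
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(t) stack$frames[t, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  writeLines(c(format(scale, digits = 17), format(stack$frame_rate)),
             paste0(path, "_scale.txt"))
  invisible(path)
}

#' @rdname write_frames_tiff
#' @export
read_frames_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- readLines(paste0(path, "_scale.txt"))
  scale <- as.numeric(meta[1]); fr <- as.numeric(meta[2])
  nt <- length(pages)
  frames <- array(0, dim = c(nt, nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_len(nt)) frames[t, , ] <- pages[[t]] * scale
  structure(list(frames = frames, frame_rate = fr,
                 frame_times = (seq_len(nt) - 1) / fr),
            class = "frame_stack")
}

#' Write ROI masks as a 16-bit label-image TIFF
#'
#' Pixel value k labels the k-th ROI (0 = background).
#'
#' @param masks a \code{roi_mask_set}.
#' @param path TIFF file path.
#' @export
write_masks_tiff <- function(masks, path) {
  shape <- attr(masks, "fov_shape")
  lab <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
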