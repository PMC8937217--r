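#' Rigid motion correction by whole-frame cross-correlation
#'
#' Frames are registered to a reference image by finding, for each frame,
#' the integer pixel shift that maximizes the 2-D cross-correlation between
#' the mean-subtracted frame and the mean-subtracted reference (computed in
#' the frequency domain), and then applying the inverse shift. Ties in the
#' correlation maximum are broken toward the zero shift. Pixels exposed by
#' the correction are filled with the frame's median intensity. Frames
#' whose estimated shift reaches \code{flag_threshold_px} in either axis
#' are flagged; downstream trace extraction marks their samples missing.
#'
#' @name registration
NULL

# circular cross-correlation of two equal-size matrices (mean-subtracted),
# returning the integer (dy, dx) maximizing it; ties broken toward zero,
# then by (|dy|, |dx|, dy, dx) for determinism
xcorr_shift <- function(frame, ref) {
  f <- frame - mean(frame)
  r <- ref - mean(ref)
  if (all(f == 0) || all(r == 0)) return(c(dy = 0L, dx = 0L, degenerate = 1L))
  cc <- Re(stats::fft(stats::fft(f) * Conj(stats::fft(r)), inverse = TRUE))
  h <- nrow(cc); w <- ncol(cc)
  mx <- max(cc)
  cand <- which(cc >= mx - 1e-9 * abs(mx), arr.ind = TRUE)
  # index (i, j) corresponds to ref shifted by (i-1, j-1) modulo size:
  # cc[i, j] = sum f[y, x] * r[y - (i-1), x - (j-1)], so the frame content
  # sits at +(i-1, j-1) relative to the reference
  dy <- cand[, 1] - 1L; dx <- cand[, 2] - 1L
  dy <- ifelse(dy > h / 2, dy - h, dy)
  dx <- ifelse(dx > w / 2, dx - w, dx)
  ord <- order(dy^2 + dx^2, abs(dy), abs(dx), dy, dx)
  c(dy = as.integer(dy[ord[1]]), dx = as.integer(dx[ord[1]]),
    degenerate = 0L)
}

#' Build a reference image from low-drift frames
#'
#' Estimates each frame's shift relative to a provisional anchor (the
#' temporal median frame of the stack) and averages only the frames whose
#' shift is below \code{drift_threshold_px} in both axes.
#'
#' @param stack a \code{frame_stack}.
#' @param drift_threshold_px maximum allowed drift for a frame to enter
#'   the reference average (pixels; default 15).
#' @return the reference image (matrix), with attribute \code{n_frames}
#'   giving the number of frames averaged.
#' @export
build_reference <- function(stack, drift_threshold_px = 15) {
  nt <- dim(stack$frames)[1]
  if (nt < 2) stop("need at least 2 frames to build a reference")
  anchor <- stack$frames[ceiling(nt / 2), , ]
  keep <- logical(nt)
  for (t in seq_len(nt)) {
    s <- xcorr_shift(stack$frames[t, , ], anchor)
    keep[t] <- abs(s[["dy"]]) < drift_threshold_px &&
      abs(s[["dx"]]) < drift_threshold_px
  }
  if (!any(keep)) stop("reference failure: all frames exceed drift threshold")
  ref <- matrix(0, dim(stack$frames)[2], dim(stack$frames)[3])
  for (t in which(keep)) ref <- ref + stack$frames[t, , ]
  ref <- ref / sum(keep)
  attr(ref, "n_frames") <- sum(keep)
  ref
}

#' Register frames to a reference image
#'
#' @param stack a \code{frame_stack}.
#' @param ref reference image (same shape as the frames), e.g. from
#'   \code{\link{build_reference}}.
#' @param flag_threshold_px shifts at or above this magnitude (either
#'   axis) are flagged (default 15).
#' @return a list with \code{stack} (corrected \code{frame_stack}) and
#'   \code{shifts} (data.frame \code{frame_index}, \code{dx}, \code{dy},
#'   \code{flagged}); \code{dx} is the column shift and \code{dy} the row
#'   shift of the frame content relative to the reference.
#' @export
register_frames <- function(stack, ref, flag_threshold_px = 15) {
  d <- dim(stack$frames)
  if (d[2] != nrow(ref) || d[3] != ncol(ref)) {
    stop("frame and reference shapes differ")
  }
  nt <- d[1]
  dx <- integer(nt); dy <- integer(nt); flagged <- logical(nt)
  corrected <- stack$frames
  for (t in seq_len(nt)) {
    fr <- stack$frames[t, , ]
    s <- xcorr_shift(fr, ref)
    dy[t] <- s[["dy"]]; dx[t] <- s[["dx"]]
    flagged[t] <- s[["degenerate"]] == 1L ||
      abs(dy[t]) >= flag_threshold_px || abs(dx[t]) >= flag_threshold_px
    if (dy[t] != 0 || dx[t] != 0) {
      corrected[t, , ] <- shift_frame(fr, -dy[t], -dx[t],
                                      fill = stats::median(fr))
    }
  }
  out <- structure(list(frames = corrected, frame_rate = stack$frame_rate,
                        frame_times = stack$frame_times),
                   class = "frame_stack")
  list(stack = out,
       shifts = data.frame(frame_index = seq_len(nt), dx = dx, dy = dy,
                           flagged = flagged))
}

#' Write a shift series as CSV
#'
#' Columns: \code{frame_index}, \code{dx}, \code{dy}, \code{flagged}.
#'
#' @param shifts shift data.frame from \code{\link{register_frames}}.
#' @param path file path.
#' @export
write_shifts_csv <- function(shifts, path) {
  utils::write.csv(shifts, path, row.names = FALSE)
  invisible(path)
}
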