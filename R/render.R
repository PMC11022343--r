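#' Render dark-field image stacks from ground-truth tracks
#'
#' Rasterizes tracks into a stack of 8-bit grey frames emulating dark-field
#' imaging: near-black background with additive Gaussian sensor noise and each
#' cell drawn as a filled bright ellipse with its area and aspect ratio,
#' oriented along its instantaneous heading. Overlapping cells are allowed;
#' every (frame, track) whose ellipse touches pixels already lit by another
#' cell is recorded in the `overlaps` attribute for bookkeeping.
#'
#' @param tracks Tibble from [simulate_individuals()] (columns `track_id`,
#'   `frame`, `x`, `y`, `heading`, `area`, `aspect`).
#' @param arena `c(width, height)` in pixels.
#' @param noise_sd Gaussian background noise SD in grey levels (0-255 scale).
#' @param foreground Grey level of cell interiors.
#' @return Integer array `[height, width, n_frames]` of grey values in
#'   0-255, with attribute `overlaps` (tibble of `frame`, `track_id`).
#' @examples
#' set.seed(1)
#' cells <- tibble::tibble(speed = 40, linearity = 0.9, size = 300, shape = 2)
#' tr <- simulate_individuals(cells, 5, 10, arena = c(64, 64))
#' stk <- render_frames(tr, arena = c(64, 64))
#' dim(stk)
#' @export
render_frames <- function(tracks, arena = c(512L, 512L), noise_sd = 4,
                          foreground = 220) {
  w <- as.integer(arena[1]); h <- as.integer(arena[2])
  frames <- sort(unique(tracks$frame))
  n_frames <- length(frames)
  stack <- array(0L, dim = c(h, w, n_frames))
  overlaps <- list()
  by_frame <- split(tracks, tracks$frame)
  for (fi in seq_along(frames)) {
    img <- matrix(0, nrow = h, ncol = w)
    if (noise_sd > 0) {
      img <- matrix(pmax(rnorm(h * w, 0, noise_sd), 0), nrow = h, ncol = w)
    }
    owner <- matrix(0L, nrow = h, ncol = w)
    fr <- by_frame[[as.character(frames[fi])]]
    if (!is.null(fr) && nrow(fr) > 0) {
      for (i in seq_len(nrow(fr))) {
        px <- ellipse_pixels(fr$x[i], fr$y[i], fr$area[i], fr$aspect[i],
                             fr$heading[i], w, h)
        if (length(px) == 0) next
        if (any(owner[px] != 0L)) {
          overlaps[[length(overlaps) + 1L]] <-
            tibble::tibble(frame = frames[fi], track_id = fr$track_id[i])
        }
        owner[px] <- fr$track_id[i]
        img[px] <- foreground
      }
    }
    stack[, , fi] <- as.integer(pmin(round(img), 255))
  }
  attr(stack, "overlaps") <- if (length(overlaps)) dplyr::bind_rows(overlaps) else
    tibble::tibble(frame = integer(0), track_id = integer(0))
  stack
}

# Linear indices of pixels inside an ellipse (centre cx,cy; area px^2; aspect
# = major/minor; theta = major-axis angle). Pixel (r,c) has centre
# (c - 0.5, r - 0.5); x right, y down, top-left origin.
ellipse_pixels <- function(cx, cy, area, aspect, theta, w, h) {
  b <- sqrt(area / (pi * aspect))   # semi-minor
  a <- aspect * b                   # semi-major
  c0 <- max(1L, floor(cx - a)); c1 <- min(w, ceiling(cx + a) + 1L)
  r0 <- max(1L, floor(cy - a)); r1 <- min(h, ceiling(cy + a) + 1L)
  if (c0 > c1 || r0 > r1) return(integer(0))
  cs <- c0:c1; rs <- r0:r1
  dx <- outer(rep(1, length(rs)), cs - 0.5 - cx)
  dy <- outer(rs - 0.5 - cy, rep(1, length(cs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0) return(integer(0))
  (cs[idx[, 2]] - 1L) * h + rs[idx[, 1]]
}

#' Write or read an image stack as multi-page TIFF
#'
#' @param stack Integer array `[height, width, n_frames]`, grey 0-255.
#' @param path Output `.tif` path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   the integer array.
#' @export
write_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The 'tiff' package is required to write image stacks.")
  }
  pages <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The 'tiff' package is required to read image stacks.")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    stack[, , i] <- as.integer(round(pg * 255))
  }
  stack
}
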