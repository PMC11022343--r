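#' Particle detection parameters
#'
#' Thresholding and particle filters for dark-field frames: connected pixel
#' groups brighter than `grey_threshold` are candidate cells, kept when their
#' area and fitted-ellipse aspect ratio fall inside the stated bounds. The
#' defaults are species-agnostic and deliberately permissive; real analyses
#' tune them per species.
#'
#' @param grey_threshold Intensity cut (0-255).
#' @param min_area,max_area Area bounds in px^2 (`min_area < max_area`).
#' @param min_aspect,max_aspect Aspect-ratio bounds (major/minor, >= 1 after
#'   normalization).
#' @return A `detection_params` list.
#' @export
detection_params <- function(grey_threshold = 100, min_area = 20,
                             max_area = 5000, min_aspect = 1,
                             max_aspect = 12) {
  if (min_area >= max_area) abort("`min_area` must be < `max_area`.")
  structure(list(grey_threshold = grey_threshold, min_area = min_area,
                 max_area = max_area, min_aspect = min_aspect,
                 max_aspect = max_aspect),
            class = "detection_params")
}

#' Detect particles in a single frame
#'
#' Labels connected components above the grey threshold and characterizes each
#' by intensity-weighted centroid, pixel area, and the aspect ratio of the
#' ellipse matching its second central moments (normalized so aspect =
#' major/minor >= 1). Components outside the area or aspect bounds are
#' dropped. An empty frame yields an empty tibble.
#'
#' @param frame Numeric/integer matrix of grey values (single channel,
#'   0-255).
#' @param params A [detection_params()].
#' @return Tibble with columns `x`, `y` (pixel coordinates, top-left origin),
#'   `area` (px^2) and `aspect`.
#' @export
detect_particles <- function(frame, params = detection_params()) {
  if (!is.matrix(frame)) abort("`frame` must be a single-channel matrix.")
  mask <- frame > params$grey_threshold
  if (!any(mask)) {
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          area = numeric(0), aspect = numeric(0)))
  }
  lab <- label_components(mask)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rr <- ((idx - 1L) %% nrow(frame)) + 1L
  cc <- ((idx - 1L) %/% nrow(frame)) + 1L
  xs <- cc - 0.5; ys <- rr - 0.5   # pixel centres
  area <- tabulate(labs)
  sx <- tapply(xs, labs, mean)
  sy <- tapply(ys, labs, mean)
  # second central moments -> moment-matched ellipse axes
  aspect <- vapply(seq_along(area), function(l) {
    sel <- labs == l
    if (sum(sel) < 2) return(1)
    vx <- mean((xs[sel] - sx[[l]])^2)
    vy <- mean((ys[sel] - sy[[l]])^2)
    vxy <- mean((xs[sel] - sx[[l]]) * (ys[sel] - sy[[l]]))
    tr <- vx + vy
    det2 <- vx * vy - vxy^2
    disc <- sqrt(max(tr^2 / 4 - det2, 0))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    if (l2 <= 0) return(params$max_aspect)  # degenerate line-like blob
    sqrt(l1 / l2)
  }, numeric(1))
  keep <- area >= params$min_area & area <= params$max_area &
    aspect >= params$min_aspect & aspect <= params$max_aspect
  tibble::tibble(x = as.numeric(sx), y = as.numeric(sy),
                 area = as.numeric(area), aspect = aspect)[keep, ]
}

# Connected-component labelling (8-connectivity). Uses EBImage when present;
# otherwise a two-pass union-find fallback.
label_components <- function(mask) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    lab <- EBImage::bwlabel(t(mask))  # EBImage images are x-major
    return(t(matrix(as.integer(lab), nrow = nrow(t(mask)))))
  }
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc]) next
    nb <- integer(0)
    for (d in list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(1L, -1L))) {
      r2 <- rr + d[1]; c2 <- cc + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && lab[r2, c2] > 0L) {
        nb <- c(nb, lab[r2, c2])
      }
    }
    if (length(nb) == 0) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[rr, cc] <- nxt
    } else {
      roots <- vapply(nb, find, integer(1))
      r0 <- min(roots)
      lab[rr, cc] <- r0
      for (r in roots) parent[r] <- r0
    }
  }
  # flatten labels
  if (nxt > 0) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    remap <- match(roots, sort(unique(roots)))
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

#' Detect particles across every frame of a stack
#'
#' @param stack Integer array `[height, width, n_frames]`.
#' @param params A [detection_params()].
#' @return Tibble of detections with a 0-based `frame` column prepended.
#' @export
detect_stack <- function(stack, params = detection_params()) {
  n <- dim(stack)[3]
  purrr::map_dfr(seq_len(n), function(i) {
    det <- detect_particles(stack[, , i], params)
    dplyr::bind_cols(tibble::tibble(frame = rep(i - 1L, nrow(det))), det)
  })
}
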