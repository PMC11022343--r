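#' Particle linking parameters
#'
#' Constraints describing plausible movement between consecutive frames: a
#' detection may extend a track only if it lies within `max_step` pixels per
#' elapsed frame of the track's last position, and a track survives at most
#' `max_gap` consecutive missed frames before being closed.
#'
#' @param max_step Maximum displacement per frame (px, > 0).
#' @param max_gap Frames a cell may go undetected (>= 0).
#' @param method `"greedy"` (deterministic nearest-neighbour, the default) or
#'   `"optimal"` (exact minimum-total-distance assignment per frame pair,
#'   useful for robustness checks at low particle counts).
#' @return A `linking_params` list.
#' @export
linking_params <- function(max_step = 15, max_gap = 2,
                           method = c("greedy", "optimal")) {
  if (max_step <= 0) abort("`max_step` must be positive.")
  if (max_gap < 0) abort("`max_gap` must be >= 0.")
  structure(list(max_step = max_step, max_gap = as.integer(max_gap),
                 method = match.arg(method)),
            class = "linking_params")
}

#' Link per-frame detections into trajectories
#'
#' Associates detections on consecutive frames into tracks. With the greedy
#' method, candidate (track, detection) pairs within the step constraint are
#' assigned in order of increasing distance, ties broken by lower track id and
#' then detection coordinates, making the output deterministic and invariant
#' to detection order within a frame. Unmatched detections found a new track
#' (numbered by coordinate order within the frame);
#' tracks missing more than `max_gap` frames are closed.
#'
#' @param detections Tibble with columns `frame` (0-based, ordered), `x`, `y`
#'   and optionally `area`, `aspect`.
#' @param params A [linking_params()].
#' @return The detections tibble with an integer `track_id` column, ordered by
#'   `track_id` then `frame`.
#' @export
link_particles <- function(detections, params = linking_params()) {
  detections <- tibble::as_tibble(detections)
  if (nrow(detections) == 0) {
    return(dplyr::mutate(detections, track_id = integer(0)))
  }
  detections <- dplyr::arrange(detections, .data$frame)
  frames <- unique(detections$frame)
  track_id_col <- integer(nrow(detections))
  # active track state
  tr_id <- integer(0); tr_x <- numeric(0); tr_y <- numeric(0); tr_f <- integer(0)
  next_id <- 1L
  row_of_frame <- split(seq_len(nrow(detections)), detections$frame)
  for (f in frames) {
    rows <- row_of_frame[[as.character(f)]]
    dx <- detections$x[rows]; dy <- detections$y[rows]
    alive <- which((f - tr_f) <= params$max_gap + 1L & (f - tr_f) >= 1L)
    assigned_det <- rep(FALSE, length(rows))
    assigned_tr <- rep(FALSE, length(alive))
    if (length(alive) > 0 && length(rows) > 0) {
      gapmul <- f - tr_f[alive]
      dist <- sqrt(outer(tr_x[alive], dx, "-")^2 + outer(tr_y[alive], dy, "-")^2)
      limit <- params$max_step * gapmul
      cand <- which(dist <= limit, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cd <- dist[cand]
        # order by distance, then track id, then detection coordinates so the
        # assignment does not depend on detection scan order within a frame
        ord <- order(cd, tr_id[alive][cand[, 1]], dx[cand[, 2]], dy[cand[, 2]])
        pairs <- if (params$method == "optimal") {
          optimal_assignment(cand[ord, , drop = FALSE], cd[ord],
                             length(alive), length(rows), max(limit))
        } else {
          cand[ord, , drop = FALSE]
        }
        cdist <- if (params$method == "optimal") NULL else NULL
        for (i in seq_len(nrow(pairs))) {
          ti <- pairs[i, 1]; di <- pairs[i, 2]
          if (!assigned_tr[ti] && !assigned_det[di]) {
            assigned_tr[ti] <- TRUE; assigned_det[di] <- TRUE
            id <- tr_id[alive[ti]]
            track_id_col[rows[di]] <- id
            j <- alive[ti]
            tr_x[j] <- dx[di]; tr_y[j] <- dy[di]; tr_f[j] <- f
          }
        }
      }
    }
    # unmatched detections start new tracks, ordered by coordinates so track
    # ids are canonical whatever the detection order within the frame
    new_idx <- which(!assigned_det)
    new_idx <- new_idx[order(dx[new_idx], dy[new_idx])]
    for (di in new_idx) {
      track_id_col[rows[di]] <- next_id
      tr_id <- c(tr_id, next_id); tr_x <- c(tr_x, dx[di])
      tr_y <- c(tr_y, dy[di]); tr_f <- c(tr_f, f)
      next_id <- next_id + 1L
    }
  }
  detections$track_id <- track_id_col
  dplyr::arrange(detections, .data$track_id, .data$frame)
}

# Exact min-total-distance maximum matching over candidate pairs, by
# depth-first branch and bound; unmatched tracks cost `penalty` so cardinality
# dominates. Candidates arrive pre-sorted by (distance, track, detection),
# which also fixes tie order among equal-cost optima.
optimal_assignment <- function(cand, cost, n_tr, n_det, penalty) {
  tracks <- sort(unique(cand[, 1]))
  if (length(tracks) > 14) return(cand)  # fall back to greedy order
  by_track <- lapply(tracks, function(t) {
    sel <- cand[, 1] == t
    list(det = cand[sel, 2], cost = cost[sel])
  })
  pen <- penalty + 1
  best <- list(cost = Inf, pairs = NULL)
  used <- rep(FALSE, n_det)
  cur <- matrix(integer(0), ncol = 2)
  recurse <- function(i, acc, pairs) {
    if (acc >= best$cost) return()
    if (i > length(tracks)) {
      best <<- list(cost = acc, pairs = pairs)
      return()
    }
    bt <- by_track[[i]]
    for (j in seq_along(bt$det)) {
      d <- bt$det[j]
      if (!used[d]) {
        used[d] <<- TRUE
        recurse(i + 1, acc + bt$cost[j], rbind(pairs, c(tracks[i], d)))
        used[d] <<- FALSE
      }
    }
    recurse(i + 1, acc + pen, pairs)  # leave this track unmatched
  }
  recurse(1L, 0, cur)
  if (is.null(best$pairs) || nrow(best$pairs) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  best$pairs
}
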