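#' Trajectory quality-control parameters
#'
#' Minimal quality a trajectory must meet to be retained: a duration of at
#' least `min_duration` seconds, a net (start-to-end straight-line)
#' displacement of at least `min_net_displacement` pixels, and a detection on
#' at least `min_detection_frequency` of the frames it spans. All-zero
#' parameters keep everything.
#'
#' @param min_duration Seconds (>= 0).
#' @param min_net_displacement Pixels (>= 0).
#' @param min_detection_frequency Fraction in `[0, 1]`.
#' @return A `qc_params` list.
#' @export
qc_params <- function(min_duration = 0.5, min_net_displacement = 10,
                      min_detection_frequency = 0.5) {
  stopifnot(min_duration >= 0, min_net_displacement >= 0,
            min_detection_frequency >= 0, min_detection_frequency <= 1)
  structure(list(min_duration = min_duration,
                 min_net_displacement = min_net_displacement,
                 min_detection_frequency = min_detection_frequency),
            class = "qc_params")
}

#' Per-trajectory movement and morphology metrics
#'
#' For each track: gross displacement (summed straight-line steps between
#' consecutive detections, which linearly bridges any gap frames), net
#' displacement (straight line from first to last detection), duration
#' (spanned frames / frame rate), speed (gross / duration), path linearity,
#' mean area and mean aspect, and the detection frequency over spanned frames.
#'
#' Linearity defaults to net/gross in `[0, 1]` (1 = perfectly straight,
#' defined as 1 for a zero-gross track); the `"gross_over_net"` convention
#' (>= 1, undefined when net = 0) is available for exact-wording
#' compatibility with protocols that phrase the ratio the other way around.
#'
#' Single-detection tracks get `NA` metrics and `defined = FALSE`.
#'
#' @param tracks Tibble with `track_id`, `frame`, `x`, `y` and optionally
#'   `area`, `aspect`.
#' @param frame_rate Frames per second.
#' @param linearity_convention `"net_over_gross"` or `"gross_over_net"`.
#' @return One row per track: `track_id`, `n_detections`, `duration`,
#'   `gross_displacement`, `net_displacement`, `speed`, `linearity`,
#'   `mean_area`, `mean_aspect`, `detection_frequency`, `defined`.
#' @export
compute_metrics <- function(tracks, frame_rate,
                            linearity_convention = c("net_over_gross",
                                                     "gross_over_net")) {
  linearity_convention <- match.arg(linearity_convention)
  tracks <- dplyr::arrange(tibble::as_tibble(tracks), .data$track_id, .data$frame)
  has_area <- "area" %in% names(tracks)
  has_aspect <- "aspect" %in% names(tracks)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_detections = dplyr::n(),
      span_frames = max(.data$frame) - min(.data$frame),
      duration = .data$span_frames / frame_rate,
      gross_displacement = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)),
      net_displacement = sqrt((dplyr::last(.data$x) - dplyr::first(.data$x))^2 +
                              (dplyr::last(.data$y) - dplyr::first(.data$y))^2),
      mean_area = if (has_area) mean(.data$area) else NA_real_,
      mean_aspect = if (has_aspect) mean(.data$aspect) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      defined = .data$n_detections >= 2,
      detection_frequency = ifelse(.data$defined,
                                   .data$n_detections / (.data$span_frames + 1), NA_real_),
      speed = ifelse(.data$defined & .data$duration > 0,
                     .data$gross_displacement / .data$duration, NA_real_),
      linearity = dplyr::case_when(
        !.data$defined ~ NA_real_,
        linearity_convention == "net_over_gross" & .data$gross_displacement == 0 ~ 1,
        linearity_convention == "net_over_gross" ~
          .data$net_displacement / .data$gross_displacement,
        .data$net_displacement == 0 ~ NA_real_,
        TRUE ~ .data$gross_displacement / .data$net_displacement
      ),
      duration = ifelse(.data$defined, .data$duration, NA_real_)
    ) |>
    dplyr::select("track_id", "n_detections", "duration", "gross_displacement",
                  "net_displacement", "speed", "linearity", "mean_area",
                  "mean_aspect", "detection_frequency", "defined")
}

#' Filter trajectories on minimal quality
#'
#' Splits metric rows into kept and discarded sets. A track is kept when its
#' duration, net displacement and detection frequency all meet the thresholds;
#' discarded rows carry the first criterion that failed (checked in the order
#' duration, net displacement, detection frequency; undefined metrics fail as
#' `"undefined"`). The union of the two sets is exactly the input.
#'
#' @param metrics Output of [compute_metrics()].
#' @param params A [qc_params()].
#' @return List with tibbles `kept` and `discarded` (the latter with a
#'   `reason` column).
#' @export
qc_filter <- function(metrics, params = qc_params()) {
  m <- tibble::as_tibble(metrics)
  reason <- dplyr::case_when(
    !m$defined ~ "undefined",
    m$duration < params$min_duration ~ "duration",
    m$net_displacement < params$min_net_displacement ~ "net_displacement",
    m$detection_frequency < params$min_detection_frequency ~ "detection_frequency",
    TRUE ~ NA_character_
  )
  list(kept = m[is.na(reason), , drop = FALSE],
       discarded = dplyr::mutate(m[!is.na(reason), , drop = FALSE],
                                 reason = reason[!is.na(reason)]))
}

#' Summarize a sample: density and population-level trait moments
#'
#' Density is the number of QC-passing trajectories corrected for the imaged
#' volume; each trait (speed, linearity, size = mean area, shape = mean
#' aspect) is summarized by its mean and unbiased (n - 1) variance over
#' trajectories. With fewer than two trajectories the variances (and with
#' zero, the means) are `NA` and the summary is flagged.
#'
#' @param kept Tibble of QC-passing metric rows ([qc_filter()]`$kept`).
#' @param sample_volume_ml Imaged volume in mL.
#' @param sample_id Optional identifier carried through.
#' @return One-row tibble: `sample_id`, `n_trajectories`, `density`
#'   (trajectories/mL), `<trait>_mean` and `<trait>_var` for the four traits,
#'   and `traits_defined`.
#' @export
summarize_sample <- function(kept, sample_volume_ml, sample_id = NA_character_) {
  stopifnot(sample_volume_ml > 0)
  n <- nrow(kept)
  mom <- function(v, f) if (n >= ifelse(identical(f, var), 2L, 1L)) f(v) else NA_real_
  tibble::tibble(
    sample_id = sample_id,
    n_trajectories = n,
    density = n / sample_volume_ml,
    speed_mean = mom(kept$speed, mean), speed_var = mom(kept$speed, var),
    linearity_mean = mom(kept$linearity, mean), linearity_var = mom(kept$linearity, var),
    size_mean = mom(kept$mean_area, mean), size_var = mom(kept$mean_area, var),
    shape_mean = mom(kept$mean_aspect, mean), shape_var = mom(kept$mean_aspect, var),
    traits_defined = n >= 2L
  )
}

#' Track an image stack end to end
#'
#' Convenience wrapper chaining [detect_stack()], [link_particles()],
#' [compute_metrics()], [qc_filter()] and [summarize_sample()].
#'
#' @param stack Integer array `[height, width, n_frames]`.
#' @param frame_rate Frames per second.
#' @param sample_volume_ml Imaged volume (mL) for the density estimate.
#' @param detection,linking,qc Parameter objects.
#' @param sample_id Optional identifier.
#' @param linearity_convention Passed to [compute_metrics()].
#' @return List with `trajectories` (linked detections), `metrics`, `kept`,
#'   `discarded` and `summary`.
#' @export
track_stack <- function(stack, frame_rate, sample_volume_ml,
                        detection = detection_params(),
                        linking = linking_params(),
                        qc = qc_params(),
                        sample_id = NA_character_,
                        linearity_convention = "net_over_gross") {
  det <- detect_stack(stack, detection)
  traj <- link_particles(det, linking)
  metrics <- compute_metrics(traj, frame_rate, linearity_convention)
  flt <- qc_filter(metrics, qc)
  list(trajectories = traj, metrics = metrics, kept = flt$kept,
       discarded = flt$discarded,
       summary = summarize_sample(flt$kept, sample_volume_ml, sample_id))
}
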