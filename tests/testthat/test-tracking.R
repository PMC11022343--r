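make_frame <- function(particles, w = 200, h = 200) {
  tr <- dplyr::mutate(particles, track_id = dplyr::row_number(), frame = 0L,
                      heading = 0)
  render_frames(tr, arena = c(w, h), noise_sd = 0)[, , 1]
}

test_that("detection keeps valid particles and drops undersized blobs", {
  frame <- make_frame(tibble::tibble(
    x = c(40, 100, 160, 60), y = c(40, 100, 160, 160),
    area = c(400, 300, 350, 5), aspect = c(2, 1.5, 3, 1)))
  det <- detect_particles(frame, detection_params(min_area = 20))
  expect_identical(nrow(det), 3L)
  expect_identical(nrow(detect_particles(matrix(0, 50, 50),
                                         detection_params())), 0L)
})

test_that("rendered cells are detected on nearly every frame", {
  set.seed(1)
  k <- 5
  # non-overlapping by construction: well-separated slow walkers
  cells <- tibble::tibble(speed = rep(10, k), linearity = 0.95,
                          size = 300, shape = 2)
  tr <- simulate_individuals(cells, 20, 10, arena = c(400, 400))
  # spread starting points far apart deterministically
  offs <- cbind(c(60, 200, 340, 60, 340), c(60, 200, 340, 340, 60))
  tr <- tr |>
    dplyr::group_by(track_id) |>
    dplyr::mutate(x = x - x[1] + offs[track_id[1], 1],
                  y = y - y[1] + offs[track_id[1], 2]) |>
    dplyr::ungroup()
  stk <- render_frames(tr, arena = c(400, 400), noise_sd = 4)
  det <- detect_stack(stk, detection_params())
  per_frame <- table(det$frame)
  expect_gte(mean(per_frame == k), 0.95)
})

test_that("static particles link into separate full-length tracks", {
  det <- tidyr::expand_grid(frame = 0:9, id = 1:2) |>
    dplyr::mutate(x = ifelse(id == 1, 50, 150), y = 50) |>
    dplyr::select(-id)
  linked <- link_particles(det, linking_params(max_step = 10, max_gap = 0))
  expect_identical(dplyr::n_distinct(linked$track_id), 2L)
  expect_true(all(table(linked$track_id) == 10))
})

test_that("the step constraint decides continuation versus fragmentation", {
  det <- tibble::tibble(frame = 0:9, x = 5 * (0:9), y = 0)
  one <- link_particles(det, linking_params(max_step = 10))
  expect_identical(dplyr::n_distinct(one$track_id), 1L)
  many <- link_particles(det, linking_params(max_step = 2))
  expect_identical(dplyr::n_distinct(many$track_id), 10L)
})

test_that("linking is invariant to detection order within frames", {
  set.seed(2)
  det <- tidyr::expand_grid(frame = 0:5, id = 1:4) |>
    dplyr::mutate(x = 40 * id + frame * 2, y = 30 * id - frame) |>
    dplyr::select(-id)
  shuffled <- det[sample(nrow(det)), ]
  a <- link_particles(det, linking_params(max_step = 10))
  b <- link_particles(shuffled, linking_params(max_step = 10))
  key <- function(d) dplyr::arrange(d, track_id, frame)[, c("track_id", "frame", "x", "y")]
  expect_identical(key(a), key(b))
})

test_that("gap bridging carries a track across missed frames", {
  det <- tibble::tibble(frame = c(0, 1, 2, 5, 6), x = c(0, 5, 10, 25, 30), y = 0)
  bridged <- link_particles(det, linking_params(max_step = 6, max_gap = 2))
  expect_identical(dplyr::n_distinct(bridged$track_id), 1L)
  broken <- link_particles(det, linking_params(max_step = 6, max_gap = 1))
  expect_identical(dplyr::n_distinct(broken$track_id), 2L)
})

test_that("optimal assignment resolves a crossing greedy gets wrong", {
  # two particles swap-adjacent: greedy takes the single nearest pair first,
  # optimal minimizes the total displacement
  det <- tibble::tibble(frame = c(0L, 0L, 1L, 1L),
                        x = c(0, 10, 4, 12), y = 0)
  greedy <- link_particles(det, linking_params(max_step = 8))
  optimal <- link_particles(det, linking_params(max_step = 8, method = "optimal"))
  expect_identical(dplyr::n_distinct(optimal$track_id), 2L)
  # total displacement of optimal <= greedy
  disp <- function(d) {
    d |>
      dplyr::group_by(track_id) |>
      dplyr::summarise(s = sum(sqrt(diff(x)^2 + diff(y)^2)), .groups = "drop") |>
      dplyr::pull(s) |> sum()
  }
  expect_lte(disp(optimal), disp(greedy))
})

test_that("trajectory metrics reproduce hand geometry", {
  m <- compute_metrics(straight_track(10, 5), frame_rate = 10)
  expect_equal(m$gross_displacement, 45)
  expect_equal(m$net_displacement, 45)
  expect_equal(m$duration, 0.9)
  expect_equal(m$speed, 50)
  expect_equal(m$linearity, 1)
  # closed square returns to start: net 0, linearity 0
  sq <- tibble::tibble(track_id = 1L, frame = 0:4,
                       x = c(0, 10, 10, 0, 0), y = c(0, 0, 10, 10, 0))
  ms <- compute_metrics(sq, frame_rate = 10)
  expect_equal(ms$net_displacement, 0)
  expect_equal(ms$linearity, 0)
  # gross-over-net convention flips the ratio
  tri <- tibble::tibble(track_id = 1L, frame = 0:2, x = c(0, 3, 3), y = c(0, 0, 4))
  m1 <- compute_metrics(tri, 10)
  m2 <- compute_metrics(tri, 10, linearity_convention = "gross_over_net")
  expect_equal(m1$linearity, 5 / 7)
  expect_equal(m2$linearity, 7 / 5)
})

test_that("random-walk metrics equal the brute-force path oracle", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    tr <- tibble::tibble(track_id = 1L, frame = 0:(n - 1),
                         x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
    m <- compute_metrics(tr, frame_rate = 10)
    o <- path_oracle(tr$x, tr$y)
    expect_equal(m$gross_displacement, o$gross, tolerance = 1e-9)
    expect_equal(m$linearity, o$net / o$gross, tolerance = 1e-9)
    expect_lte(m$net_displacement, m$gross_displacement + 1e-12)
  }
})

test_that("single-detection tracks are flagged undefined", {
  m <- compute_metrics(tibble::tibble(track_id = 1L, frame = 0L, x = 1, y = 1),
                       frame_rate = 10)
  expect_false(m$defined)
  expect_true(is.na(m$speed))
})

test_that("QC filtering partitions tracks with recorded reasons", {
  base <- straight_track(10, 5)
  tracks <- dplyr::bind_rows(lapply(1:10, function(i) {
    t <- base
    t$track_id <- i
    if (i == 1) t <- t[1:2, ]                  # short duration
    if (i == 2) { t$x <- 0; t$y <- 0.1 * t$frame }   # tiny net displacement
    if (i == 3) t <- t[c(1, 2, 10), ]          # sparse detections
    if (i == 4) t <- t[1, ]                    # undefined
    t
  }))
  m <- compute_metrics(tracks, frame_rate = 10)
  flt <- qc_filter(m, qc_params(min_duration = 0.5, min_net_displacement = 5,
                                min_detection_frequency = 0.5))
  expect_identical(nrow(flt$kept), 6L)
  expect_identical(nrow(flt$discarded), 4L)
  expect_setequal(flt$discarded$reason,
                  c("duration", "net_displacement", "detection_frequency",
                    "undefined"))
  expect_identical(nrow(flt$kept) + nrow(flt$discarded), nrow(m))
  # all-pass parameters keep everything defined
  flt0 <- qc_filter(m, qc_params(0, 0, 0))
  expect_identical(nrow(flt0$kept), sum(m$defined))
  # a clearly short track names duration as the failure
  short <- qc_filter(compute_metrics(straight_track(2, 5), 10),
                     qc_params(min_duration = 0.5))
  expect_identical(short$discarded$reason, "duration")
})

test_that("sample summaries convert counts and moments correctly", {
  kept <- tibble::tibble(track_id = 1:2, speed = c(40, 60),
                         linearity = c(0.8, 1), mean_area = c(100, 300),
                         mean_aspect = c(2, 2))
  s <- summarize_sample(kept, sample_volume_ml = 0.81)
  expect_equal(s$speed_mean, 50)
  expect_equal(s$speed_var, 200)
  expect_equal(s$density, 2 / 0.81)
  many <- kept[rep(1, 81), ]
  expect_equal(summarize_sample(many, 0.81)$density, 100)
  empty <- summarize_sample(kept[0, ], 0.81)
  expect_equal(empty$density, 0)
  expect_false(empty$traits_defined)
})
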