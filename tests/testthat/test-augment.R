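test_that("window specifications validate their regime", {
  expect_error(window_spec(0), "length_s")
  expect_error(window_spec(0.5, 0), "stride_s")
  expect_error(window_spec(0.5, 0.6), "stride_s")
  ws <- window_spec(0.5, 0.25)
  expect_equal(ws$stride_s / ws$length_s, 0.5)
  # fixed window as the stride = length special case
  expect_equal(window_spec(1)$stride_s, 0.5)
  expect_equal(window_spec(1, 1)$stride_s, 1)
})

test_that("segment counts match brute-force start enumeration", {
  # exhaustive over small spans, aggregated into one comparison
  triples <- do.call(rbind, lapply(c(1, 2, 5, 17, 40, 60), function(T)
    do.call(rbind, lapply(seq_len(T), function(L)
      cbind(T = T, L = L, S = seq_len(L))))))
  got <- apply(triples, 1, function(r)
    length(eegid:::.segment_starts(r["T"], r["L"], r["S"])))
  want <- apply(triples, 1, function(r)
    enum_window_count(r["T"], r["L"], r["S"]))
  expect_identical(got, want)
  # randomized larger triples exercised through segment_recording itself
  set.seed(42)
  for (i in 1:25) {
    T <- sample(50:500, 1)
    L <- sample(seq_len(T), 1)
    S <- sample(seq_len(L), 1)
    rec <- recording(matrix(rnorm(T), 1), "CZ", 1, "s")  # 1 Hz: L samples = L s
    segs <- suppressWarnings(segment_recording(rec, window_spec(L, S)))
    expect_length(segs, enum_window_count(T, L, S))
  }
})

test_that("the derived example T=100, L=30, S=7 yields 11 windows", {
  rec <- recording(matrix(rnorm(200), 2), c("C3", "C4"), 10, "s")  # 100 pts? no
  rec <- recording(matrix(rnorm(100), 1), "CZ", 10, "s")           # 100 pts @10Hz
  segs <- segment_recording(rec, window_spec(3, 0.7))              # L=30, S=7
  expect_length(segs, 11L)
  expect_identical(enum_window_count(100, 30, 7), 11L)
})

test_that("windows copy source values exactly and overlap by L - S points", {
  rec <- make_rec(n_ch = 3, n_t = 200, rate = 160)
  ws <- window_spec(0.5, 0.25)   # L = 80, S = 40
  segs <- segment_recording(rec, ws)
  expect_length(segs, 4L)        # floor((200-80)/40)+1
  for (k in seq_along(segs)) {
    s0 <- (k - 1L) * 40L
    expect_identical(segs[[k]]$data,
                     t(rec$signal[, (s0 + 1):(s0 + 80)]))
    expect_identical(segs[[k]]$start_sample, s0)
  }
  # consecutive windows share exactly L - S = 40 time points
  expect_identical(segs[[1]]$data[41:80, ], segs[[2]]$data[1:40, ])

  # with S = L the windows tile without overlap
  segs2 <- segment_recording(rec, window_spec(0.5, 0.5))
  expect_length(segs2, 2L)
  expect_identical(vapply(segs2, `[[`, 0L, "start_sample"), c(0L, 80L))
})

test_that("exact-fit, too-short and non-integer windows behave as specified", {
  rec <- make_rec(n_ch = 2, n_t = 80, rate = 160)
  segs <- segment_recording(rec, window_spec(0.5, 0.5))
  expect_length(segs, 1L)
  expect_identical(segs[[1]]$start_sample, 0L)

  short <- make_rec(n_ch = 2, n_t = 79, rate = 160)
  expect_warning(out <- segment_recording(short, window_spec(0.5, 0.5)),
                 "shorter")
  expect_length(out, 0L)

  expect_error(segment_recording(rec, window_spec(0.33, 0.33)),
               "whole samples")
})

test_that("datasets segment each range independently with dense sorted labels", {
  set.seed(2)
  recs <- list(make_rec(subject = "S002", n_t = 9600, seed = 1),
               make_rec(subject = "S001", n_t = 9600, seed = 2),
               make_rec(subject = "S003", n_t = 9600, seed = 3))
  ws <- window_spec(1, 1)
  ranges <- data.frame(rec_index = rep(1:3, each = 2),
                       start = rep(c(0L, 7680L), 3),
                       end = rep(c(7680L, 9600L), 3))
  ds <- build_dataset(recs, ws, ranges)
  # additivity: 48 + 12 one-second windows per subject, no straddling
  expect_identical(n_segments(ds), 3L * (48L + 12L))
  expect_identical(ds$label_map,
                   stats::setNames(0:2, c("S001", "S002", "S003")))
  expect_identical(sort(unique(ds$meta$label)), 0:2)
  # no window crosses the 7680 boundary
  expect_true(all(ds$meta$start_sample + 160 <= 7680 |
                    ds$meta$start_sample >= 7680))
  # labels follow lexicographic subject order, not input order
  expect_identical(unique(ds$meta$subject_id[ds$meta$label == 0]), "S001")

  # compositional oracle: total equals the sum of per-range counts
  counts <- mapply(function(i, s, e) {
    length(eegid:::.segment_starts(e - s, 160L, 160L))
  }, ranges$rec_index, ranges$start, ranges$end)
  expect_identical(n_segments(ds), as.integer(sum(counts)))

  # segment planes are transposed slices of the source
  k <- 50L
  src <- recs[[match(ds$meta$subject_id[k],
                     vapply(recs, function(r) r$subject_id, ""))]]
  s0 <- ds$meta$start_sample[k]
  expect_equal(ds$x[, , k], unname(t(src$signal[, (s0 + 1):(s0 + 160)])),
               tolerance = 0)
})

test_that("overlapping or out-of-bound ranges are rejected", {
  recs <- list(make_rec(n_t = 1000))
  ws <- window_spec(0.5, 0.5)
  expect_error(build_dataset(recs, ws,
                             data.frame(rec_index = 1, start = c(0, 400),
                                        end = c(500, 900))),
               "overlapping")
  expect_error(build_dataset(recs, ws,
                             data.frame(rec_index = 1, start = 0, end = 1200)),
               "bounds")
})

test_that("bind_datasets pools segments and keeps the label map", {
  recs <- list(make_rec(subject = "S001", n_t = 800, seed = 1),
               make_rec(subject = "S002", n_t = 800, seed = 2))
  ws <- window_spec(0.5, 0.5)
  d1 <- build_dataset(recs, ws)
  d2 <- build_dataset(recs, ws)
  both <- bind_datasets(d1, d2)
  expect_identical(n_segments(both), 2L * n_segments(d1))
  expect_identical(both$label_map, d1$label_map)
})
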