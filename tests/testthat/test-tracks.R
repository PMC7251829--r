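test_that("read filtering applies length, sd and amplitude thresholds", {
  par <- detection_params("CNN")
  flat <- prof_tbl(seq(0, 20000, by = 100), rep(0.3, 201), read_id = "flat")
  expect_equal(nrow(filter_reads(flat, par)), 0)
  expect_match(rejection_log(filter_reads(flat, par))$reason, "sd")
  # sd 0.2, amplitude 0.5, 20 kb: kept under CNN thresholds
  set.seed(1)
  v <- 0.3 + 0.25 * sin(seq(0, 6 * pi, length.out = 201))
  good <- prof_tbl(seq(0, 20000, by = 100), v, read_id = "good")
  expect_gt(sd(v), 0.115)
  expect_gte(max(v) - min(v), 0.4)
  expect_equal(unique(filter_reads(good, par)$read_id), "good")
  # a 4.9-kb read is rejected regardless of signal
  short <- prof_tbl(seq(0, 4900, by = 100), v[1:50], read_id = "short")
  expect_equal(nrow(filter_reads(short, par)), 0)
  expect_match(rejection_log(filter_reads(short, par))$reason, "short")
})

test_that("piecewise-linear simplification keeps endpoints and respects epsilon", {
  # exactly collinear: two breakpoints
  lin <- tibble::tibble(position = 0:50, value = seq(0, 1, length.out = 51))
  expect_equal(nrow(segment_profile(lin, 0.01)), 2)
  # triangle wave: apex retained at any epsilon below its height
  tri <- tibble::tibble(position = 0:20,
                        value = c(seq(0, 1, length.out = 11),
                                  seq(0.9, 0, length.out = 10)))
  bp <- segment_profile(tri, 0.2)
  expect_equal(nrow(bp), 3)
  expect_true(10 %in% bp$position)
  # fewer than 3 points: passthrough
  expect_equal(nrow(segment_profile(lin[1:2, ], 0.1)), 2)
})

test_that("simplification matches the recursive oracle on random profiles", {
  set.seed(99)
  for (k in 1:50) {
    n <- sample(20:60, 1)
    x <- sort(runif(n, 0, 1000))
    y <- cumsum(rnorm(n, 0, 0.3))
    eps <- runif(1, 0.05, 0.6)
    keep <- forktrace:::rdp_mask(x, y, eps)
    expect_identical(keep, rdp_oracle(x, y, eps))
    # max deviation property
    bp <- which(keep)
    for (j in seq_len(length(bp) - 1)) {
      i0 <- bp[j]; i1 <- bp[j + 1]
      if (i1 - i0 < 2) next
      slope <- (y[i1] - y[i0]) / (x[i1] - x[i0])
      dev <- abs(y[(i0 + 1):(i1 - 1)] - (y[i0] + (x[(i0 + 1):(i1 - 1)] - x[i0]) * slope))
      expect_lte(max(dev), eps + 1e-12)
    }
  }
})

test_that("track detection follows the amplitude thresholds", {
  par <- detection_params("TM")
  # rise 0.45 then fall 0.27: one track
  bp1 <- bp_tbl(c(0, 1000, 1300, 4000, 5000),
                c(0.02, 0.02, 0.47, 0.20, 0.20))
  tr1 <- detect_tracks(bp1, par)
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$rise, 0.45)
  expect_equal(tr1$fall, 0.27)
  # rise 0.43: below threshold, no track
  bp2 <- bp_tbl(c(0, 1000, 1300, 4000), c(0.02, 0.02, 0.45, 0.02))
  expect_equal(nrow(detect_tracks(bp2, par)), 0)
  # fall 0.25: below threshold, no track
  bp3 <- bp_tbl(c(0, 1000, 1300, 4000), c(0.02, 0.02, 0.52, 0.27))
  expect_equal(nrow(detect_tracks(bp3, par)), 0)
})

test_that("two well-separated pulses give two tracks with correct extents", {
  par <- detection_params("TM")
  bp <- bp_tbl(c(0, 1000, 1300, 3000, 6000, 9000, 9300, 11000, 12000),
               c(0.0, 0.0, 0.9, 0.1, 0.1, 0.1, 0.9, 0.1, 0.1))
  tr <- detect_tracks(bp, par)
  expect_equal(nrow(tr), 2)
  expect_true(tr$start[1] >= 1000 && tr$end[1] <= 3100)
  expect_true(tr$start[2] >= 9000 - 300 && tr$end[2] <= 11100)
  # mid-rise localizers sit on the steep segments
  expect_true(tr$mid_rise_pos[1] > 1000 && tr$mid_rise_pos[1] < 1300)
  expect_true(tr$mid_rise_pos[2] > 9000 && tr$mid_rise_pos[2] < 9300)
})

test_that("a plateau between rise and fall is tolerated", {
  par <- detection_params("TM")
  bp <- bp_tbl(c(0, 1000, 1300, 3000, 5000, 6000),
               c(0.0, 0.0, 0.9, 0.88, 0.1, 0.1))
  tr <- detect_tracks(bp, par)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$peak, 0.9)
})

test_that("orientation uses the slope-ratio rule then the level rule", {
  par <- detection_params("TM")
  base <- tibble::tibble(start = 1000, end = 5000, rise = 0.9, fall = 0.8,
                         min_p = 0.0, min_f = 0.02, peak = 0.9,
                         mid_rise_pos = 1200, mid_fall_pos = 3000)
  # steep up, shallow down: rightward (ratio 3 > 1.5)
  t1 <- orient_track(dplyr::mutate(base, slope_up = 0.9, slope_down = -0.3), par)
  expect_equal(t1$orientation, "right")
  expect_equal(t1$fork_start, 1200)
  # mirrored: leftward, fork start at the falling side
  t2 <- orient_track(dplyr::mutate(base, slope_up = 0.3, slope_down = -0.9), par)
  expect_equal(t2$orientation, "left")
  expect_equal(t2$fork_start, 3000)
  # symmetric slopes: level rule decides (following flank is the chase side)
  t3 <- orient_track(dplyr::mutate(base, slope_up = 0.5, slope_down = -0.5,
                                   min_f = 0.12), par)
  expect_equal(t3$orientation, "right")
  # symmetric slopes and equal minima: unoriented
  t4 <- orient_track(dplyr::mutate(base, slope_up = 0.5, slope_down = -0.5,
                                   min_f = 0.0), par)
  expect_true(is.na(t4$orientation))
  # zero down slope: ratio treated as infinite
  t5 <- orient_track(dplyr::mutate(base, slope_up = 0.5, slope_down = 0), par)
  expect_equal(t5$orientation, "right")
  # elevated pulse-side flank voids the orientation
  t6 <- orient_track(dplyr::mutate(base, slope_up = 0.9, slope_down = -0.3,
                                   min_p = 0.4, min_f = 0.5), par)
  expect_true(is.na(t6$orientation))
})

test_that("track scores follow the decided formulas and mirror symmetry", {
  par <- detection_params("TM")
  base <- tibble::tibble(start = 1000, end = 5000, rise = 0.5, fall = 0.45,
                         min_p = 0, min_f = 0.02, peak = 0.5,
                         mid_rise_pos = 1200, mid_fall_pos = 3000)
  right <- score_track(orient_track(dplyr::mutate(base, slope_up = 0.9,
                                                  slope_down = -0.3), par),
                       off_track_sd = 0.1, amplitude_scale = 1)
  expect_equal(right$ascore, 3)
  expect_equal(right$jscore, 5)   # jump 0.5 / sd 0.1
  left <- score_track(orient_track(dplyr::mutate(base, slope_up = 0.3,
                                                 slope_down = -0.9,
                                                 rise = 0.45, fall = 0.5), par),
                      off_track_sd = 0.1, amplitude_scale = 1)
  expect_equal(left$ascore, -3)
  expect_equal(left$jscore, 5)
})

test_that("event calling applies score, gap and plateau rules", {
  par <- detection_params("TM")
  mk_track <- function(start, end, orientation, fs, min_p = 0, min_f = 0.02,
                       ascore = 4, jscore = 3) {
    tibble::tibble(read_id = "r", chrom = "c", start = start, end = end,
                   rise = 0.9, fall = 0.8, slope_up = 1, slope_down = -0.2,
                   min_p = min_p, min_f = min_f, peak = 0.9,
                   mid_rise_pos = fs, mid_fall_pos = fs,
                   orientation = orientation,
                   fork_start = fs,
                   ascore = ifelse(orientation == "right", ascore, -ascore),
                   jscore = jscore, method = "TM")
  }
  flatprof <- prof_tbl(seq(0, 30000, by = 50), rep(0.02, 601), read_id = "r",
                       chrom = "c")
  # diverging pair, gap 1.2 kb, low plateau: one initiation at the midpoint
  div <- dplyr::bind_rows(mk_track(2000, 9000, "left", 9400),
                          mk_track(10600, 18000, "right", 10600))
  ev <- call_events(div, flatprof, par)
  expect_equal(ev$type, "initiation")
  expect_equal(ev$midpoint, 10000)
  # gap below 1 kb: no event
  div2 <- dplyr::bind_rows(mk_track(2000, 9000, "left", 9700),
                           mk_track(10300, 18000, "right", 10500 - 100))
  expect_equal(nrow(call_events(div2, flatprof, par)), 0)
  # high plateau between fork starts: no initiation
  highprof <- flatprof
  highprof$value[highprof$position > 9400 & highprof$position < 10600] <- 0.5
  expect_equal(nrow(call_events(div, highprof, par)), 0)
  # low-confidence member: no event
  weak <- dplyr::bind_rows(mk_track(2000, 9000, "left", 9400, ascore = 1.5),
                           mk_track(10600, 18000, "right", 10600))
  expect_equal(nrow(call_events(weak, flatprof, par)), 0)
  # converging pair with clean flanks: termination at the midpoint
  con <- dplyr::bind_rows(mk_track(2000, 14000, "right", 3000),
                          mk_track(14000, 26000, "left", 25000))
  evt <- call_events(con, flatprof, par)
  expect_equal(evt$type, "termination")
  expect_equal(evt$midpoint, 14000)
  # elevated fork-start flank (0.2 > 0.12): no termination
  con2 <- dplyr::bind_rows(mk_track(2000, 14000, "right", 3000, min_p = 0.2),
                           mk_track(14000, 26000, "left", 25000))
  expect_equal(nrow(call_events(con2, flatprof, par)), 0)
  # an intervening track voids the pair
  mid <- dplyr::bind_rows(mk_track(2000, 8000, "left", 8000),
                          mk_track(8500, 9500, "right", 8600, ascore = 1),
                          mk_track(10600, 18000, "right", 10600))
  expect_equal(nrow(call_events(mid, flatprof, par)), 0)
})

test_that("all rules are left/right symmetric under coordinate mirroring", {
  # a mirrored profile must give mirrored tracks with flipped orientations
  # and events of the same type at mirrored midpoints
  cfg <- fx_config
  gen <- random_genome(c(chrS = 60000), seed = 61)
  om <- origin_model("chrS", 30000, 1)
  run <- simulate_genome_run(gen, om, 6, cfg, matrices = fx_matrices, seed = 17)
  res <- run_tm_pipeline(run$reads, fx_matrices, keep_profiles = TRUE)
  ini <- res$events[res$events$type == "initiation", ]
  expect_gt(nrow(ini), 0)
  rid <- ini$read_id[1]
  pr <- res$profiles[res$profiles$read_id == rid, ]
  L <- max(pr$position) + min(pr$position)
  mirrored <- prof_tbl(rev(L - pr$position), rev(pr$value), read_id = rid)
  par <- detection_params("TM")
  tr <- detect_read_tracks(mirrored, par)
  orig_tr <- res$tracks[res$tracks$read_id == rid, ]
  expect_equal(nrow(tr), nrow(orig_tr))
  flip <- c(right = "left", left = "right")
  expect_equal(sort(unname(flip[orig_tr$orientation])),
               sort(tr$orientation))
  ev <- call_events(tr, mirrored, par)
  expect_true("initiation" %in% ev$type)
  mir_ini <- ev$midpoint[ev$type == "initiation"]
  expect_lt(min(abs((L - mir_ini) - ini$midpoint[ini$read_id == rid][1])), 500)
})

test_that("method events merge greedily within the sharing distance", {
  mk_ev <- function(read_id, type, mid, method) {
    tibble::tibble(read_id = read_id, chrom = "c", type = type, midpoint = mid,
                   fork_start_left = mid - 2000, fork_start_right = mid + 2000,
                   method = method)
  }
  cnn <- mk_ev("r1", "initiation", 10000, "CNN")
  tm <- mk_ev("r1", "initiation", 11500, "TM")
  pooled <- merge_method_events(cnn, tm)
  expect_equal(nrow(pooled), 1)
  expect_true(pooled$shared)
  expect_equal(pooled$midpoint, 10750)
  # beyond 2 kb: two pooled events, none shared
  tm2 <- mk_ev("r1", "initiation", 12500, "TM")
  pooled2 <- merge_method_events(cnn, tm2)
  expect_equal(nrow(pooled2), 2)
  expect_false(any(pooled2$shared))
  # one empty list: pool equals the other
  pooled3 <- merge_method_events(cnn, cnn[0, ])
  expect_equal(nrow(pooled3), 1)
  expect_false(any(pooled3$shared))
  # different event types never share
  pooled4 <- merge_method_events(cnn, mk_ev("r1", "termination", 10100, "TM"))
  expect_equal(nrow(pooled4), 2)
})
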