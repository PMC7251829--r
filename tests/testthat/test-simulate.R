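test_that("transition matrices differ only where requested and positively", {
  tms <- fx_matrices
  gap <- abs(tms$tm_t$delta - tms$tm_b$delta)
  expect_equal(sum(gap > 0.4), round(4096 * 0.125))
  expect_equal(sum(gap > 0.4), sum(tms$informative))
  # displaced hexamers all have a T at position 3, shifted upward
  t3 <- substr(hexamers(), 3, 3) == "T"
  expect_true(all(t3[tms$informative]))
  expect_true(all((tms$tm_b$delta - tms$tm_t$delta)[tms$informative] > 0.4))
  # hexamers with no T at the center of either pentamer are identical
  hx <- hexamers()
  no_t <- substr(hx, 3, 3) != "T" & substr(hx, 4, 4) != "T"
  expect_equal(tms$tm_t$delta[no_t], tms$tm_b$delta[no_t])
})

test_that("degenerate informative fraction gives identical matrices", {
  tms0 <- make_transition_matrices(sim_config(seed = 5, informative_fraction = 0))
  expect_equal(tms0$tm_t$delta, tms0$tm_b$delta)
  expect_false(any(tms0$informative))
})

test_that("transition matrices round-trip through the table format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_transition_matrices(fx_matrices$tm_t, fx_matrices$tm_b, path)
  back <- read_transition_matrices(path)
  expect_equal(back$tm_t$delta, fx_matrices$tm_t$delta, tolerance = 1e-9)
  expect_equal(back$tm_b$delta, fx_matrices$tm_b$delta, tolerance = 1e-9)
})

test_that("pulse-chase profile is asymmetric and mirrors under orientation", {
  cfg <- fx_config
  right <- pulse_chase_profile(5000, "right", cfg)
  expect_true(all(right$prob >= 0 & right$prob <= 1))
  peak_at <- which.max(right$prob)
  # steep rise: peak reached early; shallow decay afterwards
  expect_lt(peak_at, nrow(right) * 0.2)
  expect_lt(right$prob[1], 0.05)
  expect_gt(max(right$prob), 0.5)
  expect_lt(abs(right$prob[nrow(right)] - cfg$chase_floor), 0.1)
  left <- pulse_chase_profile(5000, "left", cfg)
  expect_equal(left$prob, rev(right$prob))
})

test_that("noiseless BrdU-free read reproduces the thymidine matrix exactly", {
  cfg <- fx_config_clean
  tms <- fx_matrices
  rd <- simulate_read(fx_genome[[1]], 0, tms, config = cfg, seed = 9)
  codes <- strsplit(fx_genome[[1]], "")[[1]]
  expect_equal(length(rd$shifts[[1]]), nchar(fx_genome[[1]]) - 1)
  # shifts at complete-hexamer transitions equal the TM_T lookups
  n <- nchar(fx_genome[[1]])
  hx_str <- substring(fx_genome[[1]], 1:(n - 5), 6:n)
  expected <- fx_matrices$tm_t$delta[match(hx_str, hexamers())]
  expect_equal(rd$shifts[[1]][1:(n - 5)], expected, tolerance = 1e-12)
})

test_that("fully substituted noiseless read is called B at informative sites", {
  cfg <- fx_config_clean
  rd <- simulate_read(fx_genome[[1]], 1, fx_matrices, config = cfg, seed = 4)
  calls <- call_tm(rd, fx_matrices$tm_t, fx_matrices$tm_b)
  expect_true(all(calls$call %in% c("B", "X")))
  expect_gt(sum(calls$call == "B"), 0)
  # every non-X call is at an informative hexamer
  n <- nchar(fx_genome[[1]])
  hx_str <- substring(fx_genome[[1]], 1:(n - 5), 6:n)
  inf_hex <- hexamers()[fx_matrices$informative]
  # 0-based central-T coordinate pos maps to hexamer start i = pos - 1
  called_hex <- hx_str[calls$position[calls$call == "B"] - 1]
  expect_true(all(called_hex %in% inf_hex))
})

test_that("drift injection is recovered by the closed-form fit", {
  rd <- simulate_read(fx_genome[[1]], 0, fx_matrices, drift = c(2, 0.5),
                      config = fx_config_clean, seed = 3)
  fit <- fit_drift(rd, fx_matrices$tm_t)
  expect_equal(fit$alpha, 2, tolerance = 1e-6)
  expect_equal(fit$beta, 0.5, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-12)
})

test_that("read simulation rejects degenerate inputs", {
  expect_error(simulate_read("ACGTA", 0, fx_matrices), "at least 6")
  expect_error(simulate_chimeric_read(transition_point = 0,
                                      matrices = fx_matrices,
                                      read_length = 1000), "interior")
})

test_that("realized incorporation matches the requested probability field", {
  cfg <- fx_config
  p_req <- 0.35
  reads <- simulate_cohort(30, p_req, fx_matrices, cfg, read_length = 3000,
                           seed = 11)
  tsite <- purrr::map2(reads$bases, reads$truth_incorp, function(b, inc) {
    inc[strsplit(b, "")[[1]] == "T"]
  })
  inc_all <- unlist(tsite)
  # binomial sampling error around the requested probability
  expect_lt(abs(mean(inc_all) - p_req), 4 * sqrt(p_req * (1 - p_req) / length(inc_all)))
})

test_that("seeded simulation is reproducible", {
  a <- simulate_cohort(3, 0.5, fx_matrices, fx_config, read_length = 800, seed = 21)
  b <- simulate_cohort(3, 0.5, fx_matrices, fx_config, read_length = 800, seed = 21)
  expect_identical(a$currents, b$currents)
  expect_identical(a$truth_incorp, b$truth_incorp)
})

test_that("single efficient origin yields divergent truth around it", {
  gen <- random_genome(c(chrS = 80000), seed = 31)
  om <- origin_model("chrS", 40000, 1)
  run <- simulate_genome_run(gen, om, 10, fx_config, matrices = fx_matrices,
                             seed = 13)
  tt <- run$truth_tracks
  expect_true(all(tt$orientation[tt$start >= 40000] == "right"))
  expect_true(all(tt$orientation[tt$end <= 40000] == "left"))
  ini <- run$truth_events[run$truth_events$type == "initiation", ]
  expect_true(all(ini$midpoint == 40000))
})

test_that("zero-efficiency origins yield no tracks and no events", {
  gen <- random_genome(c(chrS = 40000), seed = 32)
  om <- origin_model("chrS", 20000, 0)
  run <- simulate_genome_run(gen, om, 5, fx_config, matrices = fx_matrices,
                             seed = 14)
  expect_equal(nrow(run$truth_tracks), 0)
  expect_equal(nrow(run$truth_events), 0)
  expect_true(all(vapply(run$reads$read_id, function(id) TRUE, logical(1))))
})
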