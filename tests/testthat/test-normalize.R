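test_that("current shifts follow the m_i - m_(i+1) definition", {
  expect_equal(compute_shifts(c(10, 8, 11)), c(2, -3))
  expect_equal(compute_shifts(rep(4, 6)), rep(0, 5))
  expect_length(compute_shifts(rnorm(17)), 16)
  expect_error(compute_shifts(5), "at least 2")
})

test_that("transition-matrix estimation averages observed shifts", {
  # two hand-built reads sharing one hexamer with shifts 1.0 and 3.0
  hex <- "ACGTAC"
  mk_read <- function(id, d1) {
    shifts <- c(d1, 0.5, 0.5, 0.5, 0.5)
    tibble::tibble(read_id = id, chrom = "c", ref_start = 0, strand = "+",
                   bases = "ACGTAC", currents = list(rev(cumsum(rev(c(shifts, 0))))),
                   shifts = list(shifts))
  }
  tm <- estimate_transition_matrix(dplyr::bind_rows(mk_read("a", 1), mk_read("b", 3)),
                                   min_occurrences = 1)
  expect_equal(tm$delta[match(hex, tm$hexamer)], 2.0)
  expect_equal(tm$n_obs[match(hex, tm$hexamer)], 2L)
  expect_true(all(tm$imputed[tm$n_obs == 0]))
})

test_that("matrix recovery error scales with noise over sqrt(n)", {
  cfg <- sim_config(seed = 6, noise_sd = 0.2)
  reads <- simulate_cohort(40, 0, fx_matrices, cfg, read_length = 5000, seed = 7)
  tm <- estimate_transition_matrix(reads, min_occurrences = 1)
  obs <- tm$n_obs > 5
  err <- abs(tm$delta - fx_matrices$tm_t$delta)[obs]
  se <- 0.2 / sqrt(tm$n_obs[obs])
  # errors behave like mean-of-n noise: bounded by ~5 standard errors
  expect_lt(max(err / se), 5.5)
  expect_lt(abs(mean(err / se) - sqrt(2 / pi)), 0.15)
})

test_that("drift fit is the exact least-squares optimum", {
  rd <- simulate_read(fx_genome[[1]], 0, fx_matrices,
                      config = fx_config_clean, seed = 2)
  fit0 <- fit_drift(rd, fx_matrices$tm_t)
  expect_equal(fit0$alpha, 1, tolerance = 1e-9)
  expect_equal(fit0$beta, 0, tolerance = 1e-9)
  expect_equal(fit0$residual, 0, tolerance = 1e-15)
  # halving the signal doubles alpha
  rd2 <- rd
  rd2$shifts <- list(rd$shifts[[1]] * 0.5)
  fit2 <- fit_drift(rd2, fx_matrices$tm_t)
  expect_equal(fit2$alpha, 2, tolerance = 1e-9)
  expect_equal(fit2$beta, 0, tolerance = 1e-9)
  # tidy/glance expose the estimates
  td <- generics::tidy(fit2)
  expect_equal(td$estimate[td$term == "alpha"], 2, tolerance = 1e-9)
  expect_equal(generics::glance(fit2)$n_used, fit2$n_used)
})

test_that("closed-form drift fit matches a brute-force grid oracle", {
  set.seed(42)
  cfg <- sim_config(seed = 8, noise_sd = 0.3)
  for (k in 1:20) {
    alpha_true <- runif(1, 0.5, 2)
    beta_true <- runif(1, -0.5, 0.5)
    rd <- simulate_read(fx_genome[[1]], 0, fx_matrices,
                        drift = c(alpha_true, beta_true), config = cfg)
    fit <- fit_drift(rd, fx_matrices$tm_t)
    # coarse grid around the closed-form solution: no grid point does better
    objective <- function(a, b) {
      codes <- strsplit(rd$bases[[1]], "")[[1]]
      n <- length(codes)
      hx_str <- substring(rd$bases[[1]], 1:(n - 5), 6:n)
      hexes <- hexamers()
      eligible <- !(substr(hx_str, 3, 3) == "T" | substr(hx_str, 4, 4) == "T")
      de <- fx_matrices$tm_t$delta[match(hx_str, hexes)]
      d <- rd$shifts[[1]][1:(n - 5)]
      mean((a * d[eligible] + b - de[eligible])^2)
    }
    best <- objective(fit$alpha, fit$beta)
    grid <- expand.grid(a = fit$alpha + seq(-0.05, 0.05, length.out = 7),
                        b = fit$beta + seq(-0.05, 0.05, length.out = 7))
    vals <- mapply(objective, grid$a, grid$b)
    expect_true(all(best <= vals + 1e-12))
    expect_equal(fit$residual, best, tolerance = 1e-9)
  }
})

test_that("residual cutoff is a strict inequality at 0.25", {
  set.seed(77)
  reads <- simulate_cohort(4, 0, fx_matrices, fx_config_clean,
                           read_length = 2000, seed = 5)
  # inflate two reads with heavy noise so their residuals exceed the cutoff
  reads$shifts[[3]] <- reads$shifts[[3]] + rnorm(length(reads$shifts[[3]]), 0, 2)
  reads$shifts[[4]] <- reads$shifts[[4]] + rnorm(length(reads$shifts[[4]]), 0, 2)
  out <- normalize_reads(reads, fx_matrices$tm_t, residual_cutoff = 0.25)
  log <- rejection_log(out)
  expect_equal(sort(log$read_id), c("read3", "read4"))
  expect_true(all(log$residual > 0.25))
  expect_true(all(out$fit_residual <= 0.25))
  # noiseless cohort: zero rejections
  clean <- normalize_reads(reads[1:2, ], fx_matrices$tm_t)
  expect_equal(nrow(rejection_log(clean)), 0)
})

test_that("normalization is idempotent on noiseless input", {
  rd <- simulate_read(fx_genome[[1]], 0, fx_matrices, drift = c(1.7, -0.3),
                      config = fx_config_clean, seed = 6)
  once <- normalize_reads(rd, fx_matrices$tm_t)
  fit <- fit_drift(once, fx_matrices$tm_t)
  expect_equal(fit$alpha, 1, tolerance = 1e-6)
  expect_equal(fit$beta, 0, tolerance = 1e-6)
})

test_that("matrix estimation is invariant to read order", {
  reads <- simulate_cohort(10, 0.4, fx_matrices, fx_config,
                           read_length = 2000, seed = 9)
  tm1 <- estimate_transition_matrix(reads, min_occurrences = 1)
  tm2 <- estimate_transition_matrix(reads[sample(nrow(reads)), ],
                                    min_occurrences = 1)
  expect_equal(tm1$delta, tm2$delta, tolerance = 1e-12)
})

test_that("two-step reference estimation recovers both matrices", {
  cfg <- sim_config(seed = 10, noise_sd = 0.15)
  reads_t <- simulate_cohort(60, 0, fx_matrices, cfg, read_length = 4000,
                             drift = c(1.1, 0.05), seed = 15)
  reads_b <- simulate_cohort(60, 1, fx_matrices, cfg, read_length = 4000,
                             drift = c(0.9, -0.05), seed = 16)
  suppressMessages({
    ref <- build_reference_matrices(reads_t, reads_b, min_occurrences = 1)
  })
  # each condition's normalization frame is identifiable only up to that
  # ensemble's shared affine drift: align per condition before comparing
  obs_t <- ref$tm_t$n_obs > 20
  align_t <- stats::lm(ref$tm_t$delta[obs_t] ~ fx_matrices$tm_t$delta[obs_t])
  expect_lt(stats::median(abs(stats::residuals(align_t))), 0.02)
  # estimate the B-condition frame from hexamers identical in both
  # contexts, then check recovery at the informative hexamers
  shared <- !(substr(hexamers(), 3, 3) == "T" | substr(hexamers(), 4, 4) == "T")
  sh <- shared & ref$tm_b$n_obs > 20
  align_b <- stats::lm(ref$tm_b$delta[sh] ~ fx_matrices$tm_b$delta[sh])
  inf <- fx_matrices$informative & ref$tm_b$n_obs > 20
  pred_b <- stats::coef(align_b)[1] +
    stats::coef(align_b)[2] * fx_matrices$tm_b$delta[inf]
  expect_lt(stats::median(abs(ref$tm_b$delta[inf] - pred_b)), 0.05)
  expect_true(all(c("condition", "replicate", "n_rejected") %in%
                    names(ref$rejections)))
  # identical replicates: averaging is a no-op
  suppressMessages({
    ref2 <- build_reference_matrices(list(reads_t, reads_t), reads_b,
                                     min_occurrences = 1)
  })
  expect_equal(ref2$tm_t$delta, ref$tm_t$delta, tolerance = 1e-9)
})
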