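mk_events <- function(midpoints, chrom = "c", type = "initiation") {
  tibble::tibble(chrom = chrom, midpoint = midpoints, type = type)
}

test_that("event clustering chains gaps below the limit", {
  cl <- cluster_events(mk_events(c(0, 1000, 3000)), mied = 1500)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$d), c(1L, 2L))
  two <- cl[cl$d == 2, ]
  expect_equal(two$width, 1000)
  expect_equal(two$median_point, 500)
  # gaps at the limit do not merge (strict inequality)
  cl2 <- cluster_events(mk_events(c(0, 1500)), mied = 1500)
  expect_equal(nrow(cl2), 2)
  cl3 <- cluster_events(mk_events(c(0, 1499)), mied = 1500)
  expect_equal(nrow(cl3), 1)
})

test_that("clustering equals connected components on random fixtures", {
  set.seed(101)
  for (k in 1:50) {
    n <- sample(20:100, 1)
    ev <- mk_events(sort(round(runif(n, 0, 50000))),
                    chrom = sample(c("cA", "cB"), n, replace = TRUE))
    mied <- sample(c(300, 800, 1500, 4000), 1)
    cl <- cluster_events(ev, mied)
    oracle <- cluster_oracle(ev$chrom, ev$midpoint, mied)
    expect_equal(nrow(cl), length(unique(paste(ev$chrom, oracle))))
    expect_equal(sum(cl$d), n)
    expect_true(all(cl$width <= (cl$d - 1) * mied))
    # each oracle component's span matches one cluster
    spans <- tapply(ev$midpoint, paste(ev$chrom, oracle), function(p) max(p) - min(p))
    expect_equal(as.numeric(sort(spans)), sort(cl$width))
  }
})

test_that("cluster sweep behaves monotonically at its extremes", {
  set.seed(11)
  ev <- mk_events(sort(c(runif(60, 0, 100000),
                         rep(c(20000, 50000), each = 10) + rnorm(20, 0, 300))))
  grid <- c(0, 500, 1500, 5000, 1e7)
  sw <- cluster_sweep(ev, grid)
  expect_true(all(diff(sw$n_singleton) <= 0))
  expect_true(all(sw$total_events == nrow(ev)))
  expect_equal(sw$n_clusters[sw$mied == 1e7], 1)          # one per chromosome
  expect_equal(sw$n_singleton[sw$mied == 0], nrow(ev))    # all singletons
})

test_that("clustered events show a stable cluster-number plateau absent in shuffles", {
  set.seed(12)
  centers <- seq(10000, 190000, by = 20000)
  ev <- mk_events(sort(unlist(lapply(centers, function(c) c + rnorm(8, 0, 400)))))
  gen <- tibble::tibble(chrom = "c", length = 200000)
  grid <- c(1500, 2500, 4000, 6000)
  sw <- cluster_sweep(ev, grid)
  shuf <- shuffle_events(ev, gen, seed = 5)
  sw_s <- cluster_sweep(shuf, grid)
  # real clusters: the multi-event cluster count stays at the planted number
  expect_true(all(abs(sw$n_multi - length(centers)) <= 1))
  # shuffled control: no such plateau; counts drift with the limit
  expect_gt(max(sw_s$n_multi) - min(sw_s$n_multi), 3)
})

test_that("shuffling preserves per-chromosome counts and is seeded", {
  ev <- mk_events(c(100, 5000, 9000, 1000, 2000),
                  chrom = c("cA", "cA", "cA", "cB", "cB"))
  gen <- tibble::tibble(chrom = c("cA", "cB"), length = c(10000, 8000))
  s1 <- shuffle_events(ev, gen, seed = 3)
  s2 <- shuffle_events(ev, gen, seed = 3)
  expect_identical(s1, s2)
  expect_equal(table(s1$chrom), table(ev$chrom))
  expect_true(all(s1$midpoint >= 0))
  expect_true(all(s1$midpoint < gen$length[match(s1$chrom, gen$chrom)]))
})

test_that("shuffled nearest-distance ECDF matches the uniform model", {
  # single annotation at the center: distance of a uniform point on [0, L)
  # to the center is uniform on [0, L/2)
  gen <- tibble::tibble(chrom = "c", length = 100000)
  ann <- tibble::tibble(chrom = "c", start = 49000, end = 51000)
  ev <- mk_events(rep(1, 4000))
  set.seed(13)
  sh <- shuffle_events(ev, gen, seed = 7)
  d <- distance_to_nearest(sh, ann)$distance
  expect_lt(suppressWarnings(stats::ks.test(d / 50000, "punif")$statistic), 0.03)
})

test_that("distances to nearest annotation centers are exact", {
  ann <- tibble::tibble(chrom = "c", start = c(4000, 20000), end = c(6000, 24000))
  q <- mk_events(c(5000, 7000, 30000))
  d <- distance_to_nearest(q, ann)$distance
  expect_equal(d, c(0, 2000, 8000))
  expect_error(distance_to_nearest(q, ann[0, ]), "empty annotation")
  # hand-checkable fraction within 2 kb
  expect_equal(mean(d <= 2000), 2 / 3)
})

test_that("dimension classes follow the standard grouping", {
  cls <- dimension_class(c(1, 2, 4, 5, 12, 13, 45))
  expect_equal(as.character(cls), c("1", "2-4", "2-4", "5-12", "5-12",
                                    ">12", ">12"))
})

test_that("overlap fractions after resizing match a brute-force check", {
  a <- tibble::tibble(chrom = "c", start = c(1000, 5000, 9000),
                      end = c(1400, 5400, 9400))
  expect_equal(overlap_fraction(a, a), list(a_in_b = 1, b_in_a = 1))
  # centers 2,100 apart after 2-kb resize: gap of 100, no overlap
  b1 <- tibble::tibble(chrom = "c", start = 1000, end = 1000)
  b2 <- tibble::tibble(chrom = "c", start = 3100, end = 3100)
  ov <- overlap_fraction(b1, b2)
  expect_equal(ov$a_in_b, 0)
  # brute force on an asymmetric random fixture
  set.seed(14)
  x <- tibble::tibble(chrom = "c", start = runif(12, 0, 30000))
  x$end <- x$start + 200
  y <- tibble::tibble(chrom = "c", start = runif(5, 0, 30000))
  y$end <- y$start + 200
  ov2 <- overlap_fraction(x, y, resize = 2000)
  brute <- function(p, q) {
    mean(vapply(seq_len(nrow(p)), function(i) {
      ci <- (p$start[i] + p$end[i]) / 2
      any(abs(ci - (q$start + q$end) / 2) < 2000)
    }, logical(1)))
  }
  expect_equal(ov2$a_in_b, brute(x, y))
  expect_equal(ov2$b_in_a, brute(y, x))
})

test_that("timing assignment reads the normalized signal per bin", {
  timing <- tibble::tibble(chrom = "c", start = (0:9) * 1000,
                           end = (1:10) * 1000,
                           value = seq(0, 1, length.out = 10))
  class(timing) <- c("genome_signal", class(timing))
  attr(timing, "bin") <- 1000; attr(timing, "kind") <- "timing"
  ev <- mk_events(c(500, 9500, 25000))
  out <- assign_timing(ev, timing)
  expect_equal(out$timing[1], 0)
  expect_equal(out$timing[2], 1)
  expect_true(out$timing_missing[3])
})

test_that("PWM scanning matches a per-position brute-force oracle", {
  set.seed(15)
  mat <- matrix(runif(4 * 6), 4, 6)
  p <- pwm(mat, threshold = 0.8)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  brute <- function(seqs, p) {
    hits <- list()
    maxs <- sum(apply(p$matrix, 2, max))
    for (ch in names(seqs)) {
      s <- seqs[[ch]]
      n <- nchar(s)
      for (i in seq_len(n - 5)) {
        for (strand in c("+", "-")) {
          sub <- substr(s, i, i + 5)
          if (strand == "-") sub <- revcomp(sub)
          b <- strsplit(sub, "")[[1]]
          sc <- sum(p$matrix[cbind(match(b, c("A", "C", "G", "T")), 1:6)])
          if (sc >= p$threshold * maxs) {
            hits[[length(hits) + 1]] <- tibble::tibble(
              chrom = ch, position = i - 1L, strand = strand, score = sc)
          }
        }
      }
    }
    dplyr::arrange(dplyr::bind_rows(hits), chrom, position, strand)
  }
  for (k in 1:10) {
    seqs <- random_genome(c(s1 = 300), seed = 200 + k)
    got <- dplyr::arrange(pwm_scan(seqs, p), chrom, position, strand)
    want <- brute(seqs, p)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$position, want$position)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }
})

test_that("PWM consensus scores maximally and threshold 1 keeps only it", {
  mat <- matrix(0.1, 4, 5)
  consensus <- c(1, 3, 4, 2, 1)  # A G T C A
  mat[cbind(consensus, 1:5)] <- 0.9
  p1 <- pwm(mat, threshold = 1)
  cons_seq <- paste(c("A", "G", "T", "C", "A"), collapse = "")
  hits <- pwm_scan(c(chr = paste0(cons_seq, "CCCCC")), p1)
  fw <- hits[hits$strand == "+", ]
  expect_equal(fw$position, 0L)
  expect_equal(fw$score, 4.5)
  # motif longer than the sequence: no matches
  expect_equal(nrow(pwm_scan(c(chr = "ACG"), p1)), 0)
})

test_that("PWM scan agrees with Biostrings where threshold semantics coincide", {
  # per-column minima of zero make 80% of max equal in both conventions
  set.seed(16)
  mat <- matrix(runif(4 * 7), 4, 7)
  mat <- sweep(mat, 2, apply(mat, 2, min))   # column minima exactly 0
  rownames(mat) <- c("A", "C", "G", "T")
  p <- pwm(mat, threshold = 0.8)
  seqs <- random_genome(c(s = 2000), seed = 17)
  mine <- pwm_scan(seqs, p)
  fw <- sort(mine$position[mine$strand == "+"])
  bs <- Biostrings::matchPWM(mat, Biostrings::DNAString(seqs[[1]]),
                             min.score = "80%")
  expect_equal(fw, BiocGenerics::start(bs) - 1L)
})

test_that("motif fraction reports the observed rate against a shuffled null", {
  matches <- tibble::tibble(chrom = "c", position = c(1000, 5000), strand = "+",
                            score = 1)
  win_all <- tibble::tibble(chrom = "c", start = c(900, 4900), end = c(1100, 5100))
  out <- motif_fraction(win_all, matches, n_shuffle = 0)
  expect_equal(out$observed, 1)
  win_none <- tibble::tibble(chrom = "c", start = c(2000, 3000), end = c(2200, 3200))
  expect_equal(motif_fraction(win_none, matches, n_shuffle = 0)$observed, 0)
  # planted-motif recovery: windows on the matches beat the shuffled null
  gen <- tibble::tibble(chrom = "c", length = 1000000)
  dense <- tibble::tibble(chrom = "c", position = seq(0, 99) * 37 + 100,
                          strand = "+", score = 1)
  wins <- tibble::tibble(chrom = "c", start = dense$position - 1000,
                         end = dense$position + 1000)
  out2 <- motif_fraction(wins, dense, gen, n_shuffle = 200, seed = 9)
  expect_equal(out2$observed, 1)
  expect_gt(out2$observed, out2$quantiles[["99%"]])
})

test_that("ECDF of distances is a proper distribution function", {
  set.seed(18)
  ann <- tibble::tibble(chrom = "c", start = seq(0, 90000, by = 10000),
                        end = seq(0, 90000, by = 10000) + 100)
  q <- mk_events(runif(200, 0, 90000))
  d <- distance_to_nearest(q, ann)$distance
  f <- stats::ecdf(d)
  grid <- seq(0, max(d), length.out = 50)
  expect_true(all(diff(f(grid)) >= 0))
  expect_equal(f(max(d)), 1)
})
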