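# Event clustering, randomization controls, annotation comparisons and
# motif scanning.

#' Cluster events by inter-event distance
#'
#' Single-linkage chaining per chromosome: consecutive events closer than
#' the clustering limit `mied` (strict inequality) share a cluster.  A
#' cluster's dimension `d` is its number of events, its width the
#' distance between its outmost members, and its median point the
#' (interpolated) median of the member coordinates.
#'
#' @param events Event tibble with `chrom` and `midpoint`.
#' @param mied Maximal inter-event distance (nt) for chaining.
#' @return Cluster tibble: `chrom`, `cluster`, `start`, `end`, `d`,
#'   `width`, `median_point`, `mied`.
#' @export
cluster_events <- function(events, mied = 1500) {
  if (!nrow(events)) {
    return(tibble::tibble(chrom = character(0), cluster = integer(0),
                          start = numeric(0), end = numeric(0),
                          d = integer(0), width = numeric(0),
                          median_point = numeric(0), mied = numeric(0)))
  }
  out <- events %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::group_map(function(g, key) {
      p <- sort(g$midpoint)
      cl <- cumsum(c(TRUE, diff(p) >= mied))
      tibble::tibble(midpoint = p, cluster = cl) %>%
        dplyr::group_by(.data$cluster) %>%
        dplyr::summarise(start = min(.data$midpoint),
                         end = max(.data$midpoint),
                         d = dplyr::n(),
                         median_point = stats::median(.data$midpoint),
                         .groups = "drop") %>%
        dplyr::mutate(chrom = key$chrom)
    })
  out <- dplyr::bind_rows(out)
  out$width <- out$end - out$start
  out$mied <- mied
  out[, c("chrom", "cluster", "start", "end", "d", "width",
          "median_point", "mied")]
}

#' Cluster-count and width curves over a grid of clustering limits
#'
#' @param events Event tibble.
#' @param mied_grid Numeric vector of clustering limits (nt).
#' @return Tibble per `mied`: `n_singleton` (d = 1), `n_multi` (d > 1),
#'   `n_clusters`, `total_events`, and width quartiles of the d > 1
#'   clusters.
#' @export
cluster_sweep <- function(events, mied_grid) {
  purrr::map_dfr(mied_grid, function(m) {
    cl <- cluster_events(events, m)
    multi <- cl[cl$d > 1L, , drop = FALSE]
    tibble::tibble(
      mied = m,
      n_singleton = sum(cl$d == 1L),
      n_multi = nrow(multi),
      n_clusters = nrow(cl),
      total_events = sum(cl$d),
      width_q25 = if (nrow(multi)) stats::quantile(multi$width, 0.25) else NA_real_,
      width_median = if (nrow(multi)) stats::median(multi$width) else NA_real_,
      width_q75 = if (nrow(multi)) stats::quantile(multi$width, 0.75) else NA_real_
    )
  })
}

#' Shuffle events uniformly per chromosome
#'
#' Randomization control: events are redistributed uniformly over each
#' chromosome while keeping the per-chromosome event counts constant.
#'
#' @param events Event tibble with `chrom` and `midpoint`.
#' @param genome Tibble (`chrom`, `length`) or named sequences.
#' @param seed Optional seed.
#' @return Event tibble with shuffled `midpoint`s.
#' @export
shuffle_events <- function(events, genome, seed = NULL) {
  genome <- as_genome_tbl(genome)
  len <- stats::setNames(genome$length, genome$chrom)
  with_seed(seed, {
    out <- events
    for (ch in unique(events$chrom)) {
      idx <- which(events$chrom == ch)
      out$midpoint[idx] <- floor(stats::runif(length(idx), 0, len[[ch]]))
    }
    out
  })
}

#' Distance from query points to the nearest annotation center
#'
#' Midpoint-to-center distances: each query point is compared with the
#' centers of the annotation intervals on its chromosome.
#'
#' @param queries Tibble with `chrom` and a point column (`midpoint`,
#'   `median_point` or `position`).
#' @param annotations Tibble with `chrom`, `start`, `end` (0-based
#'   half-open) or `chrom` + `center`.
#' @return `queries` with a `distance` column (`NA` where the query's
#'   chromosome has no annotation; an error if no chromosome has any).
#' @export
distance_to_nearest <- function(queries, annotations) {
  if (!nrow(annotations)) stop("empty annotation set")
  centers <- if ("center" %in% names(annotations)) {
    annotations$center
  } else {
    (annotations$start + annotations$end) / 2
  }
  pcol <- intersect(c("midpoint", "median_point", "position"), names(queries))[1]
  if (is.na(pcol)) stop("queries need a midpoint/median_point/position column")
  ann_split <- split(centers, annotations$chrom)
  queries$distance <- vapply(seq_len(nrow(queries)), function(i) {
    cc <- ann_split[[queries$chrom[i]]]
    if (is.null(cc)) return(NA_real_)
    min(abs(cc - queries[[pcol]][i]))
  }, numeric(1))
  queries
}

#' Group cluster dimensions into the standard classes
#'
#' @param d Integer vector of cluster dimensions.
#' @param breaks Class boundaries; defaults to d = 1, 2-4, 5-12, >12.
#' @return Ordered factor of dimension classes.
#' @export
dimension_class <- function(d, breaks = c(1, 4, 12)) {
  cut(d, breaks = c(0, breaks, Inf),
      labels = c("1", paste0(utils::head(breaks, -1) + 1, "-",
                             breaks[-1]),
                 paste0(">", breaks[length(breaks)])),
      ordered_result = TRUE)
}

#' Fraction of two interval sets overlapping after midpoint resizing
#'
#' Every interval is resized to `resize` nucleotides centered on its
#' midpoint; overlap means any positive intersection.
#'
#' @param set_a,set_b Tibbles with `chrom`, `start`, `end` (or `chrom` +
#'   point column, treated as zero-width).
#' @param resize Width (nt) after resizing.
#' @return List with `a_in_b` and `b_in_a`, the fractions of elements of
#'   each set overlapping the other.
#' @export
overlap_fraction <- function(set_a, set_b, resize = 2000) {
  as_ranges <- function(x) {
    if (!all(c("start", "end") %in% names(x))) {
      pcol <- intersect(c("midpoint", "median_point", "position"), names(x))[1]
      x$start <- x[[pcol]]
      x$end <- x[[pcol]]
    }
    mid <- (x$start + x$end) / 2
    GenomicRanges::GRanges(x$chrom,
                           IRanges::IRanges(start = round(mid - resize / 2) + 1L,
                                            width = resize))
  }
  ga <- as_ranges(set_a)
  gb <- as_ranges(set_b)
  list(a_in_b = mean(IRanges::overlapsAny(ga, gb)),
       b_in_a = mean(IRanges::overlapsAny(gb, ga)))
}

#' Assign replication timing to events
#'
#' Looks up, for each event, the value of the (normalized) timing signal
#' in the bin containing its midpoint.  Events falling in missing bins
#' are flagged and get `NA`.
#'
#' @param events Event tibble with `chrom`, `midpoint`.
#' @param timing A `genome_signal` of kind `"timing"` (values in
#'   `[0, 1]`, 0 = start and 1 = end of S phase).
#' @return `events` with `timing` and `timing_missing` columns.
#' @export
assign_timing <- function(events, timing) {
  bin <- attr(timing, "bin")
  sig_split <- split(timing, timing$chrom)
  events$timing <- vapply(seq_len(nrow(events)), function(i) {
    s <- sig_split[[events$chrom[i]]]
    if (is.null(s)) return(NA_real_)
    idx <- floor(events$midpoint[i] / bin) + 1L
    if (idx < 1L || idx > nrow(s)) return(NA_real_)
    s$value[idx]
  }, numeric(1))
  events$timing_missing <- is.na(events$timing)
  events
}

# ---- position weight matrix scanning --------------------------------------

#' Build a position weight matrix object
#'
#' @param matrix Numeric matrix, 4 rows (A, C, G, T) by motif length.
#' @param threshold Fraction of the maximum attainable score a site must
#'   reach to count as a match.
#' @return List of class `pwm` with the matrix and threshold.
#' @export
pwm <- function(matrix, threshold = 0.8) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4L, threshold > 0, threshold <= 1)
  rownames(matrix) <- BASES
  structure(list(matrix = matrix, threshold = threshold), class = "pwm")
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

# score every start position of a coded sequence against the PWM columns
pwm_scores <- function(codes, mat) {
  w <- ncol(mat)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (k in seq_len(w)) {
    sc <- sc + unname(mat[codes[seq_len(n) + k - 1L] + 1L, k])
  }
  sc
}

#' Scan sequences for PWM matches on both strands
#'
#' Weight-sum scoring: a site's score is the sum over motif positions of
#' the weight of the base present.  Matches are positions whose score is
#' at least `threshold` times the maximum attainable score (the sum of
#' the column maxima).  The reverse strand is scanned by scoring the
#' reverse complement; reported positions always refer to the forward
#' strand (0-based start of the matched window).
#'
#' @param sequences Named character vector (or `DNAStringSet`).
#' @param pwm A [pwm()].
#' @return Tibble with `chrom`, `position`, `strand`, `score`.
#' @export
pwm_scan <- function(sequences, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  seqs <- as_sequences(sequences)
  mat <- pwm$matrix
  w <- ncol(mat)
  max_score <- sum(apply(mat, 2L, max))
  cutoff <- pwm$threshold * max_score
  out <- purrr::map(names(seqs), function(ch) {
    s <- seqs[[ch]]
    if (nchar(s) < w) return(NULL)
    fwd <- pwm_scores(base_codes(s), mat)
    rev <- pwm_scores(base_codes(revcomp(s)), mat)
    n <- nchar(s)
    hits_f <- which(fwd >= cutoff)
    hits_r <- which(rev >= cutoff)
    dplyr::bind_rows(
      tibble::tibble(chrom = ch, position = hits_f - 1L, strand = "+",
                     score = fwd[hits_f]),
      tibble::tibble(chrom = ch, position = n - w + 1L - hits_r,
                     strand = "-", score = rev[hits_r])
    )
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    return(tibble::tibble(chrom = character(0), position = integer(0),
                          strand = character(0), score = numeric(0)))
  }
  dplyr::arrange(out, .data$chrom, .data$position)
}

#' Fraction of windows containing a motif match, with a shuffled null
#'
#' Computes the fraction of the query windows containing at least one
#' PWM match, then builds a null distribution by re-centering the
#' windows uniformly per chromosome `n_shuffle` times.
#'
#' @param windows Tibble with `chrom`, `start`, `end` (e.g. 2-kb windows
#'   around sporadic events).
#' @param matches Match tibble from [pwm_scan()].
#' @param genome Tibble (`chrom`, `length`) or named sequences; required
#'   when `n_shuffle > 0`.
#' @param n_shuffle Number of shuffles for the null.
#' @param probs Percentiles of the null to report.
#' @param seed Optional seed.
#' @return List with `observed`, `null` (vector of shuffled fractions),
#'   `quantiles` and `percentile` (empirical percentile of the observed
#'   value in the null).
#' @export
motif_fraction <- function(windows, matches, genome = NULL,
                           n_shuffle = 1000L, probs = c(0.01, 0.5, 0.99),
                           seed = NULL) {
  frac_with_match <- function(win) {
    m_split <- split(matches$position, matches$chrom)
    hits <- vapply(seq_len(nrow(win)), function(i) {
      mp <- m_split[[win$chrom[i]]]
      !is.null(mp) && any(mp >= win$start[i] & mp < win$end[i])
    }, logical(1))
    mean(hits)
  }
  observed <- frac_with_match(windows)
  null <- numeric(0)
  if (n_shuffle > 0L) {
    if (is.null(genome)) stop("genome required for shuffled controls")
    genome <- as_genome_tbl(genome)
    len <- stats::setNames(genome$length, genome$chrom)
    width <- windows$end - windows$start
    null <- with_seed(seed, vapply(seq_len(n_shuffle), function(k) {
      w2 <- windows
      for (ch in unique(w2$chrom)) {
        idx <- which(w2$chrom == ch)
        ctr <- stats::runif(length(idx), 0, len[[ch]])
        w2$start[idx] <- pmax(0, round(ctr - width[idx] / 2))
        w2$end[idx] <- w2$start[idx] + width[idx]
      }
      frac_with_match(w2)
    }, numeric(1)))
  }
  list(observed = observed, null = null,
       quantiles = if (length(null)) stats::quantile(null, probs) else NULL,
       percentile = if (length(null)) mean(null <= observed) else NA_real_)
}
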