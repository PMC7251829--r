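# Genome-wide signals assembled from oriented tracks and events:
# replication fork directionality (RFD), origin efficiency metric (OEM),
# initiation-minus-termination density.

new_genome_signal <- function(tbl, kind, bin) {
  out <- tibble::as_tibble(tbl)
  class(out) <- c("genome_signal", class(out))
  attr(out, "kind") <- kind
  attr(out, "bin") <- bin
  out
}

#' @export
print.genome_signal <- function(x, ...) {
  cat("<genome_signal> kind =", attr(x, "kind"), "| bin =", attr(x, "bin"),
      "nt |", sum(!is.na(x$value)), "defined /", nrow(x), "bins\n")
  NextMethod()
}

# per-chromosome binned coverage of [start, end) intervals;
# genome: tibble(chrom, length)
binned_coverage <- function(intervals, chrom_len, bin) {
  nb <- ceiling(chrom_len / bin)
  cov <- numeric(nb)
  if (nrow(intervals)) {
    b0 <- pmax(floor(intervals$start / bin) + 1L, 1L)
    b1 <- pmin(ceiling(intervals$end / bin), nb)
    keep <- b1 >= b0
    d <- numeric(nb + 1L)
    for (i in which(keep)) {
      d[b0[i]] <- d[b0[i]] + 1
      d[b1[i] + 1L] <- d[b1[i] + 1L] - 1
    }
    cov <- cumsum(d[seq_len(nb)])
  }
  cov
}

#' Replication fork directionality from oriented tracks
#'
#' Per genomic bin, RFD = (R - L) / (R + L) over the rightward- and
#' leftward-oriented tracks covering the bin; bins with no coverage are
#' missing (explicitly `NA`, never 0, since RFD = 0 is meaningful).  The
#' binned signal is then smoothed with a centered running mean spanning
#' `smooth` nucleotides, missing bins excluded (a bin stays missing when
#' fewer than half of its window is defined).
#'
#' @param tracks Oriented track tibble (`chrom`, `start`, `end`,
#'   `orientation`); unoriented rows are ignored.
#' @param genome Tibble (`chrom`, `length`) or named sequences.
#' @param bin Internal grid size (nt).
#' @param smooth Running-mean window (nt).
#' @return A `genome_signal` tibble (`chrom`, `start`, `end`, `value`)
#'   with RFD in `[-1, 1]` where defined.
#' @export
compute_rfd <- function(tracks, genome, bin = 100, smooth = 1000) {
  genome <- as_genome_tbl(genome)
  tr <- tracks[!is.na(tracks$orientation), , drop = FALSE]
  out <- purrr::map(seq_len(nrow(genome)), function(g) {
    ch <- genome$chrom[g]; len <- genome$length[g]
    ctr <- tr[tr$chrom == ch, , drop = FALSE]
    R <- binned_coverage(ctr[ctr$orientation == "right", ], len, bin)
    L <- binned_coverage(ctr[ctr$orientation == "left", ], len, bin)
    tot <- R + L
    rfd <- ifelse(tot > 0, (R - L) / tot, NA_real_)
    rfd <- running_mean(rfd, smooth / bin)
    nb <- length(rfd)
    tibble::tibble(chrom = ch, start = (seq_len(nb) - 1) * bin,
                   end = pmin(seq_len(nb) * bin, len), value = rfd)
  })
  new_genome_signal(dplyr::bind_rows(out), "RFD", bin)
}

#' Origin efficiency metric from oriented tracks
#'
#' For each position, compares the rightward-fork fraction of coverage in
#' the `window` upstream of the position against the `window` downstream:
#' `OEM(x) = R/(R+L) over (x, x + window] - R/(R+L) over (x - window, x]`.
#' With this sign convention initiation zones (leftward forks upstream,
#' rightward downstream) are positive and termination zones negative.
#' Missing wherever either window has no coverage.
#'
#' @inheritParams compute_rfd
#' @param window Sliding window size (nt) on each side.
#' @return A `genome_signal` with OEM in `[-1, 1]` where defined.
#' @export
compute_oem <- function(tracks, genome, window = 10000, bin = 100) {
  genome <- as_genome_tbl(genome)
  w <- max(1L, round(window / bin))
  tr <- tracks[!is.na(tracks$orientation), , drop = FALSE]
  out <- purrr::map(seq_len(nrow(genome)), function(g) {
    ch <- genome$chrom[g]; len <- genome$length[g]
    ctr <- tr[tr$chrom == ch, , drop = FALSE]
    R <- binned_coverage(ctr[ctr$orientation == "right", ], len, bin)
    L <- binned_coverage(ctr[ctr$orientation == "left", ], len, bin)
    nb <- length(R)
    csR <- c(0, cumsum(R)); csL <- c(0, cumsum(L))
    # evaluation point x = start of bin i; upstream window covers bins
    # i-w .. i-1, downstream window bins i .. i+w-1
    i <- seq_len(nb)
    lo_l <- pmax(i - w, 1L)
    hi_r <- pmin(i + w - 1L, nb)
    sRl <- csR[i] - csR[lo_l]
    sLl <- csL[i] - csL[lo_l]
    sRr <- csR[hi_r + 1L] - csR[i]
    sLr <- csL[hi_r + 1L] - csL[i]
    left_frac <- ifelse(sRl + sLl > 0, sRl / (sRl + sLl), NA_real_)
    right_frac <- ifelse(sRr + sLr > 0, sRr / (sRr + sLr), NA_real_)
    tibble::tibble(chrom = ch, start = (i - 1) * bin,
                   end = pmin(i * bin, len),
                   value = right_frac - left_frac)
  })
  new_genome_signal(dplyr::bind_rows(out), "OEM", bin)
}

#' Initiation-minus-termination event density
#'
#' Counts initiation minus termination events in non-overlapping bins,
#' then applies a centered running mean spanning `smooth` nucleotides.
#'
#' @param events Event tibble (`chrom`, `midpoint`, `type`).
#' @inheritParams compute_rfd
#' @param bin Bin size (nt).
#' @param smooth Running-mean window (nt).
#' @return A `genome_signal` of kind `"IT_density"`.
#' @export
it_density <- function(events, genome, bin = 5000, smooth = 10000) {
  genome <- as_genome_tbl(genome)
  out <- purrr::map(seq_len(nrow(genome)), function(g) {
    ch <- genome$chrom[g]; len <- genome$length[g]
    nb <- ceiling(len / bin)
    ev <- events[events$chrom == ch, , drop = FALSE]
    bidx <- pmin(floor(ev$midpoint / bin) + 1L, nb)
    ini <- tabulate(bidx[ev$type == "initiation"], nbins = nb)
    ter <- tabulate(bidx[ev$type == "termination"], nbins = nb)
    val <- running_mean(as.numeric(ini - ter), smooth / bin)
    tibble::tibble(chrom = ch, start = (seq_len(nb) - 1) * bin,
                   end = pmin(seq_len(nb) * bin, len), value = val)
  })
  new_genome_signal(dplyr::bind_rows(out), "IT_density", bin)
}

#' Rank correlation between two genome signals
#'
#' Spearman correlation over the bins defined in both signals (joined on
#' chromosome and bin start; bins missing in either signal are excluded
#' pairwise).
#'
#' @param signal_a,signal_b `genome_signal` tibbles on a common grid.
#' @param min_bins Minimum shared defined bins required.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
rfd_correlation <- function(signal_a, signal_b, min_bins = 10L) {
  j <- dplyr::inner_join(
    signal_a[, c("chrom", "start", "value")],
    signal_b[, c("chrom", "start", "value")],
    by = c("chrom", "start"), suffix = c("_a", "_b"))
  j <- j[stats::complete.cases(j$value_a, j$value_b), , drop = FALSE]
  if (nrow(j) < min_bins) {
    stop("only ", nrow(j), " shared defined bins (need ", min_bins, ")")
  }
  stats::cor(j$value_a, j$value_b, method = "spearman")
}

#' Average a genome signal around a set of points
#'
#' Position-wise mean of the signal over windows of `flank` nucleotides
#' on each side of every point, missing bins excluded per position.
#'
#' @param points Tibble with `chrom` and a point coordinate column
#'   (`midpoint`, `median_point` or `position`).
#' @param signal A `genome_signal`.
#' @param flank Half-window (nt).
#' @return Tibble with `offset` (nt, bin centers relative to the point),
#'   `mean_value` and `n` (points contributing).
#' @export
mean_profile_around <- function(points, signal, flank = 10000) {
  bin <- attr(signal, "bin")
  pcol <- intersect(c("midpoint", "median_point", "position"), names(points))[1]
  if (is.na(pcol)) stop("points need a midpoint/median_point/position column")
  k <- round(flank / bin)
  sig_split <- split(signal, signal$chrom)
  mats <- purrr::map(seq_len(nrow(points)), function(i) {
    s <- sig_split[[points$chrom[i]]]
    if (is.null(s)) return(NULL)
    ci <- floor(points[[pcol]][i] / bin) + 1L
    idx <- (ci - k):(ci + k)
    v <- rep(NA_real_, length(idx))
    ok <- idx >= 1L & idx <= nrow(s)
    v[ok] <- s$value[idx[ok]]
    v
  })
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (!length(mats)) stop("no point has a defined flanking window")
  M <- do.call(rbind, mats)
  tibble::tibble(
    offset = ((-k):k) * bin,
    mean_value = colMeans(M, na.rm = TRUE),
    n = colSums(!is.na(M))
  )
}
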