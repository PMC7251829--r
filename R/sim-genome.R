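# Whole-genome pulse-chase simulation driven by an origin model.

# With equal fork speeds the nearest-arrival formula
# t(x) = min_j(T_j + |x - o_j| / v) handles passive replication of
# late-firing origins automatically.

# replication time and fork direction over positions x (0-based) given
# fired origins (positions o, times t) and fork speed v
replication_time <- function(x, o, t, v) {
  if (!length(o)) {
    return(list(time = rep(Inf, length(x)), dir = rep(NA_integer_, length(x))))
  }
  tt <- t[1] + abs(x - o[1]) / v
  best <- rep(1L, length(x))
  if (length(o) > 1L) {
    for (j in 2L:length(o)) {
      tj <- t[j] + abs(x - o[j]) / v
      upd <- tj < tt
      tt[upd] <- tj[upd]
      best[upd] <- j
    }
  }
  dir <- ifelse(x > o[best], 1L, ifelse(x < o[best], -1L, 0L))
  list(time = tt, dir = dir)
}

# chromosome-level ground truth for one cell: per-origin track extents and
# initiation/termination positions
cell_truth <- function(o, t, v, ps, ce, chrom_len) {
  n <- length(o)
  if (!n) {
    return(list(tracks = NULL, events = NULL))
  }
  ord <- order(o)
  o <- o[ord]; t <- t[ord]
  # actively fired = not passively replicated before its own firing time
  active <- vapply(seq_len(n), function(j) {
    if (n == 1L) TRUE else t[j] <= min(t[-j] + abs(o[j] - o[-j]) / v)
  }, logical(1))
  o <- o[active]; t <- t[active]; n <- length(o)
  # meet time/position between consecutive active origins
  meet_t <- if (n > 1L) (t[-n] + t[-1L] + (o[-1L] - o[-n]) / v) / 2 else numeric(0)
  meet_x <- if (n > 1L) (o[-n] + o[-1L]) / 2 + v * (t[-1L] - t[-n]) / 2 else numeric(0)
  tracks <- list(); events <- list()
  for (j in seq_len(n)) {
    # rightward fork: ends at the meet with the next origin or chromosome end
    t_end_r <- if (j < n) meet_t[j] else t[j] + (chrom_len - o[j]) / v
    t_end_l <- if (j > 1L) meet_t[j - 1L] else t[j] + o[j] / v
    t_end_r <- min(t_end_r, ce)
    t_end_l <- min(t_end_l, ce)
    if (t_end_r > ps) {
      tracks[[length(tracks) + 1L]] <- tibble::tibble(
        origin = j, orientation = "right",
        start = o[j] + v * (ps - t[j]), end = o[j] + v * (t_end_r - t[j]))
    }
    if (t_end_l > ps) {
      tracks[[length(tracks) + 1L]] <- tibble::tibble(
        origin = j, orientation = "left",
        start = o[j] - v * (t_end_l - t[j]), end = o[j] - v * (ps - t[j]))
    }
    if (t_end_r > ps && t_end_l > ps) {
      events[[length(events) + 1L]] <- tibble::tibble(
        type = "initiation", midpoint = o[j],
        fork_start_left = o[j] - v * (ps - t[j]),
        fork_start_right = o[j] + v * (ps - t[j]))
    }
  }
  if (n > 1L) {
    vis <- meet_t > ps & meet_t <= ce
    if (any(vis)) {
      events[[length(events) + 1L]] <- tibble::tibble(
        type = "termination", midpoint = meet_x[vis],
        fork_start_left = o[seq_len(n - 1L)][vis] +
          v * (ps - t[seq_len(n - 1L)][vis]),
        fork_start_right = o[-1L][vis] - v * (ps - t[-1L][vis]))
    }
  }
  list(tracks = if (length(tracks)) dplyr::bind_rows(tracks) else NULL,
       events = if (length(events)) dplyr::bind_rows(events) else NULL)
}

#' Simulate a whole-genome pulse-chase sequencing run
#'
#' Each read comes from an independent simulated cell: origins fire with
#' their efficiencies at uniform times before the pulse, forks progress
#' bidirectionally at `fork_speed` (later-firing origins can be passively
#' replicated), and the BrdU incorporation probability at every position
#' follows the pulse-chase time course evaluated at that position's
#' replication time.  Reads are sampled uniformly over the genome with
#' lengths from `config$read_length_range` and emitted through
#' [simulate_read()]'s signal model with a small random per-read drift.
#' Ground-truth track extents and initiation/termination midpoints
#' overlapping each read travel alongside the reads.
#'
#' @param reference Named character vector (or `DNAStringSet`) of
#'   chromosome sequences.
#' @param om An [origin_model()]; at least one origin per chromosome.
#' @param n_reads Number of reads.
#' @param config A [sim_config()].
#' @param matrices Transition matrices; defaults to
#'   [make_transition_matrices()] under `config`.
#' @param drift_jitter Length-2 numeric: per-read drift is drawn as
#'   `alpha ~ U(1 - j1, 1 + j1)`, `beta ~ U(-j2, j2)`.
#' @param keep_truth_prob Keep the per-base probability and incorporation
#'   list-columns on the reads (memory-hungry on large runs).
#' @param seed Optional seed.
#' @return List with `reads`, `truth_tracks`, `truth_events` (both
#'   read-level, coordinates genomic), `genome` (chrom/length tibble) and
#'   `matrices`.
#' @export
simulate_genome_run <- function(reference, om, n_reads,
                                config = sim_config(), matrices = NULL,
                                drift_jitter = c(0.1, 0.05),
                                keep_truth_prob = FALSE, seed = NULL) {
  stopifnot(inherits(om, "origin_model"))
  seqs <- as_sequences(reference)
  lens <- nchar(seqs)
  missing_org <- setdiff(names(seqs), unique(om$origins$chrom))
  if (length(missing_org)) {
    stop("no origin on chromosome(s): ", paste(missing_org, collapse = ", "))
  }
  if (is.null(matrices)) matrices <- make_transition_matrices(config)
  v <- om$fork_speed; ps <- om$pulse_start; ce <- om$chase_end
  with_seed(if (is.null(seed)) config$seed else seed, {
    reads <- vector("list", n_reads)
    ttracks <- vector("list", n_reads)
    tevents <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      ch <- sample(names(seqs), 1L, prob = lens)
      len <- lens[[ch]]
      L <- round(stats::runif(1, config$read_length_range[1],
                              config$read_length_range[2]))
      L <- min(L, len)
      start <- floor(stats::runif(1, 0, len - L + 1))
      org <- om$origins[om$origins$chrom == ch, , drop = FALSE]
      fired <- stats::runif(nrow(org)) < org$efficiency
      o <- org$position[fired]
      t <- stats::runif(sum(fired), 0, ps)
      x <- start + seq_len(L) - 1
      rt <- replication_time(x, o, t, v)
      peak <- stats::runif(1, config$pulse_peak_range[1],
                           config$pulse_peak_range[2])
      prob <- track_shape((rt$time - ps) * v, peak, config)
      prob[!is.finite(rt$time) | rt$time > ce] <- 0
      alpha <- stats::runif(1, 1 - drift_jitter[1], 1 + drift_jitter[1])
      beta <- stats::runif(1, -drift_jitter[2], drift_jitter[2])
      codes <- base_codes(substr(seqs[[ch]], start + 1L, start + L))
      sig <- simulate_signal(codes, prob, matrices, c(alpha, beta), config)
      row <- tibble::tibble(
        read_id = paste0("gread", i), chrom = ch, ref_start = start,
        strand = "+",
        bases = substr(seqs[[ch]], start + 1L, start + L),
        currents = list(sig$currents),
        alpha = alpha, beta = beta)
      if (keep_truth_prob) {
        row$truth_prob <- list(sig$prob)
        row$truth_incorp <- list(as.integer(sig$incorp))
      }
      reads[[i]] <- row
      tru <- cell_truth(o, t, v, ps, ce, len)
      if (!is.null(tru$tracks)) {
        tk <- tru$tracks
        ov <- pmin(tk$end, start + L) - pmax(tk$start, start)
        tk <- tk[ov >= 200, , drop = FALSE]
        if (nrow(tk)) {
          tk$read_id <- paste0("gread", i)
          tk$chrom <- ch
          ttracks[[i]] <- tk
        }
      }
      if (!is.null(tru$events)) {
        ev <- tru$events
        ev <- ev[ev$midpoint >= start & ev$midpoint < start + L, , drop = FALSE]
        if (nrow(ev)) {
          ev$spans_forks <- ev$fork_start_left >= start &
            ev$fork_start_right < start + L
          ev$read_id <- paste0("gread", i)
          ev$chrom <- ch
          tevents[[i]] <- ev
        }
      }
    }
    list(reads = dplyr::bind_rows(reads),
         truth_tracks = dplyr::bind_rows(ttracks),
         truth_events = dplyr::bind_rows(tevents),
         genome = tibble::tibble(chrom = names(seqs), length = unname(lens)),
         matrices = matrices)
  })
}
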