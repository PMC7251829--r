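# Read-level simulator: pulse-chase incorporation profiles, resquiggled
# reads, chimeric reads, labeled cohorts.

# Unimodal pulse-chase shape as a function of distance d (nt) since the
# fork position at pulse start: logistic rise from ~0 to `peak` over
# rise_length, then exponential decay to the chase floor over decay_length.
# The two branches are combined with pmin, which keeps the curve smooth and
# unimodal.
track_shape <- function(d, peak, config) {
  rl <- config$rise_length
  fl <- config$chase_floor
  rise <- peak * stats::plogis((d - rl / 2) / (rl / 8))
  decay <- fl + (peak - fl) * exp(-3 * pmax(d - rl, 0) / config$decay_length)
  out <- pmin(rise, decay)
  out[d < 0] <- 0
  out
}

#' Per-base BrdU incorporation probability along one replication track
#'
#' Models the incorporation profile a single fork writes during a BrdU
#' pulse-chase: probability rises steeply from ~0 to the peak over
#' `config$rise_length` in the direction of fork movement, then decays
#' shallowly to `config$chase_floor` over `config$decay_length`.  The
#' steep/shallow asymmetry is what later orients tracks.
#'
#' @param track_start Coordinate of the fork at the start of the pulse
#'   (where the rise begins).
#' @param orientation `"right"` or `"left"`; a leftward track is the
#'   mirror image of the rightward one about `track_start`.
#' @param config A [sim_config()].
#' @param peak Peak incorporation probability; defaults to the midpoint of
#'   `config$pulse_peak_range`.
#' @return Tibble with columns `position` (ascending) and `prob`.
#' @export
#' @examples
#' pr <- pulse_chase_profile(1000, "right", sim_config())
#' range(pr$prob)
pulse_chase_profile <- function(track_start, orientation = c("right", "left"),
                                config = sim_config(), peak = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(peak)) peak <- mean(config$pulse_peak_range)
  extent <- ceiling(config$rise_length + config$decay_length)
  d <- seq_len(extent) - 1
  prob <- track_shape(d, peak, config)
  if (orientation == "right") {
    tibble::tibble(position = track_start + d, prob = prob)
  } else {
    tibble::tibble(position = track_start - rev(d), prob = rev(prob))
  }
}

# Core signal generator shared by all read simulators.  Takes the coded
# sequence and per-base incorporation probability, draws per-T-site
# incorporation, emits shifts from the transition matrices plus Gaussian
# noise, and applies the inverse drift transform.
simulate_signal <- function(codes, prob, matrices, drift, config) {
  n <- length(codes)
  stopifnot(n >= 6L)
  prob <- rep_len(prob, n)
  incorp <- integer(n)
  tpos <- which(codes == 3L & prob > 0)
  if (length(tpos)) {
    incorp[tpos] <- stats::rbinom(length(tpos), 1L, prob[tpos])
  }
  hx <- hexamer_index(codes)
  inc <- incorp == 1L
  m <- n - 5L
  # transition i (bases i..i+5) reads the BrdU context when the T at the
  # center of either pentamer (positions i+2, i+3) is substituted
  use_b <- inc[3:(n - 3L)] | inc[4:(n - 2L)]
  delta_true <- ifelse(use_b, tm_delta(matrices$tm_b)[hx],
                       tm_delta(matrices$tm_t)[hx])
  delta <- c(delta_true, numeric(4L)) + stats::rnorm(n - 1L, 0, config$noise_sd)
  alpha <- drift[1]; beta <- drift[2]
  if (alpha <= 0) stop("drift scale alpha must be positive")
  delta_obs <- (delta - beta) / alpha
  currents <- rev(cumsum(rev(c(delta_obs, 0))))
  list(currents = currents, shifts = delta_obs, incorp = incorp, prob = prob)
}

new_read_row <- function(read_id, chrom, ref_start, bases, sig, drift) {
  tibble::tibble(
    read_id = read_id, chrom = chrom, ref_start = as.numeric(ref_start),
    strand = "+", bases = bases,
    currents = list(sig$currents), shifts = list(sig$shifts),
    truth_prob = list(sig$prob), truth_incorp = list(as.integer(sig$incorp)),
    alpha = drift[1], beta = drift[2]
  )
}

#' Simulate one resquiggled read
#'
#' Emits per-transition current shifts from the thymidine or BrdU
#' transition matrix (BrdU context where a centrally positioned T was
#' stochastically substituted according to `brdu_probability`), adds
#' Gaussian noise, and transforms the result by the inverse of the drift
#' correction so that [fit_drift()] recovers `drift`.  Per-base ground
#' truth (requested probability and realized incorporation) travels with
#' the read.
#'
#' @param reference_window Reference sequence of the read (string), length
#'   at least 6.
#' @param brdu_probability Per-base incorporation probability (scalar or
#'   vector of the sequence length).
#' @param matrices List with `tm_t` and `tm_b` as from
#'   [make_transition_matrices()].
#' @param drift Length-2 numeric `c(alpha, beta)`: emitted shifts are
#'   `(true + noise - beta) / alpha`.
#' @param config A [sim_config()] (supplies `noise_sd`).
#' @param read_id,chrom,ref_start Read metadata.
#' @param seed Optional seed.
#' @return One-row reads tibble with list-columns `currents`, `shifts`,
#'   `truth_prob`, `truth_incorp`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 3, noise_sd = 0)
#' tms <- make_transition_matrices(cfg)
#' rd <- simulate_read(strrep("ACGTT", 20), 0, tms, config = cfg, seed = 3)
#' length(rd$shifts[[1]])
simulate_read <- function(reference_window, brdu_probability, matrices,
                          drift = c(1, 0), config = sim_config(),
                          read_id = "read1", chrom = "chrS", ref_start = 0,
                          seed = NULL) {
  if (nchar(reference_window) < 6L) {
    stop("reference window must be at least 6 bases long")
  }
  codes <- base_codes(reference_window)
  if (anyNA(codes)) stop("reference window contains non-ACGT bases")
  with_seed(seed, {
    sig <- simulate_signal(codes, brdu_probability, matrices, drift, config)
    new_read_row(read_id, chrom, ref_start, reference_window, sig, drift)
  })
}

#' Simulate a read carrying one pulse-chase replication track
#'
#' Convenience wrapper placing a [pulse_chase_profile()] inside an
#' otherwise BrdU-free read.
#'
#' @param read_length Read length (nt).
#' @param track_start Fork position at pulse start, local 0-based offset
#'   within the read.
#' @param chase_to_end Keep the incorporation at the chase floor beyond
#'   the decay, to the end of the read, emulating the ongoing chase.
#' @inheritParams pulse_chase_profile
#' @inheritParams simulate_read
#' @return One-row reads tibble.
#' @export
simulate_track_read <- function(read_length, track_start,
                                orientation = c("right", "left"),
                                matrices, config = sim_config(),
                                peak = NULL, drift = c(1, 0),
                                chase_to_end = TRUE,
                                read_id = "read1", chrom = "chrS",
                                ref_start = 0, seed = NULL) {
  orientation <- match.arg(orientation)
  with_seed(seed, {
    seq <- random_genome(c(tmp = read_length), seed = NULL)[[1]]
    prof <- pulse_chase_profile(track_start, orientation, config, peak)
    prob <- numeric(read_length)
    keep <- prof$position >= 0 & prof$position < read_length
    prob[prof$position[keep] + 1L] <- prof$prob[keep]
    if (chase_to_end) {
      if (orientation == "right" && max(prof$position) < read_length - 1L) {
        prob[(max(prof$position) + 2L):read_length] <- config$chase_floor
      } else if (orientation == "left" && min(prof$position) > 0L) {
        prob[seq_len(min(prof$position))] <- config$chase_floor
      }
    }
    simulate_read(seq, prob, matrices, drift, config,
                  read_id = read_id, chrom = chrom, ref_start = ref_start)
  })
}

#' Simulate an in-silico chimeric read with a known BrdU transition
#'
#' The incorporation probability sits at the chase floor left of
#' `transition_point` and at the pulse peak right of it, the step being
#' blurred symmetrically over `config$rise_length` (logistic centered on
#' the transition).  The true coordinate is returned for precision
#' scoring of track-start detection.
#'
#' @param reference Read sequence (string); if `NULL` a random sequence of
#'   `read_length` nt is drawn.
#' @param transition_point Local 0-based coordinate of the low-to-high
#'   transition; must be interior to the read.
#' @param read_length Used when `reference` is `NULL`.
#' @inheritParams simulate_read
#' @return One-row reads tibble with an extra `transition_point` column.
#' @export
simulate_chimeric_read <- function(reference = NULL, transition_point,
                                   matrices, config = sim_config(),
                                   read_length = 20000, drift = c(1, 0),
                                   read_id = "chimera1", chrom = "chrS",
                                   ref_start = 0, seed = NULL) {
  with_seed(seed, {
    if (is.null(reference)) {
      reference <- random_genome(c(tmp = read_length), seed = NULL)[[1]]
    }
    n <- nchar(reference)
    if (transition_point <= 0 || transition_point >= n - 1) {
      stop("transition point must be interior to the read")
    }
    peak <- stats::runif(1, config$pulse_peak_range[1], config$pulse_peak_range[2])
    x <- seq_len(n) - 1
    prob <- config$chase_floor + (peak - config$chase_floor) *
      stats::plogis((x - transition_point) / (config$rise_length / 8))
    rd <- simulate_read(reference, prob, matrices, drift, config,
                        read_id = read_id, chrom = chrom, ref_start = ref_start)
    rd$transition_point <- transition_point
    rd
  })
}

#' Simulate a labeled cohort of reads at uniform BrdU content
#'
#' Every T site incorporates BrdU independently with probability
#' `content`, as in genomic DNA grown at a fixed BrdU/thymidine ratio.
#' Used to build training/validation cohorts for the content estimators.
#'
#' @param n_reads Number of reads.
#' @param content Per-T-site substitution probability in `[0, 1]`.
#' @param read_length Read length (scalar); if `NULL`, lengths are drawn
#'   from `config$read_length_range`.
#' @inheritParams simulate_read
#' @param id_prefix Prefix for read ids.
#' @return Reads tibble with one row per read plus a `content` column.
#' @export
simulate_cohort <- function(n_reads, content, matrices,
                            config = sim_config(), read_length = NULL,
                            drift = c(1, 0), id_prefix = "read",
                            chrom = "chrS", seed = NULL) {
  stopifnot(content >= 0, content <= 1)
  with_seed(seed, {
    lens <- if (is.null(read_length)) {
      round(stats::runif(n_reads, config$read_length_range[1],
                         config$read_length_range[2]))
    } else rep_len(read_length, n_reads)
    out <- purrr::map(seq_len(n_reads), function(i) {
      seq <- random_genome(c(tmp = lens[i]), seed = NULL)[[1]]
      simulate_read(seq, content, matrices, drift, config,
                    read_id = paste0(id_prefix, i), chrom = chrom,
                    ref_start = 0)
    })
    out <- dplyr::bind_rows(out)
    out$content <- content
    out
  })
}

#' Draw a random reference genome
#'
#' @param sizes Named integer vector of chromosome lengths.
#' @param seed Optional seed.
#' @param gc GC content (yeast-like default).
#' @return Named character vector of sequences.
#' @export
random_genome <- function(sizes, seed = NULL, gc = 0.38) {
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    out <- vapply(sizes, function(n) {
      paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    stats::setNames(out, names(sizes))
  })
}
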