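#' Simulation configuration for pulse-chase nanopore signals
#'
#' Bundles every knob of the signal-level simulator.  Defaults emulate the
#' conditions of a 2-min BrdU pulse followed by a thymidine chase in budding
#' yeast sequenced on a MinION: about 12.5% of the 4096 pentamer-to-pentamer
#' transitions are informative for BrdU, reads span 10-140 kb, incorporation
#' jumps steeply to 60-80% during the pulse and decays shallowly to ~10%
#' during the chase.
#'
#' @param seed Integer seed recorded in the config; individual simulator
#'   calls may override it.
#' @param informative_fraction Fraction of all 4096 hexamers whose expected
#'   thymidine/BrdU current shifts differ by more than the calling
#'   threshold.  Informative hexamers are drawn among the 1024 hexamers
#'   with a T at position 3.  Must lie in `[0, 0.25]`.
#' @param shift_gap Mean absolute difference (normalized current units)
#'   between the thymidine and BrdU expected shifts at informative
#'   hexamers.  Must exceed the 0.4 calling threshold.
#' @param noise_sd Per-transition Gaussian noise standard deviation
#'   (normalized current units).
#' @param read_length_range Length-2 numeric, read lengths in nucleotides
#'   drawn uniformly from this range.
#' @param pulse_peak_range Length-2 numeric, per-molecule peak BrdU
#'   incorporation probability drawn uniformly from this range.
#' @param chase_floor BrdU incorporation probability the chase decays to.
#' @param rise_length Distance (nt) over which incorporation rises from
#'   ~0 to the peak at a track start.
#' @param decay_length Distance (nt) over which incorporation decays from
#'   the peak back down to near the chase floor.  Must exceed
#'   `rise_length`: the rise/decay asymmetry is the orientation signal.
#' @param calling_threshold Minimum expected-shift gap for a hexamer to be
#'   callable (B/T rather than X).
#'
#' @return A list of class `sim_config`.
#' @seealso [make_transition_matrices()], [simulate_read()],
#'   [simulate_genome_run()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$informative_fraction
sim_config <- function(seed = 1L,
                       informative_fraction = 0.125,
                       shift_gap = 1.0,
                       noise_sd = 0.15,
                       read_length_range = c(10000, 140000),
                       pulse_peak_range = c(0.6, 0.8),
                       chase_floor = 0.10,
                       rise_length = 300,
                       decay_length = 5000,
                       calling_threshold = 0.4) {
  stopifnot(
    informative_fraction >= 0, informative_fraction <= 0.25,
    length(read_length_range) == 2L, read_length_range[1] <= read_length_range[2],
    length(pulse_peak_range) == 2L,
    pulse_peak_range[1] > chase_floor, pulse_peak_range[2] <= 1,
    chase_floor >= 0,
    rise_length > 0, decay_length > rise_length,
    noise_sd >= 0, calling_threshold > 0
  )
  if (informative_fraction > 0 && shift_gap <= calling_threshold) {
    stop("shift_gap must exceed the calling threshold (", calling_threshold, ")")
  }
  structure(
    list(
      seed = as.integer(seed),
      informative_fraction = informative_fraction,
      shift_gap = shift_gap,
      noise_sd = noise_sd,
      read_length_range = read_length_range,
      pulse_peak_range = pulse_peak_range,
      chase_floor = chase_floor,
      rise_length = rise_length,
      decay_length = decay_length,
      calling_threshold = calling_threshold
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " - ")))
  }
  invisible(x)
}

#' Origin firing model for whole-genome simulations
#'
#' Describes where replication can initiate on each chromosome, how
#' efficiently, and the pulse-chase timeline used to convert fork passage
#' times into BrdU incorporation probabilities.  In each simulated cell,
#' origin `i` fires with probability `efficiencies[i]` at a time drawn
#' uniformly in `(0, pulse_start)`, so that by the time BrdU appears both
#' forks have moved away from the origin and leave the characteristic
#' divergent track pair whose midpoint marks the origin.
#'
#' @param chrom Character vector, chromosome of each origin.
#' @param positions 0-based origin coordinates; strictly increasing within
#'   each chromosome.
#' @param efficiencies Per-origin firing probability per cell cycle, in
#'   `[0, 1]`.
#' @param fork_speed Replication fork speed, nucleotides per minute.
#' @param pulse_start,chase_end Minutes after the start of the cycle at
#'   which the BrdU pulse begins and at which labeling (and the simulated
#'   experiment) ends.
#'
#' @return A list of class `origin_model` with an `origins` tibble.
#' @export
#' @examples
#' om <- origin_model(chrom = "chrS", positions = c(5e4, 2e5),
#'                    efficiencies = c(1, 0.6))
origin_model <- function(chrom, positions, efficiencies,
                         fork_speed = 1500,
                         pulse_start = 10,
                         chase_end = 40) {
  chrom <- rep_len(as.character(chrom), length(positions))
  stopifnot(
    length(positions) == length(efficiencies),
    all(efficiencies >= 0), all(efficiencies <= 1),
    fork_speed > 0, pulse_start > 0, chase_end > pulse_start
  )
  org <- tibble::tibble(chrom = as.character(chrom),
                        position = as.numeric(positions),
                        efficiency = as.numeric(efficiencies))
  for (ch in unique(org$chrom)) {
    p <- org$position[org$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("origin positions must be strictly increasing within chromosome ", ch)
    }
  }
  structure(
    list(origins = org, fork_speed = fork_speed,
         pulse_start = pulse_start, chase_end = chase_end),
    class = "origin_model"
  )
}

#' @export
print.origin_model <- function(x, ...) {
  cat("<origin_model> ", nrow(x$origins), " origins, fork speed ",
      x$fork_speed, " nt/min, pulse at ", x$pulse_start,
      " min, end at ", x$chase_end, " min\n", sep = "")
  print(x$origins, n = 5)
  invisible(x)
}
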