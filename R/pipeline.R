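# End-to-end per-read pipelines.  Reads are processed one at a time so
# whole-genome runs never materialize all profiles at once.

# TM path for one read (already-normalized shifts): calls, smoothed
# fraction profile, QC, tracks, events.
tm_read_pass <- function(read_id, chrom, ref_start, codes, shifts,
                         dt, db, params, window, gap_threshold = 0.4) {
  cc <- tm_call_core(codes, shifts, dt, db, gap_threshold)
  fc <- fraction_core(cc$pos, cc$call, window)
  len <- length(codes)
  qc <- tibble::tibble(read_id = read_id, length = len,
                       n_profile = length(fc$value),
                       sd = NA_real_, amplitude = NA_real_,
                       status = "pass", n_tracks = 0L)
  if (!length(fc$value)) {
    qc$status <- "no profile (too few callable sites)"
    return(list(qc = qc, tracks = NULL, events = NULL, profile = NULL))
  }
  # The TM sd filter acts on the per-site B/T indicator (binary scale, as
  # the 0.3 threshold implies); the amplitude filter on the smoothed
  # profile.
  bt <- cc$call[cc$call != "X"] == "B"
  qc$sd <- stats::sd(as.numeric(bt))
  qc$amplitude <- diff(range(fc$value))
  if (len < params$min_read_length) {
    qc$status <- "read shorter than minimum"
  } else if (is.na(qc$sd) || qc$sd < params$min_profile_sd) {
    qc$status <- "profile sd below minimum"
  } else if (qc$amplitude < params$min_amplitude) {
    qc$status <- "profile amplitude below minimum"
  }
  profile <- tibble::tibble(read_id = read_id, chrom = chrom,
                            position = ref_start + fc$pos, value = fc$value)
  if (qc$status != "pass") {
    return(list(qc = qc, tracks = NULL, events = NULL, profile = profile))
  }
  v01 <- rescale01(profile$value)
  bp <- segment_profile(tibble::tibble(position = profile$position,
                                       value = v01), params$rdp_epsilon)
  tr <- detect_tracks(bp, params)
  if (nrow(tr)) {
    tr <- orient_track(tr, params)
    tr <- score_track(tr, off_track_sd(profile$position, profile$value, tr),
                      diff(range(profile$value)))
    tr$read_id <- read_id
    tr$chrom <- chrom
    tr$method <- params$method
  } else {
    tr <- NULL
  }
  qc$n_tracks <- if (is.null(tr)) 0L else nrow(tr)
  ev <- if (!is.null(tr) && nrow(tr) >= 2L) {
    call_events(tr, profile, params)
  } else NULL
  list(qc = qc, tracks = tr, events = ev, profile = profile)
}

#' Run the full transition-matrix pipeline over a read set
#'
#' Per read: drift normalization against the thymidine reference (reads
#' with residual above `residual_cutoff` are discarded), B/T/X calling,
#' 30-site smoothing, read filtering, piecewise-linear segmentation,
#' track detection/orientation/scoring and per-molecule event calling.
#' Reads are streamed one at a time, so memory stays flat on large runs.
#'
#' @param reads Reads tibble (raw; normalization happens inside unless
#'   `normalize = FALSE`).
#' @param matrices List with `tm_t`, `tm_b`.
#' @param params A [detection_params()] (TM defaults).
#' @param normalize Fit and apply per-read drift against `tm_t` first.
#' @param residual_cutoff Drift-fit rejection threshold.
#' @param window Smoothing window in called (B/T) sites.
#' @param keep_profiles Also return the per-read smoothed profiles
#'   (memory-hungry on large runs).
#' @return List with `tracks`, `events`, `qc` (one row per read) and
#'   `profiles` (`NULL` unless requested).
#' @export
run_tm_pipeline <- function(reads, matrices, params = detection_params("TM"),
                            normalize = TRUE, residual_cutoff = 0.25,
                            window = 30L, keep_profiles = FALSE) {
  dt <- tm_delta(matrices$tm_t)
  db <- tm_delta(matrices$tm_b)
  shifts_all <- read_shifts(reads)
  qc <- list(); tracks <- list(); events <- list(); profiles <- list()
  for (i in seq_len(nrow(reads))) {
    codes <- base_codes(reads$bases[[i]])
    shifts <- shifts_all[[i]]
    if (normalize) {
      fit <- tryCatch(fit_drift(reads[i, ], matrices$tm_t),
                      error = function(e) conditionMessage(e))
      if (is.character(fit)) {
        qc[[i]] <- tibble::tibble(read_id = reads$read_id[[i]],
                                  length = length(codes),
                                  n_profile = 0L, sd = NA_real_,
                                  amplitude = NA_real_, status = fit,
                                  n_tracks = 0L)
        next
      }
      if (fit$residual > residual_cutoff) {
        qc[[i]] <- tibble::tibble(read_id = reads$read_id[[i]],
                                  length = length(codes),
                                  n_profile = 0L, sd = NA_real_,
                                  amplitude = NA_real_,
                                  status = paste0("drift residual > ",
                                                  residual_cutoff),
                                  n_tracks = 0L)
        next
      }
      shifts <- fit$alpha * shifts + fit$beta
    }
    res <- tm_read_pass(reads$read_id[[i]], reads$chrom[[i]],
                        reads$ref_start[[i]], codes, shifts, dt, db,
                        params, window)
    qc[[i]] <- res$qc
    if (!is.null(res$tracks)) tracks[[length(tracks) + 1L]] <- res$tracks
    if (!is.null(res$events)) events[[length(events) + 1L]] <- res$events
    if (keep_profiles && !is.null(res$profile)) {
      profiles[[length(profiles) + 1L]] <- res$profile
    }
  }
  tracks <- dplyr::bind_rows(tracks)
  if (nrow(tracks)) tracks <- dplyr::relocate(tracks, "read_id", "chrom")
  list(tracks = tracks,
       events = dplyr::bind_rows(events),
       qc = dplyr::bind_rows(qc),
       profiles = if (keep_profiles) dplyr::bind_rows(profiles) else NULL)
}

#' Orientation accuracy of detected tracks against simulation truth
#'
#' Each oriented detected track is matched to the ground-truth track of
#' the same read with which it overlaps most; tracks with no overlapping
#' truth are ignored.
#'
#' @param tracks Detected track tibble (oriented).
#' @param truth_tracks Ground-truth track tibble from
#'   [simulate_genome_run()].
#' @return List with `n_oriented`, `n_matched`, `n_correct`, `accuracy`.
#' @export
orientation_accuracy <- function(tracks, truth_tracks) {
  tr <- tracks[!is.na(tracks$orientation), , drop = FALSE]
  n_matched <- 0L; n_correct <- 0L
  for (i in seq_len(nrow(tr))) {
    tt <- truth_tracks[truth_tracks$read_id == tr$read_id[i], , drop = FALSE]
    if (!nrow(tt)) next
    ov <- pmin(tt$end, tr$end[i]) - pmax(tt$start, tr$start[i])
    if (max(ov) <= 0) next
    n_matched <- n_matched + 1L
    if (tt$orientation[which.max(ov)] == tr$orientation[i]) {
      n_correct <- n_correct + 1L
    }
  }
  list(n_oriented = nrow(tr), n_matched = n_matched, n_correct = n_correct,
       accuracy = if (n_matched) n_correct / n_matched else NA_real_)
}

#' Track-start precision on simulated chimeric reads
#'
#' Generates reads whose BrdU probability steps from the chase floor to
#' the pulse peak at a known interior coordinate, runs the
#' transition-matrix path (calling, smoothing, rescaling, segmentation)
#' and localizes the largest upward shift by its mid-rise crossing.  The
#' absolute distance between the detected track start and the true
#' transition measures the method's spatial precision.
#'
#' @param n_reads Number of chimeric reads.
#' @param matrices Transition matrices; defaults to
#'   [make_transition_matrices()] under `config`.
#' @param config A [sim_config()].
#' @param params A [detection_params()].  The default lowers the
#'   simplification tolerance to 0.2: a chimeric profile is a single step
#'   whose maximal chord deviation is half the step amplitude, so the
#'   tolerance must stay below that for the step corners to be retained
#'   at all (pulse-shaped tracks, with twice the amplitude, tolerate the
#'   larger default).
#' @param read_length Chimeric read length (nt).
#' @param window Smoothing window in called sites.
#' @param seed Seed for the ensemble.
#' @return Tibble with `read_id`, `truth`, `detected`, `distance`
#'   (`NA` rows when no qualifying upshift was found).
#' @export
chimeric_precision <- function(n_reads = 300L, matrices = NULL,
                               config = sim_config(),
                               params = detection_params("TM", rdp_epsilon = 0.2),
                               read_length = 20000L, window = 30L,
                               seed = 1L) {
  if (is.null(matrices)) matrices <- make_transition_matrices(config)
  dt <- tm_delta(matrices$tm_t)
  db <- tm_delta(matrices$tm_b)
  with_seed(seed, {
    out <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      tp <- round(stats::runif(1, 0.3, 0.7) * read_length)
      rd <- simulate_chimeric_read(transition_point = tp, matrices = matrices,
                                   config = config, read_length = read_length,
                                   read_id = paste0("chimera", i))
      codes <- base_codes(rd$bases[[1L]])
      cc <- tm_call_core(codes, rd$shifts[[1L]], dt, db,
                         config$calling_threshold)
      fc <- fraction_core(cc$pos, cc$call, window)
      detected <- NA_real_
      if (length(fc$value) >= 3L) {
        bp <- segment_profile(tibble::tibble(position = fc$pos,
                                             value = rescale01(fc$value)),
                              params$rdp_epsilon)
        ups <- detect_upshifts(bp, params)
        if (nrow(ups)) detected <- ups$mid_rise_pos[which.max(ups$rise)]
      }
      out[[i]] <- tibble::tibble(read_id = rd$read_id, truth = tp,
                                 detected = detected,
                                 distance = abs(detected - tp))
    }
    dplyr::bind_rows(out)
  })
}
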