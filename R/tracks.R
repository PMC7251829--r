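# Track detection, orientation, scoring and per-molecule event calling.

#' Detection parameters for BrdU track and event calling
#'
#' Method-specific defaults are bound to the calling method: the
#' convolutional estimator produces smoother profiles than the
#' transition-matrix caller, so its standard-deviation/amplitude filters
#' and plateau ceiling differ.
#'
#' @param method `"TM"` or `"CNN"`.
#' @param min_read_length Reads shorter than this (nt) are not used.
#' @param min_profile_sd Minimal standard deviation of the BrdU content
#'   profile over the whole read.
#' @param min_amplitude Minimal profile amplitude (max - min).
#' @param up_amplitude,down_amplitude Minimal total rise / fall (rescaled
#'   units) for a track's upward and downward shifts.
#' @param slope_ratio Steep/shallow slope-magnitude ratio above which the
#'   slope rule orients a track.
#' @param level_gap Minimal difference between the flanking minima for
#'   the level rule to orient a track.
#' @param ascore_min,jscore_min High-confidence score gates for event
#'   calling.
#' @param fork_gap_min Minimal gap (nt) between fork starts for an
#'   initiation call.
#' @param plateau_max Maximal rescaled profile level between diverging
#'   fork starts (initiation) and at the flanking minima of converging
#'   forks (termination).
#' @param baseline_max Maximal rescaled level of the pulse-side flank for
#'   a track to be orientable: a genuine fork start rises out of
#'   DNA that was unreplicated during the pulse, whereas noise bumps
#'   riding on the chase decay are flanked by elevated signal on both
#'   sides.
#' @param share_distance Midpoint distance (nt) under which CNN and TM
#'   events are considered shared.
#' @param rdp_epsilon Tolerance of the piecewise-linear simplification,
#'   in rescaled signal units.
#' @param swing_tol Hysteresis tolerance of the run structure: a
#'   counter-movement smaller than this does not end a rising or falling
#'   run.  Defaults to `down_amplitude`, the smallest shift the track
#'   rules care about.
#' @param flat_eps Swing amplitude below which a swing counts as plateau
#'   rather than rise/fall.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(method = c("TM", "CNN"),
                             min_read_length = 5000,
                             min_profile_sd = NULL,
                             min_amplitude = NULL,
                             up_amplitude = 0.44,
                             down_amplitude = 0.26,
                             slope_ratio = 1.5,
                             level_gap = 0.075,
                             ascore_min = 2,
                             jscore_min = 1,
                             fork_gap_min = 1000,
                             plateau_max = NULL,
                             baseline_max = 0.15,
                             share_distance = 2000,
                             rdp_epsilon = NULL,
                             swing_tol = NULL,
                             flat_eps = 0.05) {
  method <- match.arg(method)
  if (is.null(min_profile_sd)) min_profile_sd <- if (method == "CNN") 0.115 else 0.3
  if (is.null(min_amplitude)) min_amplitude <- if (method == "CNN") 0.4 else 0.5
  if (is.null(plateau_max)) plateau_max <- if (method == "CNN") 0.14 else 0.12
  # The simplification tolerance must sit above the intrinsic sampling
  # noise of the content profile: a 30-site fraction at intermediate
  # content has binomial sd ~0.09 raw (~0.12 rescaled), and the
  # simplification retains its extreme excursions, so the TM tolerance is
  # set at ~4x that scale; windows of the convolutional estimator average
  # 96 transitions and are correspondingly smoother.
  if (is.null(rdp_epsilon)) rdp_epsilon <- if (method == "CNN") 0.25 else 0.50
  out <- list(method = method, min_read_length = min_read_length,
              min_profile_sd = min_profile_sd, min_amplitude = min_amplitude,
              up_amplitude = up_amplitude, down_amplitude = down_amplitude,
              slope_ratio = slope_ratio, level_gap = level_gap,
              ascore_min = ascore_min, jscore_min = jscore_min,
              fork_gap_min = fork_gap_min, plateau_max = plateau_max,
              baseline_max = baseline_max,
              share_distance = share_distance, rdp_epsilon = rdp_epsilon,
              swing_tol = if (is.null(swing_tol)) down_amplitude else swing_tol,
              flat_eps = flat_eps)
  stopifnot(all(vapply(out[-1], function(v) is.numeric(v) && v >= 0, logical(1))))
  structure(out, class = "detection_params")
}

#' Filter content profiles for track analysis
#'
#' Keeps a read's profile only if the read is at least
#' `min_read_length` long, the profile standard deviation reaches
#' `min_profile_sd`, and the amplitude (max - min) reaches
#' `min_amplitude` — reads with no replication track fail these and are
#' discarded up front.
#'
#' @param profiles Profile tibble (`read_id`, `chrom`, `position`,
#'   `value`).
#' @param params A [detection_params()].
#' @param lengths Optional tibble (`read_id`, `length`) with true read
#'   lengths; when absent the profile coordinate span is used.
#' @return Filtered profile tibble; per-read QC attached as attribute
#'   `"rejections"` (see [rejection_log()]).
#' @export
filter_reads <- function(profiles, params = detection_params(),
                         lengths = NULL) {
  qc <- profiles %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::summarise(span = max(.data$position) - min(.data$position),
                     sd = stats::sd(.data$value),
                     amplitude = max(.data$value) - min(.data$value),
                     n = dplyr::n(), .groups = "drop")
  if (!is.null(lengths)) {
    qc <- dplyr::left_join(qc, lengths, by = "read_id")
    qc$span <- ifelse(is.na(qc$length), qc$span, qc$length)
  }
  qc$keep <- qc$span >= params$min_read_length &
    !is.na(qc$sd) & qc$sd >= params$min_profile_sd &
    qc$amplitude >= params$min_amplitude
  qc$reason <- dplyr::case_when(
    qc$keep ~ NA_character_,
    qc$span < params$min_read_length ~ "read shorter than minimum",
    is.na(qc$sd) | qc$sd < params$min_profile_sd ~ "profile sd below minimum",
    TRUE ~ "profile amplitude below minimum"
  )
  out <- profiles[profiles$read_id %in% qc$read_id[qc$keep], , drop = FALSE]
  attr(out, "rejections") <- qc[!qc$keep, c("read_id", "span", "sd",
                                            "amplitude", "reason")]
  out
}

# min-max rescale to [0, 1]
rescale01 <- function(v) {
  r <- range(v)
  if (r[2] == r[1]) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

# Ramer-Douglas-Peucker simplification (vertical deviation), iterative.
# Returns the logical keep mask over points.
rdp_mask <- function(x, y, eps) {
  n <- length(x)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  if (n <= 2L) return(keep)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i0 <- seg[1]; i1 <- seg[2]
    if (i1 - i0 < 2L) next
    idx <- (i0 + 1L):(i1 - 1L)
    slope <- (y[i1] - y[i0]) / (x[i1] - x[i0])
    dev <- abs(y[idx] - (y[i0] + (x[idx] - x[i0]) * slope))
    m <- which.max(dev)
    if (dev[m] > eps) {
      mi <- idx[m]
      keep[mi] <- TRUE
      stack[[length(stack) + 1L]] <- c(i0, mi)
      stack[[length(stack) + 1L]] <- c(mi, i1)
    }
  }
  keep
}

#' Piecewise-linear segmentation of a rescaled profile
#'
#' Ramer-Douglas-Peucker simplification: breakpoints are a subset of the
#' input points, endpoints are always retained, and no point deviates
#' vertically from its approximating segment by more than `rdp_epsilon`.
#' (With positions in nucleotides and values in `[0, 1]`, segments are
#' nearly horizontal in raw units, so the vertical deviation is
#' numerically the perpendicular one; it is also invariant to the
#' coordinate scale.)
#'
#' @param profile Tibble with `position` and `value`; `value` is
#'   expected rescaled to `[0, 1]` per read.
#' @param rdp_epsilon Tolerance in rescaled units.
#' @return The breakpoint rows of `profile`, with their original index
#'   in column `index`.
#' @export
segment_profile <- function(profile, rdp_epsilon = 0.05) {
  n <- nrow(profile)
  if (n < 3L) {
    out <- profile
    out$index <- seq_len(n)
    return(out)
  }
  keep <- rdp_mask(profile$position, profile$value, rdp_epsilon)
  out <- profile[keep, , drop = FALSE]
  out$index <- which(keep)
  out
}

# Hysteresis (zigzag) pivot filter over the RDP polyline: reversals
# smaller than `tol` do not break a trend, so the polyline collapses to
# alternating significant extremes.  Returns pivot point indices,
# starting at 1 and ending at the final significant extreme.
zigzag_pivots <- function(val, tol) {
  n <- length(val)
  piv <- integer(0)
  hi <- 1L; lo <- 1L; trend <- 0L
  for (i in 2:n) {
    if (val[i] > val[hi]) hi <- i
    if (val[i] < val[lo]) lo <- i
    if (trend <= 0L && val[i] >= val[lo] + tol) {
      piv <- c(piv, lo)
      trend <- 1L
      hi <- i
    } else if (trend >= 0L && val[i] <= val[hi] - tol) {
      piv <- c(piv, hi)
      trend <- -1L
      lo <- i
    }
  }
  last <- if (trend == 1L) hi else if (trend == -1L) lo else n
  piv <- c(piv, last)
  if (piv[1] != 1L) piv <- c(1L, piv)
  unique(piv)
}

# swings between consecutive pivots: +1 up, -1 down, 0 negligible
pivot_swings <- function(pos, val, piv, flat_eps) {
  i0 <- piv[-length(piv)]
  i1 <- piv[-1L]
  change <- val[i1] - val[i0]
  tibble::tibble(
    class = ifelse(change > flat_eps, 1L, ifelse(change < -flat_eps, -1L, 0L)),
    i0 = i0, i1 = i1,
    pos0 = pos[i0], pos1 = pos[i1],
    val0 = val[i0], val1 = val[i1],
    change = change
  )
}

# first coordinate at which the polyline over points [i0..i1] crosses
# `level`; linear interpolation between breakpoints.  With rev = TRUE the
# scan runs right-to-left (last crossing).
cross_at <- function(pos, val, i0, i1, level, rev = FALSE) {
  idx <- if (rev) (i1 - 1L):i0 else i0:(i1 - 1L)
  for (i in idx) {
    v0 <- val[i]; v1 <- val[i + 1L]
    if ((v0 - level) * (v1 - level) <= 0 && v0 != v1) {
      return(pos[i] + (level - v0) / (v1 - v0) * (pos[i + 1L] - pos[i]))
    }
  }
  (pos[i0] + pos[i1]) / 2
}

# chord slope of the central part of a swing, measured between the 25%
# and 75% amplitude crossings (robust to shallow approach regions at the
# swing ends); rescaled units per kb
swing_slope <- function(pos, val, sw) {
  lo <- min(sw$val0, sw$val1); hi <- max(sw$val0, sw$val1)
  l25 <- lo + 0.25 * (hi - lo)
  l75 <- lo + 0.75 * (hi - lo)
  if (sw$class > 0L) {
    xhi <- cross_at(pos, val, sw$i0, sw$i1, l75)
    xlo <- cross_at(pos, val, sw$i0, sw$i1, l25, rev = TRUE)
  } else {
    xlo <- cross_at(pos, val, sw$i0, sw$i1, l25)
    xhi <- cross_at(pos, val, sw$i0, sw$i1, l75, rev = TRUE)
  }
  span <- abs(xlo - xhi)
  if (span <= 0) span <- abs(sw$pos1 - sw$pos0) / 2
  sign(sw$change) * 0.5 * (hi - lo) / span * 1000
}

#' Detect BrdU tracks on a segmented profile
#'
#' Scans the runs of the piecewise-linear approximation: a maximal rising
#' run with total rise above `up_amplitude`, followed (possibly after a
#' plateau run) by a maximal falling run with total fall above
#' `down_amplitude`, defines one track spanning rise start to fall end.
#' Chord slopes of the two runs, the flanking minima, and the mid-rise /
#' mid-fall crossing coordinates (used later as fork-start localizers,
#' being unbiased under the symmetric smoothing of the content profile)
#' are recorded.
#'
#' @param breakpoints Breakpoint tibble from [segment_profile()]
#'   (rescaled values).
#' @param params A [detection_params()].
#' @return Unoriented track tibble: `start`, `end`, `rise`, `fall`,
#'   `slope_up`, `slope_down` (rescaled units per kb), `min_p`, `min_f`,
#'   `peak`, `mid_rise_pos`, `mid_fall_pos`.
#' @export
detect_tracks <- function(breakpoints, params = detection_params()) {
  empty <- tibble::tibble(start = numeric(0), end = numeric(0),
                          rise = numeric(0), fall = numeric(0),
                          slope_up = numeric(0), slope_down = numeric(0),
                          min_p = numeric(0), min_f = numeric(0),
                          peak = numeric(0), mid_rise_pos = numeric(0),
                          mid_fall_pos = numeric(0))
  if (nrow(breakpoints) < 3L) return(empty)
  pos <- breakpoints$position
  val <- breakpoints$value
  tol <- if (is.null(params$swing_tol)) params$down_amplitude else params$swing_tol
  piv <- zigzag_pivots(val, tol)
  if (length(piv) < 3L) return(empty)
  runs <- pivot_swings(pos, val, piv, params$flat_eps)
  out <- list()
  r <- 1L
  while (r <= nrow(runs)) {
    if (runs$class[r] == 1L && runs$change[r] > params$up_amplitude) {
      r2 <- r + 1L
      while (r2 <= nrow(runs) && runs$class[r2] == 0L) r2 <- r2 + 1L
      if (r2 <= nrow(runs) && runs$class[r2] == -1L &&
          -runs$change[r2] > params$down_amplitude) {
        up <- runs[r, ]; down <- runs[r2, ]
        amp_u <- up$val1 - up$val0
        amp_d <- down$val0 - down$val1
        out[[length(out) + 1L]] <- tibble::tibble(
          start = cross_at(pos, val, up$i0, up$i1,
                           up$val0 + 0.1 * amp_u, rev = TRUE),
          end = cross_at(pos, val, down$i0, down$i1,
                         down$val1 + 0.1 * amp_d),
          rise = amp_u, fall = amp_d,
          slope_up = swing_slope(pos, val, up),
          slope_down = swing_slope(pos, val, down),
          min_p = up$val0, min_f = down$val1, peak = up$val1,
          mid_rise_pos = cross_at(pos, val, up$i0, up$i1,
                                  (up$val0 + up$val1) / 2),
          mid_fall_pos = cross_at(pos, val, down$i0, down$i1,
                                  (down$val0 + down$val1) / 2, rev = TRUE)
        )
        r <- r2
        next
      }
    }
    r <- r + 1L
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Detect upward shifts regardless of a following fall
#'
#' Used for track-start localization on profiles whose high-content side
#' runs to the read end (e.g. chimeric reads): every maximal rising run
#' with total rise above `up_amplitude` is reported with its mid-rise
#' crossing coordinate.
#'
#' @inheritParams detect_tracks
#' @return Tibble with `start`, `rise` and `mid_rise_pos` per upshift.
#' @export
detect_upshifts <- function(breakpoints, params = detection_params()) {
  if (nrow(breakpoints) < 2L) {
    return(tibble::tibble(start = numeric(0), rise = numeric(0),
                          mid_rise_pos = numeric(0)))
  }
  pos <- breakpoints$position
  val <- breakpoints$value
  tol <- if (is.null(params$swing_tol)) params$down_amplitude else params$swing_tol
  piv <- zigzag_pivots(val, tol)
  if (length(piv) < 2L) {
    return(tibble::tibble(start = numeric(0), rise = numeric(0),
                          mid_rise_pos = numeric(0)))
  }
  runs <- pivot_swings(pos, val, piv, params$flat_eps)
  up <- runs[runs$class == 1L & runs$change > params$up_amplitude, ]
  if (!nrow(up)) {
    return(tibble::tibble(start = numeric(0), rise = numeric(0),
                          mid_rise_pos = numeric(0)))
  }
  tibble::tibble(
    start = up$pos0, rise = up$change,
    mid_rise_pos = purrr::map_dbl(seq_len(nrow(up)), function(i) {
      cross_at(pos, val, up$i0[i], up$i1[i], (up$val0[i] + up$val1[i]) / 2)
    })
  )
}

#' Orient detected tracks
#'
#' The steep side of a track is the fork start: synthesis runs from the
#' steep pulse rise toward the shallow chase decay.  A track is oriented
#' rightward when the coordinate-order upward slope is more than
#' `slope_ratio` times steeper than the downward one, leftward in the
#' mirrored case; when slopes are too symmetric, the flanking minima
#' decide (the chase leaves the trailing flank above the pre-pulse
#' baseline by more than `level_gap`).  Otherwise the track stays
#' unoriented.
#'
#' @param tracks Track tibble from [detect_tracks()].
#' @param params A [detection_params()].
#' @return `tracks` with `orientation` (`"right"`, `"left"` or `NA`) and
#'   `fork_start` (mid-rise coordinate of the steep side; `NA` when
#'   unoriented).
#' @export
orient_track <- function(tracks, params = detection_params()) {
  if (!nrow(tracks)) {
    tracks$orientation <- character(0)
    tracks$fork_start <- numeric(0)
    return(tracks)
  }
  su <- abs(tracks$slope_up)
  sd_ <- abs(tracks$slope_down)
  ratio_r <- ifelse(sd_ == 0, Inf, su / sd_)
  ratio_l <- ifelse(su == 0, Inf, sd_ / su)
  level <- tracks$min_f - tracks$min_p
  orientation <- dplyr::case_when(
    ratio_r > params$slope_ratio & ratio_r >= ratio_l ~ "right",
    ratio_l > params$slope_ratio ~ "left",
    level > params$level_gap ~ "right",
    -level > params$level_gap ~ "left",
    TRUE ~ NA_character_
  )
  # a genuine fork start rises out of DNA unreplicated during the pulse:
  # void the orientation when the pulse-side flank is well above baseline
  pulse_flank <- ifelse(orientation == "right", tracks$min_p, tracks$min_f)
  orientation[!is.na(orientation) & pulse_flank > params$baseline_max] <- NA_character_
  tracks$orientation <- orientation
  tracks$fork_start <- dplyr::case_when(
    orientation == "right" ~ tracks$mid_rise_pos,
    orientation == "left" ~ tracks$mid_fall_pos,
    TRUE ~ NA_real_
  )
  tracks
}

#' Score oriented tracks
#'
#' `Ascore` is the signed fork-asymmetry: the steep/shallow
#' slope-magnitude ratio, positive for rightward tracks and negative for
#' leftward ones (so `|Ascore| > 2` is a stricter version of the 1.5
#' orientation ratio).  `Jscore` is the starting-jump amplitude in
#' pre-rescale signal units divided by the read's off-track residual
#' standard deviation — a signal-to-noise ratio, so `Jscore > 1` means
#' the jump exceeds the noise floor.  Unoriented tracks get `NA` scores.
#'
#' @param tracks Oriented track tibble from [orient_track()].
#' @param off_track_sd Residual standard deviation of the profile outside
#'   all detected tracks (pre-rescale units).
#' @param amplitude_scale Factor mapping rescaled amplitudes back to
#'   pre-rescale units (the read's profile max - min).
#' @return `tracks` with `ascore` and `jscore` columns.
#' @export
score_track <- function(tracks, off_track_sd = 1, amplitude_scale = 1) {
  if (!nrow(tracks)) {
    tracks$ascore <- numeric(0)
    tracks$jscore <- numeric(0)
    return(tracks)
  }
  su <- abs(tracks$slope_up)
  sd_ <- abs(tracks$slope_down)
  tracks$ascore <- dplyr::case_when(
    tracks$orientation == "right" ~ ifelse(sd_ == 0, Inf, su / sd_),
    tracks$orientation == "left" ~ -ifelse(su == 0, Inf, sd_ / su),
    TRUE ~ NA_real_
  )
  jump <- ifelse(tracks$orientation == "right", tracks$rise, tracks$fall)
  tracks$jscore <- ifelse(is.na(tracks$orientation), NA_real_,
                          jump * amplitude_scale / max(off_track_sd, 1e-9))
  tracks
}

# off-track residual sd of a raw (pre-rescale) profile
off_track_sd <- function(position, value, tracks) {
  off <- rep(TRUE, length(position))
  for (i in seq_len(nrow(tracks))) {
    off <- off & !(position >= tracks$start[i] & position <= tracks$end[i])
  }
  if (sum(off) >= 20L) return(stats::sd(value[off]))
  # fallback: high-frequency residual of the whole profile
  stats::sd(diff(value)) / sqrt(2)
}

#' Detect, orient and score the tracks of each read profile
#'
#' Per read: rescale the profile to `[0, 1]`, simplify it with
#' [segment_profile()], detect tracks, orient and score them.  Profiles
#' should already have passed [filter_reads()].
#'
#' @param profiles Profile tibble (`read_id`, `chrom`, `position`,
#'   `value`, pre-rescale units).
#' @param params A [detection_params()].
#' @return Track tibble with `read_id`, `chrom` and all
#'   [detect_tracks()] / [orient_track()] / [score_track()] columns,
#'   plus `method`.
#' @export
detect_read_tracks <- function(profiles, params = detection_params()) {
  out <- profiles %>%
    dplyr::group_by(.data$read_id, .data$chrom) %>%
    dplyr::group_map(function(g, key) {
      v01 <- rescale01(g$value)
      bp <- segment_profile(tibble::tibble(position = g$position, value = v01),
                            params$rdp_epsilon)
      tr <- detect_tracks(bp, params)
      if (!nrow(tr)) return(NULL)
      tr <- orient_track(tr, params)
      scale <- diff(range(g$value))
      tr <- score_track(tr, off_track_sd(g$position, g$value, tr), scale)
      tr$read_id <- key$read_id
      tr$chrom <- key$chrom
      tr$method <- params$method
      tr
    })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) return(out)
  dplyr::relocate(out, "read_id", "chrom")
}

#' Call initiation and termination events from a read's tracks
#'
#' Works on consecutive track pairs in coordinate order along each read
#' (any intervening detected track voids a pair, oriented or not).  An
#' initiation is a (leftward, rightward) diverging pair with both tracks
#' high-confidence (`|Ascore| > ascore_min`, `Jscore > jscore_min`), a
#' fork-start gap of at least `fork_gap_min`, and a mean rescaled profile
#' level between the fork starts of at most `plateau_max`; its midpoint
#' (between the fork starts) estimates the origin position.  A
#' termination is a (rightward, leftward) converging high-confidence pair
#' whose flanking minima (the profile level at the base of each fork
#' start) are at most `plateau_max`.
#'
#' @param tracks Oriented, scored track tibble ([detect_read_tracks()]).
#' @param profiles Profile tibble of the same reads (pre-rescale values;
#'   rescaled internally per read for the plateau check).
#' @param params A [detection_params()].
#' @return Event tibble: `read_id`, `chrom`, `type`
#'   (`"initiation"`/`"termination"`), `midpoint`, `fork_start_left`,
#'   `fork_start_right`, `method`.
#' @export
call_events <- function(tracks, profiles, params = detection_params()) {
  empty <- tibble::tibble(read_id = character(0), chrom = character(0),
                          type = character(0), midpoint = numeric(0),
                          fork_start_left = numeric(0),
                          fork_start_right = numeric(0),
                          method = character(0))
  if (!nrow(tracks)) return(empty)
  prof_split <- split(profiles[, c("position", "value")], profiles$read_id)
  out <- list()
  for (rid in unique(tracks$read_id)) {
    tr <- tracks[tracks$read_id == rid, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    if (nrow(tr) < 2L) next
    pr <- prof_split[[rid]]
    v01 <- if (!is.null(pr)) rescale01(pr$value) else NULL
    passes <- !is.na(tr$orientation) &
      abs(tr$ascore) > params$ascore_min & tr$jscore > params$jscore_min
    for (i in seq_len(nrow(tr) - 1L)) {
      if (!(passes[i] && passes[i + 1L])) next
      o1 <- tr$orientation[i]; o2 <- tr$orientation[i + 1L]
      if (o1 == "left" && o2 == "right") {
        fs1 <- tr$fork_start[i]; fs2 <- tr$fork_start[i + 1L]
        if (fs2 - fs1 < params$fork_gap_min) next
        if (!is.null(v01)) {
          between <- pr$position > fs1 & pr$position < fs2
          if (any(between) && mean(v01[between]) > params$plateau_max) next
        }
        out[[length(out) + 1L]] <- tibble::tibble(
          read_id = rid, chrom = tr$chrom[i], type = "initiation",
          midpoint = (fs1 + fs2) / 2,
          fork_start_left = fs1, fork_start_right = fs2,
          method = tr$method[i])
      } else if (o1 == "right" && o2 == "left") {
        if (tr$min_p[i] > params$plateau_max ||
            tr$min_f[i + 1L] > params$plateau_max) next
        fs1 <- tr$fork_start[i]; fs2 <- tr$fork_start[i + 1L]
        out[[length(out) + 1L]] <- tibble::tibble(
          read_id = rid, chrom = tr$chrom[i], type = "termination",
          midpoint = (fs1 + fs2) / 2,
          fork_start_left = fs1, fork_start_right = fs2,
          method = tr$method[i])
      }
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Pool events detected by the CNN and TM paths
#'
#' Greedy nearest-pair matching per read and event type: the closest
#' CNN/TM midpoint pair within `share_distance` is marked shared (ties
#' broken by smaller distance, then leftmost) and counted once in the
#' pool; all unmatched events are retained.
#'
#' @param cnn_events,tm_events Event tibbles from [call_events()].
#' @param share_distance Maximal midpoint distance (nt) for sharing.
#' @return Pooled event tibble with a `shared` flag; shared events carry
#'   the mean of the two midpoints and `method = "shared"`.
#' @export
merge_method_events <- function(cnn_events, tm_events, share_distance = 2000) {
  a <- cnn_events; b <- tm_events
  if (!nrow(a) && !nrow(b)) {
    out <- a
    out$shared <- logical(0)
    return(out)
  }
  pool <- list()
  keys <- unique(rbind(a[c("read_id", "type")], b[c("read_id", "type")]))
  for (k in seq_len(nrow(keys))) {
    ai <- a[a$read_id == keys$read_id[k] & a$type == keys$type[k], , drop = FALSE]
    bi <- b[b$read_id == keys$read_id[k] & b$type == keys$type[k], , drop = FALSE]
    if (nrow(ai) && nrow(bi)) {
      pairs <- expand.grid(i = seq_len(nrow(ai)), j = seq_len(nrow(bi)))
      pairs$dist <- abs(ai$midpoint[pairs$i] - bi$midpoint[pairs$j])
      pairs$left <- pmin(ai$midpoint[pairs$i], bi$midpoint[pairs$j])
      pairs <- pairs[pairs$dist <= share_distance, , drop = FALSE]
      pairs <- pairs[order(pairs$dist, pairs$left), , drop = FALSE]
      used_i <- logical(nrow(ai)); used_j <- logical(nrow(bi))
      for (p in seq_len(nrow(pairs))) {
        i <- pairs$i[p]; j <- pairs$j[p]
        if (used_i[i] || used_j[j]) next
        used_i[i] <- TRUE; used_j[j] <- TRUE
        sh <- ai[i, , drop = FALSE]
        sh$midpoint <- (ai$midpoint[i] + bi$midpoint[j]) / 2
        sh$method <- "shared"
        sh$shared <- TRUE
        pool[[length(pool) + 1L]] <- sh
      }
      rest_a <- ai[!used_i, , drop = FALSE]
      rest_b <- bi[!used_j, , drop = FALSE]
    } else {
      rest_a <- ai; rest_b <- bi
    }
    if (nrow(rest_a)) { rest_a$shared <- FALSE; pool[[length(pool) + 1L]] <- rest_a }
    if (nrow(rest_b)) { rest_b$shared <- FALSE; pool[[length(pool) + 1L]] <- rest_b }
  }
  dplyr::bind_rows(pool)
}
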