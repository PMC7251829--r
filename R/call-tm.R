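# Transition-matrix BrdU calling: B/T/X per central-T site, plus the
# 30-site sliding fraction that turns calls into a content profile.

# Per-read core: local 0-based positions of callable T sites and their
# calls ("B", "T", "X").  Calling sites are hexamers with a T at position
# 3; a site is callable (B/T) only when the two expected shifts differ by
# more than gap_threshold, otherwise it is indeterminate (X).  Equidistant
# observations are conservatively X.
tm_call_core <- function(codes, shifts, dt, db, gap_threshold) {
  hx <- hexamer_index(codes)
  if (!length(hx)) {
    return(list(pos = integer(0), call = character(0)))
  }
  site <- which(codes[3:(length(codes) - 3L)] == 3L)   # hexamer start i with T at i+2
  site <- site[site <= length(hx)]
  if (!length(site)) return(list(pos = integer(0), call = character(0)))
  et <- dt[hx[site]]
  eb <- db[hx[site]]
  d <- shifts[site]
  call <- rep("X", length(site))
  callable <- abs(et - eb) > gap_threshold & is.finite(d)
  dist_t <- abs(d - et)
  dist_b <- abs(d - eb)
  call[callable & dist_b < dist_t] <- "B"
  call[callable & dist_t < dist_b] <- "T"
  list(pos = site + 1L, call = call)   # local 0-based coord of the central T
}

#' Call BrdU per T site with the transition matrices
#'
#' At every hexamer with a T at position 3 (the center of the first
#' pentamer), compares the observed normalized shift with the expected
#' thymidine and BrdU shifts.  When the two expectations differ by more
#' than `gap_threshold` the nearer one wins (`"B"` or `"T"`); otherwise,
#' or on a tie, the site is indeterminate (`"X"`).  Calls are
#' deterministic and position-local.
#'
#' @param reads Reads tibble (normalized shifts expected).
#' @param tm_t,tm_b Thymidine / BrdU [transition_matrix()] objects.
#' @param gap_threshold Minimum expected-shift gap for a B/T call.
#' @return Tibble with `read_id`, `chrom`, `position` (0-based reference
#'   coordinate of the central T) and `call`.
#' @export
call_tm <- function(reads, tm_t, tm_b, gap_threshold = 0.4) {
  dt <- tm_delta(tm_t)
  db <- tm_delta(tm_b)
  shifts <- read_shifts(reads)
  out <- purrr::map(seq_len(nrow(reads)), function(i) {
    codes <- base_codes(reads$bases[[i]])
    cc <- tm_call_core(codes, shifts[[i]], dt, db, gap_threshold)
    tibble::tibble(read_id = reads$read_id[[i]], chrom = reads$chrom[[i]],
                   position = reads$ref_start[[i]] + cc$pos, call = cc$call)
  })
  dplyr::bind_rows(out)
}

# Per-read core of the sliding fraction: positions (0-based) and calls at
# B/T sites only; returns positions and values of the smoothed profile.
fraction_core <- function(pos, call, window) {
  keep <- call != "X"
  pos <- pos[keep]
  b <- as.numeric(call[keep] == "B")
  n <- length(b)
  if (n < window) return(list(pos = numeric(0), value = numeric(0)))
  cs <- c(0, cumsum(b))
  k <- seq_len(n - window + 1L)
  value <- (cs[k + window] - cs[k]) / window
  half <- window %/% 2L
  # anchor at the center of the window (mean of the two central site
  # coordinates for an even window)
  anchor <- (pos[k + half - 1L] + pos[k + half]) / 2
  list(pos = anchor, value = value)
}

#' Smooth B/T calls into a fractional BrdU content profile
#'
#' Sliding fraction `B / (B + T)` over `window` consecutive sites called
#' B or T (indeterminate X sites are excluded from both numerator and
#' denominator).  Each value is anchored at the center of its window of
#' call sites.  Reads with fewer than `window` non-X sites yield an empty
#' profile.
#'
#' @param calls Call tibble from [call_tm()].
#' @param window Number of consecutive B/T sites per window.
#' @return Profile tibble with `read_id`, `chrom`, `position`, `value`.
#' @export
profile_to_fraction <- function(calls, window = 30L) {
  stopifnot(window >= 2L)
  out <- calls %>%
    dplyr::group_by(.data$read_id, .data$chrom) %>%
    dplyr::group_map(function(g, key) {
      fc <- fraction_core(g$position, g$call, window)
      tibble::tibble(read_id = key$read_id, chrom = key$chrom,
                     position = fc$pos, value = fc$value)
    })
  dplyr::bind_rows(out)
}
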