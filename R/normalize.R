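# Drift normalization and reference transition-matrix estimation.

#' Current shifts from per-base mean currents
#'
#' The shift at transition `i` is `delta_i = m_i - m_(i+1)`: `n` currents
#' yield `n - 1` shifts.
#'
#' @param x Numeric vector of per-base currents, or a reads tibble with a
#'   `currents` list-column (shifts are then (re)derived for every read).
#' @return Numeric vector of length `n - 1`, or the reads tibble with a
#'   fresh `shifts` list-column.
#' @export
#' @examples
#' compute_shifts(c(10, 8, 11))
compute_shifts <- function(x) {
  if (is.data.frame(x)) {
    x$shifts <- purrr::map(x$currents, compute_shifts)
    return(x)
  }
  if (length(x) < 2L) stop("at least 2 currents are required to form shifts")
  x[-length(x)] - x[-1L]
}

# Shifts list-column, deriving from currents when absent.
read_shifts <- function(reads) {
  if ("shifts" %in% names(reads)) return(reads$shifts)
  purrr::map(reads$currents, compute_shifts)
}

#' Estimate a transition matrix from a read population
#'
#' Per-hexamer arithmetic mean of the observed shifts over all reads.
#' Only transitions with a complete hexamer context (bases `i..i+5`) are
#' used.  Hexamers observed fewer than `min_occurrences` times are
#' flagged; hexamers never observed are imputed with the global mean
#' shift and flagged as imputed so expected-shift lookups have no holes.
#'
#' @param reads Reads tibble.
#' @param min_occurrences Minimum observations for an unflagged entry.
#' @param context `"T"` or `"B"`, recorded on the result.
#' @param max_reads Cap on the number of reads used (first `max_reads`).
#' @return A [transition_matrix()].
#' @export
estimate_transition_matrix <- function(reads, min_occurrences = 5L,
                                       context = c("T", "B"),
                                       max_reads = 4000L) {
  context <- match.arg(context)
  if (is.null(reads) || nrow(reads) == 0L) stop("empty read set")
  if (nrow(reads) > max_reads) reads <- reads[seq_len(max_reads), ]
  shifts <- read_shifts(reads)
  sums <- numeric(4096L)
  counts <- numeric(4096L)
  for (i in seq_len(nrow(reads))) {
    codes <- base_codes(reads$bases[[i]])
    hx <- hexamer_index(codes)
    d <- shifts[[i]][seq_along(hx)]
    ok <- !is.na(hx) & is.finite(d)
    if (!any(ok)) next
    s <- rowsum(d[ok], hx[ok])
    idx <- as.integer(rownames(s))
    sums[idx] <- sums[idx] + s[, 1L]
    counts[idx] <- counts[idx] + tabulate(hx[ok], nbins = 4096L)[idx]
  }
  if (!any(counts > 0)) stop("no usable transitions in read set")
  delta <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  global <- sum(sums) / sum(counts)
  imputed <- counts == 0
  delta[imputed] <- global
  tm <- transition_matrix(delta, context = context,
                          n_obs = as.integer(counts), imputed = imputed)
  attr(tm, "low_count") <- counts < min_occurrences
  tm
}

#' Fit the per-read linear drift against a reference matrix
#'
#' Finds `(alpha, beta)` minimizing `sum((alpha * delta_i + beta -
#' delta_e_i)^2)` over the read's transitions, where `delta_e` is the
#' expected shift from `reference_matrix`.  Transitions whose hexamer has
#' a T at the center of either pentamer are disregarded (those are the
#' BrdU-sensitive contexts), so the fit is blind to the read's BrdU
#' content.  The solution is the closed-form ordinary least squares
#' estimate; the reported residual is the minimized mean squared
#' distance.
#'
#' @param read One-row reads tibble (or a reads tibble whose first row is
#'   used).
#' @param reference_matrix A [transition_matrix()].
#' @param min_transitions Minimum usable transitions; below this the
#'   2-parameter fit is considered unstable and the read is rejected.
#' @return Object of class `drift_fit`: list with `alpha`, `beta`,
#'   `residual`, `n_used`, `read_id`.
#' @export
fit_drift <- function(read, reference_matrix, min_transitions = 50L) {
  stopifnot(is.data.frame(read), nrow(read) >= 1L)
  read <- read[1L, ]
  codes <- base_codes(read$bases[[1L]])
  hx <- hexamer_index(codes)
  d <- read_shifts(read)[[1L]][seq_along(hx)]
  eligible <- !hexamer_has_central_t()[hx] & is.finite(d)
  n_used <- sum(eligible)
  if (n_used < min_transitions) {
    stop("read ", read$read_id[[1L]], " rejected: only ", n_used,
         " usable non-T-centered transitions (need ", min_transitions, ")")
  }
  x <- d[eligible]
  y <- tm_delta(reference_matrix)[hx[eligible]]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("read ", read$read_id[[1L]],
                     " rejected: degenerate (constant) shift signal")
  alpha <- sum((x - mean(x)) * (y - mean(y))) / sxx
  beta <- mean(y) - alpha * mean(x)
  residual <- mean((alpha * x + beta - y)^2)
  structure(
    list(alpha = alpha, beta = beta, residual = residual,
         n_used = n_used, read_id = read$read_id[[1L]]),
    class = "drift_fit"
  )
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf("<drift_fit> %s: alpha = %.4f, beta = %.4f, residual = %.5f (n = %d)\n",
              x$read_id, x$alpha, x$beta, x$residual, x$n_used))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_drift
#' @param x A `drift_fit`.
#' @param ... Unused.
#' @export
tidy.drift_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"), estimate = c(x$alpha, x$beta))
}

#' @rdname fit_drift
#' @export
glance.drift_fit <- function(x, ...) {
  tibble::tibble(read_id = x$read_id, alpha = x$alpha, beta = x$beta,
                 residual = x$residual, n_used = x$n_used)
}

#' Drift-normalize a read population against a reference matrix
#'
#' Fits the per-read drift with [fit_drift()] and replaces each surviving
#' read's shifts by `alpha * delta + beta` (currents are rebuilt to stay
#' consistent).  Reads whose minimized mean squared distance exceeds
#' `residual_cutoff` are discarded, as are reads with too few usable
#' transitions; both end up in the rejection log.
#'
#' @param reads Reads tibble.
#' @param reference_matrix A [transition_matrix()].
#' @param residual_cutoff Discard reads with residual strictly greater
#'   than this.
#' @param min_transitions Passed to [fit_drift()].
#' @return The surviving reads with extra columns `fit_alpha`,
#'   `fit_beta`, `fit_residual`; the rejection log (tibble with
#'   `read_id`, `residual`, `reason`) is attached as attribute
#'   `"rejections"` and available via [rejection_log()].
#' @export
normalize_reads <- function(reads, reference_matrix, residual_cutoff = 0.25,
                            min_transitions = 50L) {
  stopifnot(is.data.frame(reads))
  fits <- purrr::map(seq_len(nrow(reads)), function(i) {
    tryCatch(fit_drift(reads[i, ], reference_matrix, min_transitions),
             error = function(e) conditionMessage(e))
  })
  failed <- vapply(fits, is.character, logical(1))
  resid <- vapply(fits, function(f) if (is.character(f)) NA_real_ else f$residual,
                  numeric(1))
  keep <- !failed & resid <= residual_cutoff
  rejections <- tibble::tibble(
    read_id = reads$read_id[!keep],
    residual = resid[!keep],
    reason = vapply(which(!keep), function(i) {
      if (failed[i]) fits[[i]] else paste0("residual > ", residual_cutoff)
    }, character(1))
  )
  out <- reads[keep, , drop = FALSE]
  if (nrow(out)) {
    kept_fits <- fits[keep]
    sh <- read_shifts(out)
    out$shifts <- purrr::map2(sh, kept_fits, function(d, f) f$alpha * d + f$beta)
    out$currents <- purrr::map(out$shifts, function(d) rev(cumsum(rev(c(d, 0)))))
    out$fit_alpha <- vapply(kept_fits, `[[`, numeric(1), "alpha")
    out$fit_beta <- vapply(kept_fits, `[[`, numeric(1), "beta")
    out$fit_residual <- vapply(kept_fits, `[[`, numeric(1), "residual")
  }
  attr(out, "rejections") <- rejections
  out
}

#' Rejection log attached to a filtered object
#'
#' @param x Result of [normalize_reads()] or other filtering steps.
#' @return Tibble of rejected items (empty tibble when none).
#' @export
rejection_log <- function(x) {
  r <- attr(x, "rejections")
  if (is.null(r)) tibble::tibble() else r
}

#' Two-step estimation of reference thymidine / BrdU transition matrices
#'
#' For each condition (replicates allowed): (1) bootstrap a transition
#' matrix from the raw reads; (2) drift-normalize the reads against it,
#' discarding reads with residual above `residual_cutoff`, and re-estimate
#' the matrix from the normalized survivors.  Replicate matrices are then
#' averaged.  Finally both read populations are re-normalized against the
#' thymidine reference.
#'
#' @param thymidine_reads,brdu_reads A reads tibble or a list of replicate
#'   reads tibbles.
#' @param residual_cutoff,min_transitions See [normalize_reads()].
#' @param min_occurrences,max_reads See [estimate_transition_matrix()].
#' @return List with `tm_t`, `tm_b`, normalized `reads_t`, `reads_b`, and
#'   a `rejections` summary tibble (per condition and replicate).
#' @export
build_reference_matrices <- function(thymidine_reads, brdu_reads,
                                     residual_cutoff = 0.25,
                                     min_transitions = 50L,
                                     min_occurrences = 5L,
                                     max_reads = 4000L) {
  as_replicates <- function(x, cond) {
    if (is.data.frame(x)) x <- list(x)
    if (length(x) == 1L) {
      message("condition ", cond, ": single replicate supplied; ",
              "replicate averaging is a no-op")
    }
    x
  }
  one_condition <- function(replicates, context) {
    mats <- list(); logs <- list(); normed <- list()
    for (r in seq_along(replicates)) {
      reads <- replicates[[r]]
      step1 <- estimate_transition_matrix(reads, min_occurrences, context,
                                          max_reads)
      nr <- normalize_reads(reads, step1, residual_cutoff, min_transitions)
      if (nrow(nr) == 0L) stop("condition ", context, " replicate ", r,
                               ": zero surviving reads")
      mats[[r]] <- estimate_transition_matrix(nr, min_occurrences, context,
                                              max_reads)
      logs[[r]] <- tibble::tibble(
        condition = context, replicate = r,
        n_total = nrow(reads), n_rejected = nrow(rejection_log(nr))
      )
      normed[[r]] <- nr
    }
    delta <- rowMeans(vapply(mats, function(m) m$delta, numeric(4096L)))
    n_obs <- as.integer(rowSums(vapply(mats, function(m) as.numeric(m$n_obs),
                                       numeric(4096L))))
    list(tm = transition_matrix(delta, context, n_obs = n_obs,
                                imputed = n_obs == 0L),
         log = dplyr::bind_rows(logs),
         reads = dplyr::bind_rows(normed))
  }
  t_rep <- as_replicates(thymidine_reads, "T")
  b_rep <- as_replicates(brdu_reads, "B")
  ct <- one_condition(t_rep, "T")
  cb <- one_condition(b_rep, "B")
  # final pass: everything re-normalized against the thymidine reference
  reads_t <- normalize_reads(dplyr::bind_rows(t_rep), ct$tm,
                             residual_cutoff, min_transitions)
  reads_b <- normalize_reads(dplyr::bind_rows(b_rep), ct$tm,
                             residual_cutoff, min_transitions)
  list(tm_t = ct$tm, tm_b = cb$tm,
       reads_t = reads_t, reads_b = reads_b,
       rejections = dplyr::bind_rows(ct$log, cb$log))
}
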