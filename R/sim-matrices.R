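#' Construct a transition-matrix object
#'
#' A transition matrix maps each of the 4096 hexamers (pentamer-to-pentamer
#' transitions) to the expected normalized current shift in a given context
#' (`"T"` for thymidine, `"B"` for BrdU).
#'
#' @param delta Numeric vector of length 4096 in canonical hexamer order
#'   (see [hexamers()]).
#' @param context `"T"` or `"B"`.
#' @param n_obs Optional integer vector of per-hexamer observation counts.
#' @param imputed Optional logical vector flagging hexamers whose value was
#'   imputed (never observed).
#' @return A tibble of class `transition_matrix` with columns `hexamer`,
#'   `delta`, `n_obs`, `imputed`.
#' @export
transition_matrix <- function(delta, context = c("T", "B"),
                              n_obs = NA_integer_, imputed = FALSE) {
  context <- match.arg(context)
  stopifnot(length(delta) == 4096L, all(is.finite(delta)))
  out <- tibble::tibble(
    hexamer = hexamers(),
    delta = as.numeric(delta),
    n_obs = as.integer(rep_len(n_obs, 4096L)),
    imputed = rep_len(as.logical(imputed), 4096L)
  )
  class(out) <- c("transition_matrix", class(out))
  attr(out, "context") <- context
  out
}

# Fast path: expected-shift vector in canonical hexamer order.
tm_delta <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix") ||
              (is.data.frame(tm) && all(c("hexamer", "delta") %in% names(tm))))
  if (identical(tm$hexamer, hexamers())) return(tm$delta)
  tm$delta[match(hexamers(), tm$hexamer)]
}

#' Simulate a thymidine/BrdU pair of transition matrices
#'
#' Draws a thymidine-context matrix with standard-normal expected shifts,
#' then displaces a subset of hexamers with a T at position 3 (the center of
#' the first pentamer) positively in the BrdU context, emulating the
#' positive current shift BrdU induces in the pore.  Only that informative
#' subset differs by more than the calling threshold; hexamers with no T at
#' the center of either pentamer are identical in the two contexts, and the
#' remaining T-containing hexamers receive a small sub-threshold
#' displacement.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list with elements `tm_t` and `tm_b` ([transition_matrix()]
#'   objects) and `informative`, the logical mask of displaced hexamers.
#' @export
#' @examples
#' tms <- make_transition_matrices(sim_config(seed = 7))
#' sum(abs(tms$tm_t$delta - tms$tm_b$delta) > 0.4)
make_transition_matrices <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(if (is.null(seed)) config$seed else seed, {
    delta_t <- stats::rnorm(4096L)
    delta_b <- delta_t

    t3 <- hexamer_has_t3()
    n_inf <- round(4096L * config$informative_fraction)
    stopifnot(n_inf <= sum(t3))
    # Informative hexamers are biased toward GC-rich flanking contexts:
    # in an AT-rich genome those hexamers are rare, which reproduces the
    # observed sparsity of callable sites (roughly one every ~15-20 nt
    # rather than the 1-in-8 a uniform draw of 12.5% of hexamers would
    # give).  Ties within a GC class are drawn at random.
    hx <- hexamers()
    flanks <- paste0(substr(hx, 1L, 2L), substr(hx, 4L, 6L))
    gc <- vapply(strsplit(flanks, "", fixed = TRUE),
                 function(b) sum(b %in% c("C", "G")), integer(1))
    cand <- which(t3)
    cand <- cand[order(-gc[cand], stats::runif(length(cand)))]
    informative <- rep(FALSE, 4096L)
    informative[cand[seq_len(n_inf)]] <- TRUE

    thr <- config$calling_threshold
    if (n_inf > 0L) {
      # Informative gaps sit well clear of the calling threshold (callable
      # sites are defined by clear separation; the bulk of the informative
      # transitions shift by about one normalized unit): uniform within
      # +/-20% of shift_gap, always displaced positively (BrdU shifts the
      # current up).
      gaps <- stats::runif(n_inf, 0.8, 1.2) * config$shift_gap
      if (min(gaps) <= thr) {
        stop("shift_gap too close to the calling threshold for an ",
             "informative band clear of it")
      }
      delta_b[informative] <- delta_t[informative] + gaps
    }
    # Sub-threshold perturbation at the other hexamers with a central T
    # (either pentamer): BrdU still nudges them, but below callability.
    # The degenerate zero-informative config leaves the contexts identical.
    if (n_inf > 0L) {
      minor <- hexamer_has_central_t() & !informative
      delta_b[minor] <- delta_t[minor] +
        stats::runif(sum(minor), 0, 0.5 * thr)
    }

    list(
      tm_t = transition_matrix(delta_t, context = "T"),
      tm_b = transition_matrix(delta_b, context = "B"),
      informative = informative
    )
  })
}

#' Write / read a transition-matrix pair as a delimited table
#'
#' Serializes both contexts side by side as a 4096-row TSV with columns
#' `hexamer`, `delta_t`, `delta_b`, `n_obs_t`, `n_obs_b`.
#'
#' @param tm_t,tm_b [transition_matrix()] objects.
#' @param path File path.
#' @return `write_transition_matrices()` returns `path` invisibly;
#'   `read_transition_matrices()` returns a list with `tm_t` and `tm_b`.
#' @export
write_transition_matrices <- function(tm_t, tm_b, path) {
  stopifnot(identical(tm_t$hexamer, tm_b$hexamer))
  readr::write_tsv(
    tibble::tibble(hexamer = tm_t$hexamer,
                   delta_t = tm_t$delta, delta_b = tm_b$delta,
                   n_obs_t = tm_t$n_obs, n_obs_b = tm_b$n_obs),
    path
  )
  invisible(path)
}

#' @rdname write_transition_matrices
#' @export
read_transition_matrices <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(nrow(tab) == 4096L)
  ord <- match(hexamers(), tab$hexamer)
  if (anyNA(ord)) stop("transition matrix table does not cover all 4096 hexamers")
  list(
    tm_t = transition_matrix(tab$delta_t[ord], "T", n_obs = tab$n_obs_t[ord]),
    tm_b = transition_matrix(tab$delta_b[ord], "B", n_obs = tab$n_obs_b[ord])
  )
}
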