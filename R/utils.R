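# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers' random streams are untouched.  A `NULL`
#' seed evaluates the code against the current RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Base <-> integer code maps.  A=0, C=1, G=2, T=3; lexicographic like
# Biostrings' DNA order restricted to ACGT.
BASES <- c("A", "C", "G", "T")
BASE_CODE <- stats::setNames(0:3, BASES)

# Integer codes (0..3) for a base string; NA for non-ACGT.
base_codes <- function(bases) {
  if (length(bases) == 1L && nchar(bases) > 1L) {
    bases <- strsplit(bases, "", fixed = TRUE)[[1L]]
  }
  unname(BASE_CODE[bases])
}

#' All 4096 hexamers in canonical (index) order
#'
#' The canonical order is lexicographic over A < C < G < T, i.e. hexamer
#' index `1 + sum(code[k] * 4^(6-k))` for 1-based position `k`.
#'
#' @return Character vector of length 4096.
#' @export
#' @examples
#' head(hexamers())
hexamers <- function() {
  g <- expand.grid(b6 = BASES, b5 = BASES, b4 = BASES, b3 = BASES,
                   b2 = BASES, b1 = BASES, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3, g$b4, g$b5, g$b6)
}

# 1-based canonical index of the hexamer starting at each position of a
# coded base vector.  Returns a vector of length n - 5 (NA where any base
# is NA).
hexamer_index <- function(codes) {
  n <- length(codes)
  if (n < 6L) return(integer(0))
  m <- n - 5L
  idx <- codes[seq_len(m)] * 1024L
  idx <- idx + codes[seq_len(m) + 1L] * 256L
  idx <- idx + codes[seq_len(m) + 2L] * 64L
  idx <- idx + codes[seq_len(m) + 3L] * 16L
  idx <- idx + codes[seq_len(m) + 4L] * 4L
  idx <- idx + codes[seq_len(m) + 5L]
  idx + 1L
}

# Logical masks over the 4096 canonical hexamers.
# "Central T" calling sites have T at position 3 (the center of the first
# pentamer); drift fitting excludes hexamers with T at position 3 or 4
# (the center of either pentamer).
hexamer_has_t3 <- function() {
  substr(hexamers(), 3L, 3L) == "T"
}

hexamer_has_central_t <- function() {
  hx <- hexamers()
  substr(hx, 3L, 3L) == "T" | substr(hx, 4L, 4L) == "T"
}

# Centered running mean over a possibly NA-holed numeric vector.
# Window of k bins (k forced odd); edges shrink to the available window;
# bins where fewer than min_frac of the window positions are defined stay NA.
running_mean <- function(x, k, min_frac = 0.5) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs))
  cn <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  s <- cs[hi + 1L] - cs[lo]
  m <- cn[hi + 1L] - cn[lo]
  width <- hi - lo + 1L
  out <- ifelse(m > 0 & m >= min_frac * width, s / m, NA_real_)
  out
}

# Coerce a reference genome given as a named character vector, a single
# string, or a Biostrings::DNAStringSet into a named character vector.
as_sequences <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("reference must be a named character vector or a DNAStringSet")
}

# Tibble (chrom, length) from sequences or from an explicit genome tibble.
as_genome_tbl <- function(genome) {
  if (is.data.frame(genome)) {
    stopifnot(all(c("chrom", "length") %in% names(genome)))
    return(tibble::as_tibble(genome[, c("chrom", "length")]))
  }
  seqs <- as_sequences(genome)
  tibble::tibble(chrom = names(seqs), length = nchar(unname(seqs)))
}

# Guard against mixed chromosome naming conventions ("chrI" vs "I").
check_chrom_naming <- function(chroms) {
  u <- unique(chroms)
  pref <- grepl("^chr", u)
  if (any(pref) && !all(pref)) {
    stop("mixed chromosome naming conventions: ",
         paste(utils::head(u[pref], 3), collapse = ", "), " vs ",
         paste(utils::head(u[!pref], 3), collapse = ", "))
  }
  invisible(TRUE)
}
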