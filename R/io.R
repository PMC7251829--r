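# Readers and writers: resquiggled-read tables, FASTA, BED, wiggle /
# bedGraph.  All internal coordinates are 0-based half-open; BED is
# native 0-based, wiggle's 1-based starts are converted on load.

#' Read and write the resquiggled-read table
#'
#' The on-disk format is a TSV with one row per read and columns
#' `read_id`, `chrom`, `ref_start` (0-based), `strand`, `bases` (the
#' reference-aligned sequence, forward strand) and `currents`
#' (comma-separated per-base mean normalized currents).  Optional
#' ground-truth columns written by the simulator (`truth_prob`,
#' `truth_incorp`, comma-separated per base) round-trip as well.
#' Current shifts `delta_i = m_i - m_(i+1)` are derived on load.
#' Structurally malformed rows raise an error naming the row; reads with
#' non-ACGT bases or mismatched lengths are dropped and logged in the
#' rejection attribute.
#'
#' @param path File path.
#' @return `read_resquiggled_table()`: reads tibble with `shifts`
#'   derived; rejected rows via [rejection_log()].
#' @export
read_resquiggled_table <- function(path) {
  # fields can be megabytes long (one row per read), which chokes
  # scan()-based readers; parse lines directly
  lines <- readLines(path)
  if (!length(lines)) stop("empty resquiggled table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  required <- c("read_id", "chrom", "ref_start", "strand", "bases", "currents")
  if (!all(required %in% header)) {
    stop("resquiggled table must have columns: ",
         paste(required, collapse = ", "))
  }
  fields <- fields[-1L]
  tab <- lapply(stats::setNames(seq_along(header), header), function(j) {
    vapply(fields, function(f) if (length(f) >= j) f[[j]] else NA_character_,
           character(1))
  })
  bad <- which(Reduce(`|`, lapply(tab[required],
                                  function(v) is.na(v) | v == "")))
  if (length(bad)) {
    stop("malformed row ", bad[1], " in ", path, ": missing required field")
  }
  parse_num <- function(s) {
    if (is.na(s) || s == "") return(NULL)
    suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
  }
  rows <- list(); rejects <- list()
  for (i in seq_along(tab$read_id)) {
    bases <- tab$bases[i]
    cur <- parse_num(tab$currents[i])
    reason <- NULL
    if (grepl("[^ACGT]", bases)) {
      reason <- "non-ACGT bases"
    } else if (anyNA(cur)) {
      reason <- "unparseable currents"
    } else if (length(cur) != nchar(bases)) {
      reason <- "currents/bases length mismatch"
    }
    if (!is.null(reason)) {
      rejects[[length(rejects) + 1L]] <-
        tibble::tibble(row = i, read_id = tab$read_id[i], reason = reason)
      next
    }
    row <- tibble::tibble(
      read_id = tab$read_id[i], chrom = tab$chrom[i],
      ref_start = as.numeric(tab$ref_start[i]), strand = tab$strand[i],
      bases = bases, currents = list(cur),
      shifts = list(compute_shifts(cur)))
    tp <- if ("truth_prob" %in% names(tab)) parse_num(tab$truth_prob[i]) else NULL
    ti <- if ("truth_incorp" %in% names(tab)) parse_num(tab$truth_incorp[i]) else NULL
    if (!is.null(tp)) row$truth_prob <- list(tp)
    if (!is.null(ti)) row$truth_incorp <- list(as.integer(ti))
    rows[[length(rows) + 1L]] <- row
  }
  rejects <- dplyr::bind_rows(rejects)
  if (nrow(rejects)) {
    message(nrow(rejects), " read(s) rejected on load; see rejection_log()")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "rejections") <- rejects
  out
}

#' @rdname read_resquiggled_table
#' @param reads Reads tibble.
#' @param truth Also write the simulator's ground-truth columns when
#'   present.
#' @export
write_resquiggled_table <- function(reads, path, truth = TRUE) {
  fmt <- function(v) vapply(v, function(x) {
    paste(formatC(x, format = "g", digits = 10), collapse = ",")
  }, character(1))
  out <- data.frame(
    read_id = reads$read_id, chrom = reads$chrom,
    ref_start = format(reads$ref_start, scientific = FALSE, trim = TRUE),
    strand = reads$strand, bases = reads$bases,
    currents = fmt(reads$currents),
    stringsAsFactors = FALSE)
  if (truth && !is.null(reads$truth_prob)) out$truth_prob <- fmt(reads$truth_prob)
  if (truth && !is.null(reads$truth_incorp)) out$truth_incorp <- fmt(reads$truth_incorp)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write tracks, events or clusters as BED6
#'
#' Tracks use their extent with strand `+` for rightward and `-` for
#' leftward orientation (unoriented tracks get `.`); events are expanded
#' by `event_halfwidth` around their midpoint with `name` `init`/`term`;
#' clusters span their outmost events with `score = d`.  Output is
#' sorted by chromosome and start and starts with a header comment.
#'
#' @param items Tibble of tracks, events or clusters (auto-detected from
#'   columns).
#' @param path File path.
#' @param event_halfwidth Half-width (nt) for events.
#' @return `path`, invisibly.
#' @export
write_bed <- function(items, path, event_halfwidth = 1) {
  header <- "# chrom\tstart\tend\tname\tscore\tstrand"
  if (!nrow(items)) {
    readr::write_lines(header, path)
    return(invisible(path))
  }
  if ("type" %in% names(items)) {           # events
    bed <- tibble::tibble(
      chrom = items$chrom,
      start = pmax(0, round(items$midpoint - event_halfwidth)),
      end = round(items$midpoint + event_halfwidth),
      name = ifelse(items$type == "initiation", "init", "term"),
      score = if ("jscore" %in% names(items)) round(items$jscore, 2) else 1,
      strand = ".")
  } else if ("d" %in% names(items)) {       # clusters
    bed <- tibble::tibble(
      chrom = items$chrom, start = round(items$start),
      end = round(pmax(items$end, items$start + 1)),
      name = paste0("cluster_d", items$d), score = items$d, strand = ".")
  } else {                                  # tracks
    strand <- if ("orientation" %in% names(items)) {
      ifelse(is.na(items$orientation), ".",
             ifelse(items$orientation == "right", "+", "-"))
    } else "."
    nm <- if ("read_id" %in% names(items)) items$read_id else "track"
    bed <- tibble::tibble(
      chrom = items$chrom, start = round(items$start),
      end = round(items$end), name = nm,
      score = if ("jscore" %in% names(items)) round(items$jscore, 2) else 0,
      strand = strand)
  }
  bed <- dplyr::arrange(bed, .data$chrom, .data$start)
  body <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", bed$chrom, as.integer(bed$start),
                  as.integer(bed$end), bed$name, format(bed$score), bed$strand)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read an annotation BED file
#'
#' BED is natively 0-based half-open, which matches the package's
#' internal convention, so coordinates pass through unchanged.  Mixed
#' chromosome naming conventions ("chrI" alongside "I") raise an error.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  check_chrom_naming(out$chrom)
  out
}

#' Read a wiggle or bedGraph track as a genome signal
#'
#' Wiggle's 1-based starts are converted to the internal 0-based
#' half-open convention (a `fixedStep start=1` value lands on internal
#' coordinate 0).  With `kind = "timing"` the values are binned into
#' non-overlapping windows and min-max normalized to `[0, 1]` (start and
#' end of S phase).
#'
#' @param path File path (`.wig`, `.bedgraph`/`.bg`).
#' @param kind Signal kind label; `"timing"` triggers binning and
#'   normalization.
#' @param bin Bin size used for `kind = "timing"`.
#' @return A `genome_signal` tibble (`chrom`, `start`, `end`, `value`).
#' @export
read_wig <- function(path, kind = "generic", bin = 1000) {
  fmt <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) "bedGraph" else "wig"
  gr <- rtracklayer::import(path, format = fmt)
  tb <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = gr$score)
  check_chrom_naming(tb$chrom)
  if (kind != "timing") {
    return(new_genome_signal(tb, kind, bin = stats::median(tb$end - tb$start)))
  }
  out <- tb %>%
    dplyr::mutate(bin_start = floor((.data$start + .data$end) / 2 / bin) * bin) %>%
    dplyr::group_by(.data$chrom, .data$bin_start) %>%
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  # complete the grid per chromosome so bin lookup by index works
  out <- out %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::group_map(function(g, key) {
      grid <- seq(0, max(g$bin_start), by = bin)
      tibble::tibble(chrom = key$chrom, start = grid, end = grid + bin,
                     value = g$value[match(grid, g$bin_start)])
    }) %>%
    dplyr::bind_rows()
  rng <- range(out$value, na.rm = TRUE)
  out$value <- (out$value - rng[1]) / (rng[2] - rng[1])
  new_genome_signal(out, "timing", bin)
}

#' Write a genome signal as bedGraph
#'
#' Missing bins are omitted (bedGraph has no NA representation; absence
#' of a line encodes an undefined bin, distinct from value 0).
#'
#' @param signal A `genome_signal`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(signal, path) {
  ok <- !is.na(signal$value)
  lines <- sprintf("%s\t%d\t%d\t%s", signal$chrom[ok],
                   as.integer(signal$start[ok]), as.integer(signal$end[ok]),
                   format(signal$value[ok], trim = TRUE))
  readr::write_lines(c(sprintf("track type=bedGraph name=%s",
                               attr(signal, "kind")), lines), path)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names truncated at the
#'   first whitespace).
#' @export
read_fasta_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_sequences(x)
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fasta_genome <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
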