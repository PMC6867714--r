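#' Construct a genome object
#'
#' A genome is a named set of upper-case nucleotide sequences with a
#' per-contig circularity flag. Bacterial and archaeal chromosomes are
#' circular by default, so coverage and windows wrap across the origin
#' unless a contig is declared linear.
#'
#' @param seqs Named character vector of sequences (A, C, G, T, N).
#' @param circular Logical, recycled per contig. Default `TRUE`.
#' @return An object of class `genome_seq`: list with elements `seqs`
#'   (named upper-case character vector) and `circular` (named logical).
#' @export
genome_seq <- function(seqs, circular = TRUE) {
  if (length(seqs) == 0) stop("genome must contain at least one contig")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("every contig needs a name")
  if (anyDuplicated(ids)) {
    stop("duplicate contig ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0)) stop("zero-length contig sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC (non-ACGTN) characters in contig(s): ",
         paste(ids[bad], collapse = ", "))
  }
  circular <- rep_len(as.logical(circular), length(seqs))
  names(circular) <- ids
  structure(list(seqs = seqs, circular = circular), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq> ", length(x$seqs), " contig(s)\n", sep = "")
  for (id in names(x$seqs)) {
    cat("  ", id, ": ", nchar(x$seqs[[id]]),
        " bp", if (x$circular[[id]]) " (circular)" else " (linear)", "\n", sep = "")
  }
  invisible(x)
}

#' Contig lengths of a genome
#' @param genome A `genome_seq`.
#' @return Named integer vector of contig lengths in bp.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  vapply(genome$seqs, nchar, integer(1))
}

#' Read a genome from FASTA
#'
#' Contigs are keyed by the first whitespace-delimited token of each
#' header; sequence is upper-cased. Duplicate ids and non-ACGTN
#' characters are rejected.
#'
#' @param path FASTA file.
#' @param circular Circularity flag passed to [genome_seq()].
#' @return A `genome_seq`.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_seq(seqs, circular = circular)
}

#' Write a genome to FASTA
#' @param genome A `genome_seq`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_seq"))
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

interval_cols <- c("contig", "start", "end", "strand", "name", "score")

#' Build an interval table
#'
#' All coordinates in the package are 0-based half-open (BED-native):
#' an interval `[start, end)` covers bases `start .. end - 1`. Records
#' are sorted by (contig, start, end).
#'
#' @param contig,start,end,strand,name,score Interval fields; `strand`
#'   is one of `"+", "-", "."`.
#' @param genome Optional `genome_seq` used to validate bounds.
#' @return A tibble with columns contig, start, end, strand, name, score.
#' @export
interval_tbl <- function(contig, start, end, strand = ".", name = ".",
                         score = 0, genome = NULL) {
  tb <- tibble::tibble(
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(contig)),
    name = rep_len(as.character(name), length(contig)),
    score = rep_len(as.numeric(score), length(contig))
  )
  validate_intervals(tb, genome)
}

validate_intervals <- function(tb, genome = NULL) {
  stopifnot(all(interval_cols %in% names(tb)))
  bad <- which(tb$start < 0 | tb$start >= tb$end)
  if (length(bad)) {
    stop("invalid interval(s) (need 0 <= start < end) at record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(tb$strand %in% c("+", "-", "."))) stop("strand must be one of + - .")
  if (!is.null(genome)) {
    lens <- contig_lengths(genome)
    unknown <- setdiff(unique(tb$contig), names(lens))
    if (length(unknown)) stop("unknown contig(s): ", paste(unknown, collapse = ", "))
    # on circular contigs an interval may run past L (origin wrap)
    lim <- ifelse(genome$circular[tb$contig], 2 * lens[tb$contig], lens[tb$contig])
    over <- which(tb$end > lim)
    if (length(over)) {
      stop("interval end beyond contig length at record(s): ",
           paste(utils::head(over, 5), collapse = ", "))
    }
  }
  dplyr::arrange(tb, .data$contig, .data$start, .data$end)
}

#' Read intervals or fragments from BED
#'
#' Accepts BED3 or BED6; coordinates are kept exactly as in the file
#' (0-based half-open). `kind = "fragments"` forces strand `"."` and
#' marks the table as a protected-fragment set; lengths below 160 bp
#' are the sequencing design's size selection, longer records are kept
#' but flagged in the `size_selected` attribute.
#'
#' @param path BED file (3 or 6 columns, tab- or space-separated).
#' @param kind `"annotation"` (default) or `"fragments"`.
#' @param genome Optional `genome_seq` for bounds checking.
#' @return A sorted interval tibble; for fragments, with a `length` column.
#' @export
read_bed <- function(path, kind = c("annotation", "fragments"), genome = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  tb <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 3) stop("BED needs at least 3 columns: ", path)
  bed_order <- c("contig", "start", "end", "name", "score", "strand")
  names(tb) <- bed_order[seq_len(min(6L, ncol(tb)))]
  bad <- which(tb$start >= tb$end)
  if (length(bad)) {
    stop("start >= end on line(s): ", paste(utils::head(bad, 5), collapse = ", "),
         " of ", path)
  }
  if (!"strand" %in% names(tb)) tb$strand <- "."
  if (!"name" %in% names(tb)) tb$name <- "."
  if (!"score" %in% names(tb)) tb$score <- 0
  tb$score <- suppressWarnings(as.numeric(tb$score))
  tb$score[is.na(tb$score)] <- 0
  tb <- tibble::as_tibble(tb[interval_cols])
  tb$strand[is.na(tb$strand) | tb$strand == ""] <- "."
  tb <- validate_intervals(tb, genome)
  if (kind == "fragments") tb <- as_fragments(tb)
  tb
}

#' Mark an interval table as a fragment set
#'
#' Fragments are unstranded protected intervals; a `length` column
#' (`end - start`) is added.
#'
#' @param tb Interval tibble.
#' @return The tibble with strand `"."` and a `length` column.
#' @export
as_fragments <- function(tb) {
  tb$strand <- "."
  tb$length <- tb$end - tb$start
  if (any(tb$length < 1)) stop("fragment of length < 1")
  tb
}

#' Write intervals as BED6
#' @param tb Interval tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(tb, path) {
  tb <- validate_intervals(tb)
  out <- tb[c("contig", "start", "end", "name", "score", "strand")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Select one TSS per broad TSS region
#'
#' Experimentally mapped transcription starts come as broad regions
#' with several candidate positions, each with a read-support count.
#' The position with the most reads inside each broad region is taken
#' as the TSS; ties are broken toward the smallest coordinate, and an
#' all-zero-support group keeps its first position with a warning.
#'
#' @param raw Tibble with columns `tss_id` (broad region id), `contig`,
#'   `position` (0-based), `strand`, `reads`, and optionally `gene`.
#' @return Tibble with one row per `tss_id`: contig, position, strand,
#'   reads, gene.
#' @export
select_tss <- function(raw) {
  stopifnot(all(c("tss_id", "contig", "position", "strand", "reads") %in% names(raw)))
  if (!"gene" %in% names(raw)) raw$gene <- NA_character_
  if (any(raw$reads < 0)) stop("negative read support")
  zero <- raw |>
    dplyr::summarise(allzero = all(.data$reads == 0), .by = "tss_id")
  if (any(zero$allzero)) {
    warning(sum(zero$allzero), " broad TSS group(s) with zero read support; ",
            "keeping first position")
  }
  raw |>
    dplyr::arrange(.data$tss_id, .data$position) |>
    dplyr::slice_max(.data$reads, n = 1, with_ties = FALSE, by = "tss_id") |>
    dplyr::select("tss_id", "contig", "position", "strand", "reads", "gene") |>
    dplyr::arrange(.data$contig, .data$position)
}

#' Per-base fragment coverage
#'
#' Counts, for every base of every contig, the number of fragments
#' overlapping it. On circular contigs a fragment running past the
#' contig end wraps and contributes to the origin-proximal bases, so
#' total mass is conserved. An optional length filter restricts the
#' track to a fragment-size window.
#'
#' @param fragments Fragment tibble (see [read_bed()]).
#' @param genome A `genome_seq`.
#' @param length_filter Optional `c(lo, hi)` (inclusive) on fragment length.
#' @param label Library label stored in the track metadata.
#' @return A `coverage_track`: list of per-contig numeric vectors with
#'   metadata (`n_fragments`, `length_filter`, `label`).
#' @export
coverage_track <- function(fragments, genome, length_filter = NULL, label = "") {
  stopifnot(inherits(genome, "genome_seq"))
  lens <- contig_lengths(genome)
  unknown <- setdiff(unique(fragments$contig), names(lens))
  if (length(unknown)) stop("fragments on unknown contig(s): ",
                            paste(unknown, collapse = ", "))
  if (!"length" %in% names(fragments)) fragments <- as_fragments(fragments)
  if (!is.null(length_filter)) {
    fragments <- dplyr::filter(fragments, .data$length >= length_filter[1],
                               .data$length <= length_filter[2])
    if (nrow(fragments) == 0) warning("length filter excluded all fragments")
  }
  track <- lapply(names(lens), function(id) {
    L <- lens[[id]]
    fr <- fragments[fragments$contig == id, ]
    v <- numeric(L)
    if (nrow(fr) == 0) return(v)
    s <- fr$start
    e <- fr$end
    if (genome$circular[[id]]) {
      s <- s %% L
      e <- s + fr$length
    } else if (any(e > L)) {
      stop("fragment beyond linear contig end on ", id)
    }
    e1 <- pmin(e, L)
    d <- tabulate(s + 1L, nbins = L) - tabulate(e1[e1 < L] + 1L, nbins = L)
    v <- cumsum(d)
    # tails of origin-spanning fragments cover [0, e - L)
    wrap <- pmin(e - L, L)
    for (w in wrap[wrap > 0]) v[seq_len(w)] <- v[seq_len(w)] + 1
    v
  })
  names(track) <- names(lens)
  structure(list(track = track, n_fragments = nrow(fragments),
                 length_filter = length_filter, label = label),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", x$label, " — ", x$n_fragments, " fragments",
      if (!is.null(x$length_filter))
        paste0(", lengths [", x$length_filter[1], ",", x$length_filter[2], "]"),
      "\n", sep = "")
  for (id in names(x$track)) {
    cat("  ", id, ": ", length(x$track[[id]]), " bp, mean ",
        signif(mean(x$track[[id]]), 4), "\n", sep = "")
  }
  invisible(x)
}

#' Export a track as bedGraph
#'
#' Runs of equal value are merged into single bedGraph records.
#'
#' @param track A `coverage_track` or `normalized_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(track$track)) {
    v <- track$track[[id]]
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(paste(id, s[keep], e[keep], signif(r$values[keep], 8),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#' @param path bedGraph file.
#' @param genome A `genome_seq` giving contig lengths.
#' @param label Library label.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, genome, label = "") {
  lens <- contig_lengths(genome)
  tb <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("contig", "start", "end", "value"))
  track <- lapply(names(lens), function(id) {
    v <- numeric(lens[[id]])
    sub <- tb[tb$contig == id, ]
    for (i in seq_len(nrow(sub))) {
      v[(sub$start[i] + 1):sub$end[i]] <- sub$value[i]
    }
    v
  })
  names(track) <- names(lens)
  structure(list(track = track, n_fragments = NA_integer_,
                 length_filter = NULL, label = label),
            class = "coverage_track")
}
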