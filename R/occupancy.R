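#' Fragment-size classes of the oligomer ladder
#'
#' Fragments are binned by protected length into classes centered on
#' the oligomer footprints (60, 90, 120, 150 bp) with a +/- 5 bp
#' tolerance; lengths between classes belong to none.
#'
#' @param length Fragment length(s) in bp.
#' @param centers Class centers.
#' @param tol Tolerance in bp.
#' @return Integer vector of class centers (NA where unassigned).
#' @export
assign_size_class <- function(length, centers = c(60L, 90L, 120L, 150L), tol = 5L) {
  stopifnot(all(length >= 1))
  i <- vapply(length, function(l) {
    d <- abs(centers - l)
    j <- which.min(d)
    if (d[j] <= tol) centers[j] else NA_integer_
  }, integer(1))
  i
}

#' Empty-vector normalized occupancy
#'
#' Per-base occupancy is the histone-strain coverage divided by the
#' pooled empty-vector coverage uniformly increased by one, so that
#' zero-coverage control regions stay analyzable:
#' `O(x) = c_strain(x) / (c_EV(x) + 1)`. With `scale_libraries` both
#' tracks are first scaled to fragments-per-million.
#'
#' @param strain A `coverage_track` (optionally size-class filtered).
#' @param ev The empty-vector `coverage_track`, pooled over sizes.
#' @param scale_libraries Scale both tracks to fragments-per-million
#'   before dividing. Default `FALSE` (matched library designs).
#' @return A `normalized_track` (same container as `coverage_track`).
#' @export
normalize_track <- function(strain, ev, scale_libraries = FALSE) {
  if (!identical(sort(names(strain$track)), sort(names(ev$track)))) {
    stop("strain and EV tracks cover different contigs")
  }
  fs <- fe <- 1
  if (scale_libraries) {
    fs <- 1e6 / max(strain$n_fragments, 1)
    fe <- 1e6 / max(ev$n_fragments, 1)
  }
  track <- lapply(names(strain$track), function(id) {
    if (length(strain$track[[id]]) != length(ev$track[[id]])) {
      stop("track length mismatch on ", id)
    }
    (strain$track[[id]] * fs) / (ev$track[[id]] * fe + 1)
  })
  names(track) <- names(strain$track)
  structure(list(track = track, n_fragments = strain$n_fragments,
                 length_filter = strain$length_filter,
                 label = paste0(strain$label, "/EV"),
                 scaled = scale_libraries),
            class = c("normalized_track", "coverage_track"))
}

#' Mean occupancy in sliding windows
#'
#' Windows of `width` bp stepped by `step` bp (default 60/30, i.e.
#' half-overlapping). The final partial window is dropped on linear
#' contigs and wrapped across the origin on circular ones.
#'
#' @param track A `coverage_track`/`normalized_track`.
#' @param width,step Window width and step in bp.
#' @param circular Named logical per contig (default: all circular).
#' @return Tibble contig, start, end, mean_value.
#' @export
windowed_means <- function(track, width = 60L, step = 30L, circular = TRUE) {
  purrr::map_dfr(names(track$track), function(id) {
    v <- track$track[[id]]
    L <- length(v)
    if (width > L) stop("window wider than contig ", id)
    circ <- if (length(circular) > 1) circular[[id]] else circular
    starts <- if (circ) seq(0L, L - 1L, by = step) else seq(0L, L - width, by = step)
    cs <- cumsum(c(0, if (circ) c(v, v[seq_len(width)]) else v))
    m <- (cs[starts + width + 1L] - cs[starts + 1L]) / width
    tibble::tibble(contig = id, start = starts,
                   end = starts + width, mean_value = m)
  })
}

#' Replicate concordance of windowed coverage
#'
#' Each replicate's 60/30 window coverage is expressed as a proportion
#' of its total fragment count, then the two window vectors are
#' compared by Spearman correlation.
#'
#' @param a,b Fragment tibbles (replicates).
#' @param genome A `genome_seq`.
#' @param width,step Window parameters.
#' @return List: `rho`, `p`, `windows` (tibble with both proportions).
#' @export
replicate_correlation <- function(a, b, genome, width = 60L, step = 30L) {
  wa <- windowed_means(coverage_track(a, genome), width, step,
                       circular = genome$circular)
  wb <- windowed_means(coverage_track(b, genome), width, step,
                       circular = genome$circular)
  pa <- wa$mean_value / nrow(a)
  pb <- wb$mean_value / nrow(b)
  if (length(pa) < 2) stop("need at least two windows")
  if (stats::sd(pa) == 0 || stats::sd(pb) == 0) {
    warning("zero-variance window coverage; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_,
                windows = dplyr::mutate(wa, prop_a = pa, prop_b = pb)))
  }
  ct <- suppressWarnings(stats::cor.test(pa, pb, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value,
       windows = dplyr::mutate(wa, prop_a = pa, prop_b = pb))
}

#' Coverage around TSSs by distance and fragment size
#'
#' For each fragment-size bin, mean coverage at each signed distance
#' from the TSS (negative = upstream); minus-strand TSSs are mirrored
#' so orientation is transcriptional.
#'
#' @param fragments Fragment tibble.
#' @param tss TSS tibble (contig, position, strand).
#' @param genome A `genome_seq`.
#' @param D Half-width of the profile in bp.
#' @param size_bins List of `c(lo, hi)` length bins; default the four
#'   ladder classes.
#' @return A `tss_profile`: list with `profile` (matrix (2D+1) x bins),
#'   `distance`, `bins`, `n_tss`.
#' @export
tss_profile <- function(fragments, tss, genome, D = 500L,
                        size_bins = lapply(c(60, 90, 120, 150),
                                           function(c) c(c - 5, c + 5))) {
  if (nrow(tss) == 0) {
    warning("no TSS in range; empty profile")
    return(structure(list(profile = matrix(numeric(0), nrow = 2 * D + 1),
                          distance = -D:D, bins = size_bins, n_tss = 0L),
                     class = "tss_profile"))
  }
  bin_names <- vapply(size_bins, function(b) paste0(b[1], "-", b[2]), character(1))
  prof <- matrix(0, nrow = 2 * D + 1, ncol = length(size_bins),
                 dimnames = list(NULL, bin_names))
  for (j in seq_along(size_bins)) {
    cov <- coverage_track(fragments, genome, length_filter = size_bins[[j]])
    for (i in seq_len(nrow(tss))) {
      v <- cov$track[[tss$contig[i]]]
      L <- length(v)
      idx <- (tss$position[i] + (-D:D)) %% L + 1L
      w <- v[idx]
      if (tss$strand[i] == "-") w <- rev(w)
      prof[, j] <- prof[, j] + w
    }
  }
  structure(list(profile = prof / nrow(tss), distance = -D:D,
                 bins = size_bins, n_tss = nrow(tss)),
            class = "tss_profile")
}

#' Tidy a TSS profile into long format
#' @param x A `tss_profile`.
#' @param ... Unused.
#' @return Tibble distance, size_bin, mean_coverage.
#' @method tidy tss_profile
#' @export
tidy.tss_profile <- function(x, ...) {
  tibble::as_tibble(x$profile) |>
    dplyr::mutate(distance = x$distance) |>
    tidyr::pivot_longer(-"distance", names_to = "size_bin",
                        values_to = "mean_coverage")
}

# mean of a track over a 0-based half-open interval, wrapping if needed
interval_mean <- function(v, start, end) {
  L <- length(v)
  idx <- (start + seq_len(end - start) - 1L) %% L + 1L
  mean(v[idx])
}

#' Per-gene GC content and mean occupancy
#'
#' @param genome A `genome_seq`.
#' @param genes Gene interval tibble.
#' @param track A `normalized_track` (or any coverage track).
#' @return List: `genes` (tibble gene, contig, start, end, strand, gc,
#'   mean_occ), `rho`, `p` (Spearman across genes).
#' @export
gene_gc_occupancy <- function(genome, genes, track) {
  keep <- genes$end > genes$start
  genes <- genes[keep, ]
  rows <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    id <- genes$contig[i]
    s <- substr(genome$seqs[[id]], genes$start[i] + 1L, genes$end[i])
    gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
    tibble::tibble(gene = genes$name[i], contig = id, start = genes$start[i],
                   end = genes$end[i], strand = genes$strand[i], gc = gc,
                   mean_occ = interval_mean(track$track[[id]],
                                            genes$start[i], genes$end[i]))
  })
  if (stats::sd(rows$mean_occ) == 0 || stats::sd(rows$gc) == 0) {
    warning("constant occupancy or GC; correlation undefined")
    return(list(genes = rows, rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(rows$gc, rows$mean_occ,
                                         method = "spearman"))
  list(genes = rows, rho = unname(ct$estimate), p = ct$p.value)
}

# replichore-aware codirectionality: replication travels away from the
# origin toward the terminus on each arm
codirectional <- function(position, strand, origin, terminus, L) {
  # on the arm (origin -> terminus going right, modulo L) replication
  # moves in + orientation; on the other arm in - orientation
  d_right <- (position - origin) %% L
  arm_len_right <- (terminus - origin) %% L
  repl_plus <- d_right <= arm_len_right
  (strand == "+") == repl_plus
}

#' Regional transcription and the GC-occupancy relationship
#'
#' Genes (ordered by position) are split by whether transcription is
#' codirectional with replication, then grouped into consecutive
#' `window`-gene blocks per stratum. Each block yields its median
#' expression and its within-block Spearman correlation of gene GC
#' with mean occupancy; the output statistic is the across-block
#' Spearman correlation between the two.
#'
#' @param gene_table `genes` tibble from [gene_gc_occupancy()].
#' @param expression Tibble gene, expression (e.g. mean abundance).
#' @param window Genes per block.
#' @param step Block step in genes (default `window`: non-overlapping).
#' @param origin,terminus Replication origin/terminus coordinates (bp).
#' @param genome_length Contig length L (bp).
#' @param split_by_codirectionality Compute strata separately.
#' @return List: `windows` (tibble stratum, window, n, median_expr,
#'   rho_gc_occ), `across` (tibble stratum, rho, p, n_windows).
#' @export
regional_modulation <- function(gene_table, expression, window = 200L,
                                step = window, origin = 0L, terminus = NULL,
                                genome_length, split_by_codirectionality = TRUE) {
  if (is.null(terminus)) terminus <- genome_length %/% 2L
  tb <- dplyr::inner_join(gene_table, expression, by = "gene") |>
    dplyr::arrange(.data$contig, .data$start)
  tb$codir <- codirectional((tb$start + tb$end) %/% 2L, tb$strand,
                            origin, terminus, genome_length)
  tb$stratum <- if (split_by_codirectionality)
    ifelse(tb$codir, "codirectional", "head-on") else "all"
  win_rows <- purrr::map_dfr(split(tb, tb$stratum), function(sub) {
    n <- nrow(sub)
    if (n < window) return(tibble::tibble())
    starts <- seq(1L, n - window + 1L, by = step)
    purrr::map_dfr(seq_along(starts), function(k) {
      sl <- sub[starts[k]:(starts[k] + window - 1L), ]
      rho <- if (stats::sd(sl$gc) > 0 && stats::sd(sl$mean_occ) > 0)
        stats::cor(sl$gc, sl$mean_occ, method = "spearman") else NA_real_
      tibble::tibble(stratum = sl$stratum[1], window = k, n = nrow(sl),
                     median_expr = stats::median(sl$expression),
                     rho_gc_occ = rho)
    })
  })
  across <- win_rows |>
    dplyr::summarise(
      n_windows = dplyr::n(),
      rho = if (dplyr::n() >= 2)
        suppressWarnings(stats::cor(.data$median_expr, .data$rho_gc_occ,
                                    method = "spearman")) else NA_real_,
      p = if (dplyr::n() >= 2)
        suppressWarnings(stats::cor.test(.data$median_expr, .data$rho_gc_occ,
                                         method = "spearman")$p.value)
      else NA_real_,
      .by = "stratum")
  list(windows = win_rows, across = across)
}

#' Moving-window GC-occupancy correlation along the chromosome
#'
#' Spearman correlation of gene GC with gene occupancy in windows of
#' `span` neighbouring genes advanced by `step` genes, anchored at the
#' window's midpoint coordinate.
#'
#' @param gene_table `genes` tibble from [gene_gc_occupancy()].
#' @param span Genes per window.
#' @param step Step in genes.
#' @return Tibble window, midpoint, rho.
#' @export
moving_gc_occupancy <- function(gene_table, span = 500L, step = 20L) {
  tb <- dplyr::arrange(gene_table, .data$contig, .data$start)
  n <- nrow(tb)
  if (n < span) {
    warning("fewer genes than span; shrinking span to ", n)
    span <- n
  }
  starts <- seq(1L, n - span + 1L, by = step)
  purrr::map_dfr(seq_along(starts), function(k) {
    sl <- tb[starts[k]:(starts[k] + span - 1L), ]
    tibble::tibble(
      window = k,
      midpoint = sl$start[ceiling(span / 2)],
      rho = if (stats::sd(sl$gc) > 0 && stats::sd(sl$mean_occ) > 0)
        stats::cor(sl$gc, sl$mean_occ, method = "spearman") else NA_real_
    )
  })
}

#' Occupancy difference at NAP-bound vs downstream unbound regions
#'
#' For each region bound by a nucleoid-associated protein, Delta =
#' mean occupancy inside the region minus mean occupancy in the
#' unbound gap immediately downstream (increasing coordinate). The
#' last region of a linear contig without a downstream gap is skipped
#' and counted. A two-sided Wilcoxon signed-rank test summarizes the
#' Delta distribution.
#'
#' @param track A `normalized_track`.
#' @param bound Sorted interval tibble of bound regions.
#' @param circular Per-contig circularity (default TRUE).
#' @return List: `deltas` (tibble per region), `statistic`, `p`,
#'   `n_skipped`.
#' @export
nap_delta <- function(track, bound, circular = TRUE) {
  bound <- dplyr::arrange(bound, .data$contig, .data$start)
  n_skipped <- 0L
  rows <- purrr::map_dfr(split(bound, bound$contig), function(sub) {
    id <- sub$contig[1]
    v <- track$track[[id]]
    L <- length(v)
    circ <- if (length(circular) > 1) circular[[id]] else circular
    purrr::map_dfr(seq_len(nrow(sub)), function(i) {
      gap_start <- sub$end[i]
      gap_end <- if (i < nrow(sub)) sub$start[i + 1] else
        if (circ) sub$start[1] + L else L
      if (is.na(gap_end) || gap_end <= gap_start) {
        n_skipped <<- n_skipped + 1L
        return(tibble::tibble())
      }
      ob <- interval_mean(v, sub$start[i], sub$end[i])
      ou <- interval_mean(v, gap_start, gap_end)
      tibble::tibble(contig = id, start = sub$start[i], end = sub$end[i],
                     name = sub$name[i], occ_bound = ob, occ_unbound = ou,
                     delta = ob - ou)
    })
  })
  if (nrow(rows) == 0 || all(rows$delta == 0)) {
    if (nrow(rows)) warning("all deltas zero; signed-rank test undefined")
    return(list(deltas = rows, statistic = NA_real_, p = NA_real_,
                n_skipped = n_skipped))
  }
  wt <- suppressWarnings(stats::wilcox.test(rows$delta, exact = FALSE))
  list(deltas = rows, statistic = unname(wt$statistic), p = wt$p.value,
       n_skipped = n_skipped)
}
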