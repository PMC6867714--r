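#' Low-pass Fourier smoothing of a coverage vector
#'
#' Discrete Fourier transform of the per-base signal, keeping only the
#' lowest `ceiling(kappa * N)` frequency components (with their
#' conjugates, so the result is real); the inverse transform is the
#' smoothed track. `kappa = 1` is the identity; the DC component is
#' always kept, so the mean is preserved.
#'
#' @param v Numeric per-base vector.
#' @param kappa Fraction of low-frequency components to keep, in (0, 1].
#' @return Smoothed numeric vector of the same length.
#' @export
fft_smooth <- function(v, kappa = 0.1) {
  if (kappa <= 0 || kappa > 1) stop("kappa must lie in (0, 1]")
  N <- length(v)
  m <- ceiling(kappa * N)
  if (m >= N) return(v)
  f <- stats::fft(v)
  keep <- logical(N)
  keep[seq_len(m)] <- TRUE                      # DC + lowest m-1 positive freqs
  if (m > 1) keep[N - seq_len(m - 1) + 1L] <- TRUE  # conjugates
  f[!keep] <- 0
  Re(stats::fft(f, inverse = TRUE)) / N
}

#' Oligomer rank of a footprint width
#'
#' A width within +/- 5 bp of a model length `60 + 30 * (r - 1)`
#' (ranks 1..4) is assigned that rank; anything else gets `NA`.
#'
#' @param width Footprint width(s) in bp.
#' @param f0,step,r_max,tol Model parameters.
#' @return Integer rank vector with `NA` for unassignable widths.
#' @export
assign_rank <- function(width, f0 = 60L, step = 30L, r_max = 4L, tol = 5L) {
  stopifnot(all(width >= 1))
  model <- oligomer_length(seq_len(r_max), f0, step)
  vapply(width, function(w) {
    d <- abs(model - w)
    j <- which.min(d)
    if (d[j] <= tol) j else NA_integer_
  }, integer(1))
}

#' Call footprints on a smoothed coverage track
#'
#' Local maxima of the smoothed signal above the `q`-quantile of the
#' track become candidate calls. Neighbouring maxima whose separating
#' dip stays above `merge_frac` of the lower peak are treated as one
#' footprint (such shallow dips are filter ripple, not separate
#' particles) and collapse onto the higher maximum; the surviving dips
#' bound each call. A call's width is the extent above half the peak
#' height inside its dip bounds, its center (dyad) the midpoint of
#' that extent, and its score combines normalized height with
#' closeness of the width to the nearest oligomer model length.
#' Remaining overlaps are resolved greedily by descending score (ties
#' to the leftmost center).
#'
#' @param smoothed Numeric smoothed per-base vector (one contig).
#' @param q Threshold quantile in `[0, 1]`.
#' @param contig Contig id recorded in the calls.
#' @param merge_frac Dip-depth fraction below which two maxima merge.
#' @param f0,step,r_max Oligomer model parameters for rank assignment.
#' @return Tibble contig, start, end, center, width, height, score, rank.
#' @export
call_peaks <- function(smoothed, q = 0.3, contig = "chr", merge_frac = 0.85,
                       f0 = 60L, step = 30L, r_max = 4L) {
  v <- smoothed
  N <- length(v)
  empty <- tibble::tibble(contig = character(), start = integer(),
                          end = integer(), center = integer(),
                          width = integer(), height = numeric(),
                          score = numeric(), rank = integer())
  thr <- stats::quantile(v, q, names = FALSE)
  # local maxima on run-length-compressed values (leftmost of plateaus)
  r <- rle(v)
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1], -Inf)
  mx <- run_start[r$values > left & r$values > right]
  mx <- mx[v[mx] > thr]
  if (length(mx) == 0) return(empty)
  # single pass: merge maxima separated by shallow dips, record the
  # surviving dip positions as call boundaries
  keep <- mx[1]
  dips <- integer(0)
  for (i in seq_along(mx)[-1]) {
    last <- keep[length(keep)]
    seg <- v[last:mx[i]]
    dval <- min(seg)
    dpos <- last + which.min(seg) - 1L
    if (dval > merge_frac * min(v[last], v[mx[i]])) {
      if (v[mx[i]] > v[last]) keep[length(keep)] <- mx[i]
    } else {
      keep <- c(keep, mx[i])
      dips <- c(dips, dpos)
    }
  }
  bounds <- c(1L, dips, N)
  model <- oligomer_length(seq_len(r_max), f0, step)
  vmax <- max(v)
  calls <- purrr::map_dfr(seq_along(keep), function(i) {
    p <- keep[i]
    h <- v[p]
    half <- h / 2
    lb <- bounds[i]
    rb <- bounds[i + 1]
    # stop one base short of the dip so neighbouring calls cannot
    # collide on the shared boundary
    l <- p
    while (l - 1 > lb && v[l - 1] >= half) l <- l - 1
    rr <- p
    while (rr + 1 < rb && v[rr + 1] >= half) rr <- rr + 1
    width <- rr - l + 1L
    closeness <- max(0, 1 - min(abs(model - width)) / step)
    # dyad = midpoint of the half-height extent: robust for the
    # flat-topped protection footprints
    tibble::tibble(start = l - 1L, end = rr, center = (l + rr) %/% 2L - 1L,
                   width = width, height = h,
                   score = (h / vmax) * closeness)
  })
  # greedy non-overlap by descending score, leftmost center on ties
  calls <- dplyr::arrange(calls, dplyr::desc(.data$score), .data$center)
  taken <- logical(N)
  sel <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    idx <- (calls$start[i] + 1L):calls$end[i]
    if (!any(taken[idx])) {
      taken[idx] <- TRUE
      sel[i] <- TRUE
    }
  }
  calls <- calls[sel, ]
  calls$rank <- assign_rank(calls$width, f0, step, r_max)
  calls$contig <- contig
  dplyr::arrange(calls[c("contig", "start", "end", "center", "width",
                         "height", "score", "rank")], .data$start)
}

#' Flank AT composition vs oligomer extension
#'
#' Tests whether tetramers extend into larger oligomers preferentially
#' when their flanks are GC-rich. Each ranked call contributes one
#' tetramer record. For an unextended (rank 1) call the tetramer's
#' flanks are the `flank` bp immediately outside each call edge — the
#' sequence that blocked (or never hosted) an extension. For an
#' extended (rank >= 2) call the flanks at the moment of the extension
#' decision lie inside the final footprint, so the outer `flank` bp
#' at each end of the call are used. Flank AT fractions are compared
#' between the two groups with a two-sided rank-sum test; extension
#' into AT-rich flanks should be rarer, so extended calls are expected
#' to show lower flank AT. Flanks clipped by a linear contig end
#' exclude the call.
#'
#' @param calls Call tibble from [call_peaks()] (rank assigned).
#' @param genome A `genome_seq`.
#' @param flank Flank width in bp.
#' @return List: `stats` (tibble per call: flank_at_left/right/mean,
#'   extended), `test` (list statistic, p), `n_clipped`.
#' @export
extension_vs_flank <- function(calls, genome, flank = 30L) {
  calls <- calls[!is.na(calls$rank), ]
  n_clipped <- 0L
  is_at_by_contig <- lapply(genome$seqs, function(s)
    as.numeric(strsplit(s, "")[[1]] %in% c("A", "T")))
  rows <- purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    id <- calls$contig[i]
    is_at <- is_at_by_contig[[id]]
    L <- length(is_at)
    circ <- genome$circular[[id]]
    extended <- calls$rank[i] >= 2L
    if (extended) {
      lf_s <- calls$start[i]
      rf_s <- calls$end[i] - flank
    } else {
      lf_s <- calls$start[i] - flank
      rf_s <- calls$end[i]
    }
    if (!circ && (lf_s < 0 || rf_s + flank > L)) {
      n_clipped <<- n_clipped + 1L
      return(tibble::tibble())
    }
    at_of <- function(s) mean(is_at[(s + seq_len(flank) - 1L) %% L + 1L])
    la <- at_of(lf_s)
    ra <- at_of(rf_s)
    tibble::tibble(contig = id, center = calls$center[i],
                   rank = calls$rank[i], extended = extended,
                   flank_at_left = la, flank_at_right = ra,
                   flank_at_mean = (la + ra) / 2)
  })
  if (nrow(rows) == 0) {
    warning("no usable calls (all flanks clipped)")
    return(list(stats = rows, test = list(statistic = NA_real_, p = NA_real_),
                n_clipped = n_clipped))
  }
  ext <- rows$flank_at_mean[rows$extended]
  une <- rows$flank_at_mean[!rows$extended]
  test <- if (length(ext) >= 5 && length(une) >= 5) {
    wt <- suppressWarnings(stats::wilcox.test(ext, une))
    list(statistic = unname(wt$statistic), p = wt$p.value)
  } else {
    list(statistic = NA_real_, p = NA_real_)
  }
  list(stats = rows, test = test, n_clipped = n_clipped)
}

#' Peaks of a fragment-length histogram
#'
#' Builds a 1 bp histogram of fragment lengths, smooths it with a
#' 3 bp moving average and calls local maxima whose smoothed count
#' exceeds `ratio` times the local background (running median over
#' +/- `bg_halfwidth` bp). Used to detect the oligomer ladder.
#'
#' @param lengths Integer fragment lengths.
#' @param range Length range considered (bp).
#' @param smooth Moving-average width (bp, odd).
#' @param ratio Peak-to-background calling ratio.
#' @param bg_halfwidth Background window half-width (bp).
#' @param min_sep Peaks closer than this merge onto the higher one
#'   (a sparse rung can split into twin maxima under counting noise).
#' @return Tibble length, count, background.
#' @export
length_peaks <- function(lengths, range = c(20L, 160L), smooth = 3L,
                         ratio = 1.5, bg_halfwidth = 15L, min_sep = 10L) {
  lens <- range[1]:range[2]
  counts <- tabulate(factor(lengths, levels = lens), nbins = length(lens))
  h <- (smooth - 1L) %/% 2L
  sm <- stats::filter(counts, rep(1 / smooth, smooth), sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  sm <- as.numeric(sm)
  n <- length(sm)
  bg <- vapply(seq_len(n), function(i) {
    idx <- max(1, i - bg_halfwidth):min(n, i + bg_halfwidth)
    stats::median(sm[idx])
  }, numeric(1))
  is_max <- sm > c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf)
  # the first and last bins only see a one-sided background and collect
  # clipping pile-ups, so they cannot be called as rungs
  is_max[c(1L, n)] <- FALSE
  peak <- is_max & sm > ratio * bg & sm > 0
  out <- tibble::tibble(length = lens[peak], count = sm[peak],
                        background = bg[peak])
  # consolidate split rungs: among peaks closer than min_sep keep the higher
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) {
    for (i in seq_len(nrow(out) - 1)) {
      if (!keep[i]) next
      j <- i + 1
      if (out$length[j] - out$length[i] < min_sep) {
        if (out$count[j] > out$count[i]) keep[i] <- FALSE else keep[j] <- FALSE
      }
    }
  }
  out[keep, ]
}

#' Histone-specific ladder peaks
#'
#' Length-histogram peaks of the histone-strain digest that have no
#' counterpart within `match_tol` bp in the empty-vector control;
#' their mean consecutive spacing and smallest location summarize the
#' oligomer ladder.
#'
#' @param strain_lengths,ev_lengths Fragment lengths of the two libraries.
#' @param match_tol EV-coincidence tolerance (bp).
#' @param ... Passed to [length_peaks()].
#' @return List: `peaks` (strain-specific peak tibble), `ev_peaks`,
#'   `mean_spacing` (bp), `first_rung` (bp).
#' @export
ladder_peaks <- function(strain_lengths, ev_lengths, match_tol = 5L, ...) {
  ps <- length_peaks(strain_lengths, ...)
  pe <- length_peaks(ev_lengths, ...)
  specific <- ps[vapply(ps$length, function(l)
    !any(abs(pe$length - l) <= match_tol), logical(1)), ]
  spacing <- if (nrow(specific) >= 2) mean(diff(specific$length)) else NA_real_
  list(peaks = specific, ev_peaks = pe, mean_spacing = spacing,
       first_rung = if (nrow(specific)) min(specific$length) else NA_integer_)
}

#' Match footprint calls to known placements
#'
#' Each placement is matched to the closest call center within
#' `tol` bp of its own midpoint (one call per placement, greedy by
#' distance). Used for recovery evaluation against simulated truth.
#'
#' @param calls Call tibble from [call_peaks()].
#' @param placements Placement tibble (start, end, rank).
#' @param tol Matching tolerance in bp.
#' @return Tibble per placement: true_center, true_rank, matched,
#'   call_center, call_rank, dist.
#' @export
match_calls <- function(calls, placements, tol = 5L) {
  tc <- (placements$start + placements$end) %/% 2L
  cc <- calls$center
  purrr::map_dfr(seq_along(tc), function(i) {
    d <- abs(cc - tc[i])
    j <- if (length(d)) which.min(d) else NA_integer_
    hit <- length(d) > 0 && d[j] <= tol
    tibble::tibble(true_center = tc[i], true_rank = placements$rank[i],
                   matched = hit,
                   call_center = if (hit) cc[j] else NA_integer_,
                   call_rank = if (hit) calls$rank[j] else NA_integer_,
                   dist = if (hit) d[j] else NA_integer_)
  })
}
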