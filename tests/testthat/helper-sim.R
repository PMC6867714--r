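# shared simulated fixtures, built once per test run

tiny_study_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(tiny_sim_config(seed = 42L))
    cache
  }
})

# the reference study conditions (200 kb defaults), plus the smoothed
# coverage and footprint calls derived from them
default_study_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- simulate_study(sim_config(seed = 1L))
      cov <- coverage_track(st$fragments, st$genome, label = "strain")
      sm <- fft_smooth(cov$track$chrS)
      calls <- call_peaks(sm, contig = "chrS")
      cache <<- c(st, list(cov = cov, smoothed = sm, calls = calls))
    }
    cache
  }
})

# fraction of simulation seeds in which the down-regulated group shows
# higher TSS +/- 25 bp occupancy than the up-regulated group
repression_sign_stability_cached <- local({
  cache <- NULL
  function(n_seeds = 20L) {
    if (!is.null(cache)) return(cache)
    correct <- 0L
    for (sd in seq_len(n_seeds)) {
      cfg <- sim_config(seed = sd)
      st <- simulate_study(cfg)
      ev_cov <- coverage_track(st$ev_fragments, st$genome)
      tracks <- list(pooled = normalize_track(
        coverage_track(st$fragments, st$genome), ev_cov))
      gr <- exclusion_filter(st$expression$de_binding,
                             st$expression$de_nonbinding)
      wo <- window_occupancy(gr, tracks, st$tss, st$promoters, st$genes,
                             start_codon_offset = cfg$utr_length)
      t_tss <- wo$tests[wo$tests$window == "tss_pm25", ]
      if (isTRUE(t_tss$mean_down > t_tss$mean_up)) correct <- correct + 1L
    }
    cache <<- correct / n_seeds
    cache
  }
})

random_genome <- function(L, seed = 1, gc = 0.5, circular = TRUE) {
  withr::local_seed(seed)
  s <- paste(sample(c("A", "T", "G", "C"), L, replace = TRUE,
                    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
             collapse = "")
  genome_seq(c(chr = s), circular = circular)
}

random_fragments <- function(n, L, seed = 1, min_len = 20, max_len = 160) {
  withr::local_seed(seed)
  s <- sample.int(L, n, replace = TRUE) - 1L
  len <- if (min_len == max_len) rep(min_len, n) else
    sample(min_len:max_len, n, replace = TRUE)
  tibble::tibble(contig = "chr", start = s, end = s + len, strand = ".",
                 name = ".", score = 0, length = len)
}

# brute-force per-base coverage oracle (wrapping, O(n*len))
naive_coverage <- function(fragments, L) {
  v <- numeric(L)
  for (i in seq_len(nrow(fragments))) {
    idx <- (fragments$start[i]:(fragments$end[i] - 1)) %% L + 1
    v[idx] <- v[idx] + 1
  }
  v
}

# brute-force k-mer window counter
naive_kmer_counts <- function(seq_str, center0, window, k) {
  h <- (window - 1) %/% 2
  L <- nchar(seq_str)
  idx <- (center0 - h):(center0 + h) %% L
  win <- paste(strsplit(seq_str, "")[[1]][idx + 1], collapse = "")
  km <- substring(win, 1:(window - k + 1), k:window)
  table(factor(km, levels = oligofoot:::all_kmers(k)))
}
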