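test_that("fragment lengths map to ladder size classes with +/-5 bp tolerance", {
  expect_equal(assign_size_class(63), 60L)
  expect_true(is.na(assign_size_class(66)))
  expect_equal(assign_size_class(145), 150L)
  expect_equal(assign_size_class(c(55, 65, 90, 120, 155)),
               c(60L, 60L, 90L, 120L, 150L))
  expect_true(is.na(assign_size_class(40)))
})

make_track <- function(v, n = 10L, label = "t") {
  structure(list(track = list(chr = v), n_fragments = n,
                 length_filter = NULL, label = label),
            class = "coverage_track")
}

test_that("EV normalization divides by pseudocounted control coverage", {
  s <- make_track(c(4, 2))
  e <- make_track(c(1, 0))
  o <- normalize_track(s, e)
  expect_equal(o$track$chr, c(2, 2))

  e0 <- make_track(c(0, 0))
  expect_equal(normalize_track(s, e0)$track$chr, c(4, 2))

  # uniform EV: a monotone transform preserving rank order
  s2 <- make_track(c(5, 1, 3, 2))
  ek <- make_track(rep(3, 4))
  o2 <- normalize_track(s2, ek)
  expect_equal(o2$track$chr, c(5, 1, 3, 2) / 4)
  expect_equal(order(o2$track$chr), order(s2$track$chr))

  # library scaling to fragments-per-million
  o3 <- normalize_track(make_track(c(4, 2), n = 2L),
                        make_track(c(1, 0), n = 4L), scale_libraries = TRUE)
  expect_equal(o3$track$chr, c(4, 2) * 5e5 / (c(1, 0) * 2.5e5 + 1))

  expect_error(normalize_track(s, structure(list(track = list(x = 1)),
                                            class = "coverage_track")),
               "different contigs")
})

test_that("window means equal brute-force slice means", {
  v <- c(rep(2, 120))
  w <- windowed_means(make_track(v), 60, 30, circular = FALSE)
  expect_equal(nrow(w), 3L)
  expect_true(all(w$mean_value == 2))

  withr::local_seed(21)
  v2 <- rnorm(500)
  w2 <- windowed_means(make_track(v2), 60, 30, circular = FALSE)
  manual <- vapply(w2$start, function(s) mean(v2[(s + 1):(s + 60)]), numeric(1))
  expect_equal(w2$mean_value, manual)

  # circular windows wrap across the origin
  w3 <- windowed_means(make_track(v2), 60, 30, circular = TRUE)
  expect_equal(nrow(w3), ceiling(500 / 30))
  last <- w3[nrow(w3), ]
  expect_equal(last$mean_value,
               mean(v2[c((last$start + 1):500, 1:(last$end - 500))]))
})

test_that("replicate correlation works on proportions of total fragments", {
  st <- tiny_study_cached()
  rc <- replicate_correlation(st$fragments, st$fragments, st$genome)
  expect_equal(rc$rho, 1)

  # subsampled halves of one digest are strongly concordant, and
  # concordance grows with depth
  std <- default_study_cached()
  withr::local_seed(31)
  n <- nrow(std$fragments)
  idx <- sample.int(n, n %/% 2)
  rc2 <- replicate_correlation(std$fragments[idx, ], std$fragments[-idx, ],
                               std$genome)
  expect_gt(rc2$rho, 0.7)
  cfg <- sim_config(seed = 1L)
  deep <- simulate_digest(list(placements = std$placements),
                          list(genome = std$genome), cfg,
                          n_fragments = 2L * nrow(std$fragments))
  idx2 <- sample.int(nrow(deep), nrow(deep) %/% 2)
  rc3 <- replicate_correlation(deep[idx2, ], deep[-idx2, ], std$genome)
  expect_gt(rc3$rho, 0.8)
  expect_gt(rc3$rho, rc2$rho)

  g <- genome_seq(c(chr = strrep("A", 200)))
  fr <- tibble::tibble(contig = "chr", start = 0L, end = 200L, strand = ".",
                       name = ".", score = 0, length = 200L)
  expect_warning(rc3 <- replicate_correlation(fr, fr, g), "zero-variance")
  expect_true(is.na(rc3$rho))
})

test_that("TSS profiles are strand-oriented and place fragments exactly", {
  g <- random_genome(2000, seed = 41)
  tss <- tibble::tibble(tss_id = "t", contig = "chr", position = 1000L,
                        strand = "+", reads = 1L, gene = "g")
  fr <- tibble::tibble(contig = "chr", start = 1010L, end = 1070L,
                       strand = ".", name = ".", score = 0, length = 60L)
  pr <- tss_profile(fr, tss, g, D = 100, size_bins = list(c(55, 65)))
  nz <- which(pr$profile[, 1] > 0)
  expect_equal(pr$distance[nz], 10:69)

  # minus-strand TSS mirrors the distances
  tss$strand <- "-"
  prm <- tss_profile(fr, tss, g, D = 100, size_bins = list(c(55, 65)))
  expect_equal(prm$distance[prm$profile[, 1] > 0], -69:-10)

  expect_warning(tss_profile(fr, tss[0, ], g, D = 10), "no TSS")
})

test_that("synthetic promoters are depleted of occupancy around the TSS", {
  st <- default_study_cached()
  ev_cov <- coverage_track(st$ev_fragments, st$genome)
  pooled <- normalize_track(st$cov, ev_cov)
  v <- pooled$track$chrS
  L <- length(v)
  tss_occ <- vapply(st$tss$position, function(p)
    mean(v[(p + (-50:50)) %% L + 1]), numeric(1))
  expect_lt(mean(tss_occ), mean(v))
})

test_that("per-gene GC/occupancy table covers every gene and flags constants", {
  st <- tiny_study_cached()
  ev_cov <- coverage_track(st$ev_fragments, st$genome)
  tr <- normalize_track(coverage_track(st$fragments, st$genome), ev_cov)
  gg <- gene_gc_occupancy(st$genome, st$genes, tr)
  expect_equal(nrow(gg$genes), nrow(st$genes))
  expect_true(all(gg$genes$gc >= 0 & gg$genes$gc <= 1))

  flat <- structure(list(track = list(chrS = rep(
    1, contig_lengths(st$genome)[[1]]))), class = "coverage_track")
  expect_warning(g2 <- gene_gc_occupancy(st$genome, st$genes, flat),
                 "constant")
  expect_true(is.na(g2$rho))
})

test_that("regional windows stratify by codirectionality and shuffle to null", {
  st <- default_study_cached()
  ev_cov <- coverage_track(st$ev_fragments, st$genome)
  tr <- normalize_track(st$cov, ev_cov)
  gg <- gene_gc_occupancy(st$genome, st$genes, tr)$genes
  withr::local_seed(51)
  expr <- tibble::tibble(gene = gg$gene, expression = rnorm(nrow(gg)))
  rm <- regional_modulation(gg, expr, window = 10, step = 10,
                            origin = 0, genome_length = 200000L)
  # stratum labels partition the genes
  expect_equal(sum(rm$windows$n), nrow(rm$windows) * 10)
  expect_true(all(rm$windows$stratum %in% c("codirectional", "head-on")))
  # shuffled expression: across-window correlation near zero
  ok <- rm$across$n_windows >= 4
  expect_true(all(abs(rm$across$rho[ok]) < 0.75))

  pooled <- regional_modulation(gg, expr, window = 10, step = 10, origin = 0,
                                genome_length = 200000L,
                                split_by_codirectionality = FALSE)
  expect_equal(unique(pooled$windows$stratum), "all")
})

test_that("moving-window correlations match their direct recomputation", {
  st <- tiny_study_cached()
  ev_cov <- coverage_track(st$ev_fragments, st$genome)
  tr <- normalize_track(coverage_track(st$fragments, st$genome), ev_cov)
  gg <- gene_gc_occupancy(st$genome, st$genes, tr)$genes
  mv <- moving_gc_occupancy(gg, span = 8L, step = 3L)
  n <- nrow(gg)
  expect_equal(nrow(mv), floor((n - 8) / 3) + 1)
  ordered <- gg[order(gg$start), ]
  for (k in seq_len(nrow(mv))) {
    sl <- ordered[(1 + (k - 1) * 3):((k - 1) * 3 + 8), ]
    expect_equal(mv$rho[k], cor(sl$gc, sl$mean_occ, method = "spearman"))
  }
  expect_warning(moving_gc_occupancy(gg, span = 1000L), "shrinking")
})

test_that("NAP deltas compare bound regions with the downstream gap", {
  v <- c(rep(2, 50), rep(1.5, 30), rep(3, 20))
  tr <- make_track(v)
  bound <- interval_tbl("chr", 0L, 50L, name = "nap1")
  nd <- nap_delta(tr, bound, circular = FALSE)
  # downstream gap is [50, 100): mean of the remaining track
  expect_equal(nd$deltas$delta, 2 - mean(v[51:100]))

  # uniform track: all deltas zero, test flagged undefined
  expect_warning(nd0 <- nap_delta(make_track(rep(1, 100)), bound,
                                  circular = FALSE), "deltas zero")
  expect_true(is.na(nd0$p))

  # last region on a linear contig without downstream gap is skipped
  b2 <- interval_tbl("chr", c(0L, 80L), c(50L, 100L), name = c("a", "b"))
  nd2 <- nap_delta(tr, b2, circular = FALSE)
  expect_equal(nrow(nd2$deltas), 1L)
  expect_equal(nd2$n_skipped, 1L)

  # oracle on a random instance (circular: wrap-around gap for the last)
  withr::local_seed(61)
  vr <- runif(1000)
  starts <- c(100L, 400L, 700L)
  ends <- c(200L, 500L, 800L)
  ndr <- nap_delta(make_track(vr), interval_tbl("chr", starts, ends,
                                                name = letters[1:3]),
                   circular = TRUE)
  manual <- c(mean(vr[101:200]) - mean(vr[201:400]),
              mean(vr[401:500]) - mean(vr[501:700]),
              mean(vr[701:800]) - mean(vr[c(801:1000, 1:100)]))
  expect_equal(ndr$deltas$delta, manual)
})

test_that("rank statistics are invariant to monotone track rescaling", {
  st <- tiny_study_cached()
  ev_cov <- coverage_track(st$ev_fragments, st$genome)
  tr <- normalize_track(coverage_track(st$fragments, st$genome), ev_cov)
  gg1 <- gene_gc_occupancy(st$genome, st$genes, tr)
  tr2 <- tr
  tr2$track$chrS <- tr$track$chrS * 7 + 2
  gg2 <- gene_gc_occupancy(st$genome, st$genes, tr2)
  expect_equal(gg1$rho, gg2$rho)
})
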