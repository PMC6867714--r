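test_that("k-mer features count sliding windows exactly", {
  g <- genome_seq(c(chr = strrep("ACGT", 50)), circular = TRUE)
  f <- kmer_features(g, positions = 100L, k_set = 1L, window = 61L)
  expect_equal(unname(f[1, c("A", "C", "G", "T")]), c(15, 15, 16, 15))
  expect_equal(sum(f[1, ]), 61)

  f4 <- kmer_features(g, positions = c(50L, 100L), k_set = 1:4, window = 61L)
  expect_equal(ncol(f4), 340L)
  # sum over k-mers of size k is window - k + 1
  for (k in 1:4) {
    cols <- nchar(colnames(f4)) == k
    expect_true(all(rowSums(f4[, cols]) == 61 - k + 1))
  }

  hp <- genome_seq(c(chr = strrep("A", 200)), circular = TRUE)
  fh <- kmer_features(hp, 100L, k_set = 2L, window = 31L)
  expect_equal(unname(fh[1, "AA"]), 30)

  expect_error(kmer_features(g, 10L, window = 60L), "odd")
})

test_that("k-mer features equal a naive substring-count oracle", {
  g <- random_genome(5000, seed = 101)
  pos <- c(30L, 777L, 2500L, 4990L)
  for (k in c(1L, 2L, 3L)) {
    f <- kmer_features(g, pos, k_set = k, window = 61L)
    for (i in seq_along(pos)) {
      oracle <- naive_kmer_counts(g$seqs[[1]], pos[i], 61L, k)
      expect_equal(unname(f[i, ]), as.numeric(oracle))
    }
  }
})

test_that("windows containing N are excluded and reported", {
  s <- strrep("ACGT", 100)
  substr(s, 201, 201) <- "N"
  g <- genome_seq(c(chr = s), circular = TRUE)
  f <- kmer_features(g, positions = c(100L, 200L, 300L), k_set = 1L,
                     window = 21L)
  expect_equal(nrow(f), 2L)
  expect_equal(attr(f, "excluded"), 200L)
})

test_that("the training prefix follows the one-sixth convention", {
  expect_identical(train_prefix_end(4641652L), 773608L)
  expect_identical(train_prefix_end(200000L), 33333L)
})

test_that("an infinite penalty zeroes all coefficients", {
  st <- tiny_study_cached()
  g <- st$genome
  pos <- seq(0L, 19990L, by = 10L)
  feats <- kmer_features(g, pos, k_set = 1:2, window = 61L)
  withr::local_seed(111)
  resp <- rnorm(nrow(feats))
  m <- fit_sparse(feats, resp, 20000L, lambda = 1e9)
  expect_true(all(tidy(m)$estimate == 0))
  tr_mean <- mean(resp[as.integer(rownames(feats)) < train_prefix_end(20000L)])
  expect_equal(m$intercept, tr_mean, tolerance = 1e-6)
  pred <- predict(m, feats)
  expect_true(all(abs(pred - tr_mean) < 1e-6))

  expect_error(fit_sparse(feats, rep(1, nrow(feats)), 20000L), "constant")
})

test_that("a noiseless planted k-mer response is recovered exactly", {
  g <- random_genome(50000, seed = 121)
  feats <- kmer_features(g, seq(0L, 49990L, by = 10L), k_set = 1:4,
                         window = 61L)
  beta <- stats::setNames(numeric(ncol(feats)), colnames(feats))
  planted <- c("GC", "AT", "CCG", "GGCC", "A")
  beta[planted] <- c(2, -1.5, 3, 4, -0.5)
  resp <- as.numeric(feats %*% beta) + 10
  m <- fit_sparse(feats, resp, 50000L)
  ev <- evaluate_model(m, feats, resp, "test")
  expect_gt(ev$rho, 0.99)
  nz <- tidy(m)$term[tidy(m)$estimate != 0]
  expect_gte(length(nz), 5L)
  expect_true(all(planted %in% nz))
})

test_that("sparsity is non-increasing along the regularization path", {
  g <- random_genome(20000, seed = 122)
  feats <- kmer_features(g, seq(0L, 19990L, by = 20L), k_set = 1:2,
                         window = 61L)
  withr::local_seed(123)
  resp <- as.numeric(feats[, "G"]) + rnorm(nrow(feats), 0, 0.5)
  m <- fit_sparse(feats, resp, 20000L)
  df <- m$fit$df
  lam <- m$fit$lambda
  expect_true(all(diff(df[order(-lam)]) >= 0))
})

test_that("model evaluation enforces the train/test split and nulls out", {
  st <- tiny_study_cached()
  ev_cov <- coverage_track(st$ev_fragments, st$genome)
  tr <- normalize_track(coverage_track(st$fragments, st$genome), ev_cov)
  pos <- seq(0L, 19990L, by = 2L)
  feats <- kmer_features(st$genome, pos, k_set = 1:2, window = 61L)
  resp <- tr$track$chrS[as.integer(rownames(feats)) + 1L]
  m <- fit_sparse(feats, resp, 20000L)
  etr <- evaluate_model(m, feats, resp, "train")
  expect_identical(etr$region, "train")

  withr::local_seed(131)
  shuffled <- sample(resp)
  m0 <- fit_sparse(feats, shuffled, 20000L)
  e0 <- evaluate_model(m0, feats, shuffled, "test")
  expect_lt(abs(e0$rho), 0.05)
})

test_that("G and C rank among the top univariate k-mers under GC preference", {
  st <- default_study_cached()
  ev_cov <- coverage_track(st$ev_fragments, st$genome)
  pooled <- normalize_track(st$cov, ev_cov)
  pos <- seq(0L, 199990L, by = 20L)
  feats <- kmer_features(st$genome, pos, k_set = 1L, window = 121L)
  resp <- pooled$track$chrS[as.integer(rownames(feats)) + 1L]
  rr <- rank(resp)
  uni <- sort(stats::cor(apply(feats, 2, rank), rr)[, 1], decreasing = TRUE)
  expect_true(all(c("G", "C") %in% names(uni)[1:2]))
  expect_true(all(c("A", "T") %in% names(uni)[3:4]))
  expect_gt(uni[["G"]], 0)
  expect_lt(uni[["T"]], 0)
})

test_that("read-internal profiles are flat on unstructured data", {
  g <- random_genome(50000, seed = 141, gc = 0.5)
  withr::local_seed(142)
  s <- sample.int(49000, 10000, replace = TRUE) - 1L
  fr <- tibble::tibble(contig = "chr", start = s, end = s + 60L,
                       strand = ".", name = ".", score = 0, length = 60L)
  pr <- read_internal_profile(fr, g, 60L)
  expect_lt(max(abs(pr$enrichment - 1)), 0.1)
  expect_lt(pr$symmetry_score, 0.1)
  expect_equal(rowSums(pr$freq), rep(1, 60))
})

test_that("only fragments of the exact stated length contribute", {
  g <- random_genome(1000, seed = 143)
  fr <- tibble::tibble(contig = "chr", start = c(10L, 100L, 200L),
                       end = c(70L, 161L, 260L), strand = ".", name = ".",
                       score = 0, length = c(60L, 61L, 60L))
  suppressWarnings(pr <- read_internal_profile(fr, g, 60L))
  expect_equal(pr$n_fragments, 2L)
  expect_warning(read_internal_profile(fr[fr$length == 61L, ], g, 60L),
                 "no fragments")
})

test_that("a reverse-complement-closed fragment set is dyad-symmetric", {
  g <- random_genome(10000, seed = 144)
  withr::local_seed(145)
  s <- sample.int(9000, 2000, replace = TRUE) - 1L
  fr <- tibble::tibble(contig = "chr", start = s, end = s + 60L,
                       strand = ".", name = ".", score = 0, length = 60L)
  # close the set under reverse complement by mirroring the genome:
  # append the reverse complement and the mirrored fragment positions
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g$seqs[[1]])))
  g2 <- genome_seq(c(chr = paste0(g$seqs[[1]], rc)), circular = FALSE)
  s_rc <- 20000L - (s + 60L)
  fr2 <- tibble::tibble(contig = "chr", start = c(s, 10000L + s_rc),
                        end = c(s, 10000L + s_rc) + 60L, strand = ".",
                        name = ".", score = 0, length = 60L)
  pr <- read_internal_profile(fr2, g2, 60L)
  # sampling-noise bound: E cells have sd ~ sqrt(3/n) at background 0.25,
  # so a perfectly symmetric profile has mean |E - E_mirror| ~ 2*sd/sqrt(pi)
  noise_bound <- 2 * (2 * sqrt(3 / pr$n_fragments) / sqrt(pi))
  expect_lt(pr$symmetry_score, noise_bound)
})
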