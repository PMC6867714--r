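test_that("oligomer model lengths follow the tetramer-plus-dimer-step rule", {
  expect_equal(oligomer_length(1:4), c(60, 90, 120, 150))
})

test_that("genome simulation is deterministic and plants AT-rich promoters", {
  cfg <- tiny_sim_config(seed = 5L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome$seqs, b$genome$seqs)
  expect_identical(a$genes, b$genes)

  gc_of <- function(g, tb) {
    vapply(seq_len(nrow(tb)), function(i) {
      s <- substr(g$seqs[[tb$contig[i]]], tb$start[i] + 1, tb$end[i])
      mean(strsplit(s, "")[[1]] %in% c("G", "C"))
    }, numeric(1))
  }
  cfg100 <- sim_config(genome_length = 150000L, n_genes = 100L, seed = 5L)
  sg <- simulate_genome(cfg100)
  prom_gc <- gc_of(sg$genome, sg$promoters)
  gene_gc <- gc_of(sg$genome, sg$genes)
  expect_lt(wilcox.test(prom_gc, gene_gc, alternative = "less")$p.value, 0.01)

  # degenerate config: promoter GC equals background within binomial error
  cfg_eq <- sim_config(genome_length = 50000L, n_genes = 20L,
                       gc_promoter = 0.499, gc_background = 0.5, seed = 6L)
  sg_eq <- simulate_genome(cfg_eq)
  pg <- gc_of(sg_eq$genome, sg_eq$promoters)
  expect_gt(t.test(pg, mu = 0.5)$p.value, 0.001)

  expect_error(simulate_genome(sim_config(genome_length = 2000L)), "fit")
})

test_that("placements never overlap and have model-length footprints", {
  st <- tiny_study_cached()
  pl <- st$placements
  len <- pl$end - pl$start
  expect_true(all(len %in% oligomer_length(1:4)))
  expect_equal(len, oligomer_length(pl$rank))
  # non-overlap on the circle
  L <- contig_lengths(st$genome)[[1]]
  occ <- numeric(L)
  for (i in seq_len(nrow(pl))) {
    idx <- (pl$start[i]:(pl$end[i] - 1)) %% L + 1
    occ[idx] <- occ[idx] + 1
  }
  expect_lte(max(occ), 1)
  expect_equal(sum(occ), sum(len))
})

test_that("nucleation follows the GC weight and goes flat when it is zero", {
  cfg0 <- sim_config(genome_length = 60000L, n_genes = 30L, gene_length = 600L,
                     beta_gc = 0, seed = 11L)
  sg <- simulate_genome(cfg0)
  sp <- simulate_placements(sg, cfg0)
  seqv <- strsplit(sg$genome$seqs[[1]], "")[[1]]
  occ <- sp$occupancy[[1]]
  w <- seq(1, length(occ) - 200, by = 200)
  wocc <- vapply(w, function(s) mean(occ[s:(s + 199)]), numeric(1))
  wgc <- vapply(w, function(s) mean(seqv[s:(s + 199)] %in% c("G", "C")),
                numeric(1))
  expect_lt(abs(cor(wocc, wgc, method = "spearman")), 0.15)

  # default weight: occupancy tracks GC at the reference conditions
  st <- default_study_cached()
  seqv1 <- strsplit(st$genome$seqs[[1]], "")[[1]]
  occ1 <- st$occupancy[[1]]
  w1 <- seq(1, length(occ1) - 200, by = 200)
  wocc1 <- vapply(w1, function(s) mean(occ1[s:(s + 199)]), numeric(1))
  wgc1 <- vapply(w1, function(s) mean(seqv1[s:(s + 199)] %in% c("G", "C")),
                 numeric(1))
  expect_gt(cor(wocc1, wgc1, method = "spearman"), 0.3)
})

test_that("fully AT flanks with full penalty forbid extension", {
  g <- genome_seq(c(chrS = strrep("AT", 5000)), circular = TRUE)
  cfg <- sim_config(genome_length = 10000L, n_genes = 2L, gene_length = 500L,
                    alpha = 1, density = 2, seed = 3L)
  sp <- simulate_placements(list(genome = g), cfg)
  expect_true(all(sp$placements$rank == 1L))
})

test_that("noise-free digestion returns exact model lengths; mu scales yield", {
  st <- tiny_study_cached()
  cfg0 <- tiny_sim_config(seed = 42L)
  cfg0$sigma <- 0
  cfg0$w_at <- 0
  fr <- simulate_digest(list(placements = st$placements),
                        list(genome = st$genome), cfg0)
  expect_true(all(fr$length %in% oligomer_length(1:4)))

  cfg2 <- cfg0
  cfg2$mu <- cfg0$mu * 2
  fr2 <- simulate_digest(list(placements = st$placements),
                         list(genome = st$genome), cfg2)
  lambda <- nrow(st$placements) * cfg2$mu
  expect_lt(abs(nrow(fr2) - lambda), 3 * sqrt(lambda))
})

test_that("the simulated digest shows the oligomer ladder and the EV does not", {
  st <- default_study_cached()
  lp <- ladder_peaks(st$fragments$length, st$ev_fragments$length)
  pk <- lp$peaks$length
  for (rung in c(60, 90, 120)) expect_true(any(abs(pk - rung) <= 3))
  ev_ladder <- sum(vapply(c(60, 90, 120, 150), function(r)
    any(abs(lp$ev_peaks$length - r) <= 3), logical(1)))
  expect_lt(ev_ladder, 2)
})

test_that("EV coverage is flat without cut bias and AT-biased with it", {
  cfg <- sim_config(genome_length = 50000L, n_genes = 20L, w_at = 0,
                    seed = 9L)
  sg <- simulate_genome(cfg)
  ev <- simulate_ev(sg, cfg)
  cov <- coverage_track(ev, sg$genome)
  seqv <- strsplit(sg$genome$seqs[[1]], "")[[1]]
  w <- seq(1, 50000 - 500, by = 500)
  wcov <- vapply(w, function(s) mean(cov$track[[1]][s:(s + 499)]), numeric(1))
  wat <- vapply(w, function(s) mean(seqv[s:(s + 499)] %in% c("A", "T")),
                numeric(1))
  expect_gt(cor.test(wcov, wat)$p.value, 0.01)

  cfg$w_at <- 0.7
  ev2 <- simulate_ev(sg, cfg)
  cov2 <- coverage_track(ev2, sg$genome)
  wcov2 <- vapply(w, function(s) mean(cov2$track[[1]][s:(s + 499)]), numeric(1))
  expect_gt(cor(wcov2, wat), 0)
})

test_that("expression coupling plants detectable repression and a compendium hit", {
  st <- default_study_cached()
  ex <- st$expression
  occ <- st$occ_tss
  joined <- merge(ex$de_binding, occ, by = "gene")
  down <- joined$occ_tss[joined$padj < 0.05 & joined$log2fc < 0]
  up <- joined$occ_tss[joined$padj < 0.05 & joined$log2fc > 0]
  expect_lt(wilcox.test(down, up, alternative = "greater")$p.value, 0.01)

  sims <- compendium_similarity(ex$de_binding, ex$compendium)
  expect_equal(sims$comparison[1], ex$planted_comparison)

  # gamma = 0: no association between occupancy and estimated fold change
  cfg0 <- tiny_sim_config(seed = 13L)
  cfg0$gamma <- 0
  st0 <- simulate_study(cfg0)
  j0 <- merge(st0$expression$de_binding, st0$occ_tss, by = "gene")
  expect_gt(cor.test(j0$occ_tss, j0$log2fc, method = "spearman")$p.value, 0.01)
})

test_that("changing one stage seed leaves the other stages untouched", {
  cfg <- tiny_sim_config(seed = 1L)
  sg1 <- simulate_genome(cfg, seed = 1L)
  sg2 <- simulate_genome(cfg, seed = 1L)
  expect_identical(sg1$genome$seqs, sg2$genome$seqs)
  sp1 <- simulate_placements(sg1, cfg, seed = 1L)
  fr_a <- simulate_digest(sp1, sg1, cfg, seed = 1L)
  fr_b <- simulate_digest(sp1, sg1, cfg, seed = 2L)
  expect_false(identical(fr_a, fr_b))
  expect_identical(simulate_digest(sp1, sg1, cfg, seed = 1L), fr_a)
})
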