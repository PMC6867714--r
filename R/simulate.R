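#' Simulation configuration
#'
#' Parameters of the synthetic study system: a bacterial-style genome
#' with AT-rich promoters, oligomeric histone particles (tetramer core
#' of `f0` bp extended in dimer steps of `step` bp up to rank
#' `r_max`), biased MNase digestion, a matched empty-vector (EV)
#' library, and occupancy-coupled differential expression.
#'
#' The defaults are the package's reference study conditions: a 200 kb
#' genome at background GC 0.5 with one hundred 1 kb genes behind
#' 100 bp promoters of GC 0.3, particle density 8 per kb, extension
#' base probability 0.6 damped by AT-rich flanks (`alpha` = 0.8), 2 bp
#' end jitter, AT cut bias 0.7, twenty fragments per particle and a
#' repression coupling of 1 between promoter occupancy and log2
#' fold change.
#'
#' @param genome_length Genome length L in bp.
#' @param gc_background,gc_promoter Background / promoter GC fraction
#'   (promoters must be more AT-rich: `gc_promoter < gc_background`).
#' @param n_genes,gene_length Gene count and transcript length (bp).
#' @param promoter_width Promoter width immediately upstream of the TSS (bp).
#' @param utr_length Distance from TSS to start codon (bp).
#' @param beta_gc Nucleation sequence weight: tetramer nucleation
#'   probability proportional to `exp(beta_gc * GC61)`.
#' @param density Target particle density (particles per kb).
#' @param step Dimer step size in bp (ladder spacing).
#' @param f0 Tetramer footprint in bp.
#' @param r_max Maximum oligomer rank.
#' @param p_extend Extension base probability per attempt.
#' @param alpha AT-flank extension penalty in `p_extend * (1 - alpha * AT_flank)`.
#' @param sigma End-jitter standard deviation (bp) of the digestion.
#' @param w_at Probability that a fragment end snaps to the nearest
#'   A/T base (MNase AT preference); also scales the EV cut bias.
#' @param mu Mean fragments emitted per particle (Poisson).
#' @param ev_fragments EV fragment count; default matches the expected
#'   histone-strain yield.
#' @param gamma Expression coupling: true log2FC = `-gamma` times the
#'   standardized TSS occupancy (repression sign convention).
#' @param phi Negative-binomial dispersion of replicate counts.
#' @param n_replicates Replicates per condition.
#' @param n_compendium Number of comparison vectors in the synthetic
#'   compendium (one of them planted to correlate with the
#'   histone-strain response at rho 0.5).
#' @param seed Base seed; each stochastic stage derives its own stream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000L,
                       gc_background = 0.5,
                       gc_promoter = 0.3,
                       n_genes = 100L,
                       gene_length = 1000L,
                       promoter_width = 100L,
                       utr_length = 50L,
                       beta_gc = 16,
                       density = 8,
                       step = 30L,
                       f0 = 60L,
                       r_max = 4L,
                       p_extend = 0.6,
                       alpha = 0.8,
                       sigma = 2,
                       w_at = 0.7,
                       mu = 20,
                       ev_fragments = NULL,
                       gamma = 1,
                       phi = 0.2,
                       n_replicates = 5L,
                       n_compendium = 50L,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$ev_fragments)) {
    cfg$ev_fragments <- as.integer(round(density * genome_length / 1000 * mu))
  }
  if (!(gc_promoter < gc_background && gc_promoter > 0 && gc_background < 1)) {
    stop("need 0 < gc_promoter < gc_background < 1")
  }
  if (step * (r_max - 1) + f0 > 160) {
    stop("largest footprint exceeds the <160 bp sequencing size selection")
  }
  probs <- c(p_extend = p_extend, alpha = alpha, w_at = w_at)
  if (any(probs < 0 | probs > 1)) stop("p_extend, alpha, w_at must lie in [0,1]")
  if (gamma < 0) stop("gamma must be >= 0 (repression sign convention)")
  class(cfg) <- "sim_config"
  cfg
}

#' Protected length of an oligomer rank
#'
#' Under the tetramer-plus-dimer-step model a particle of rank r
#' protects `f0 + step * (r - 1)` bp: 60, 90, 120, 150 bp for ranks
#' 1..4 at the defaults (tetramer, hexamer, octamer, decamer).
#'
#' @param rank Oligomer rank (1 = tetramer).
#' @param f0 Tetramer footprint (bp).
#' @param step Dimer step (bp).
#' @return Protected length in bp.
#' @export
oligomer_length <- function(rank, f0 = 60L, step = 30L) {
  stopifnot(all(rank >= 1))
  f0 + step * (rank - 1L)
}

# independent deterministic seed per stage, stable across platforms
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 48271L + h * 1009L) %% 2147483562L
}

gc_window <- function(is_gc, w, circular = TRUE) {
  # sliding mean of a 0/1 vector over centered windows of odd width w
  L <- length(is_gc)
  h <- (w - 1L) %/% 2L
  x <- if (circular) c(is_gc[(L - h + 1L):L], is_gc, is_gc[1:h]) else
    c(rep(NA_real_, h), is_gc, rep(NA_real_, h))
  cs <- cumsum(c(0, x))
  (cs[(w + 1):(L + w)] - cs[1:L]) / w
}

#' Simulate a genome with AT-rich promoters
#'
#' Bases are drawn independently with region-specific GC: background
#' `gc_background`, promoters `gc_promoter`. Genes are laid out
#' non-overlapping with uniformly random gaps; each gene carries a
#' promoter immediately upstream of its TSS (the promoter's 3' edge),
#' and its start codon sits `utr_length` bp into the transcript.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return List: `genome` (`genome_seq`, one circular contig "chrS"),
#'   `genes`, `promoters` (interval tibbles), `tss` (tibble with
#'   tss_id, contig, position, strand, reads, gene).
#' @export
simulate_genome <- function(config = sim_config(), seed = NULL) {
  cfg <- config
  seed <- if (is.null(seed)) cfg$seed else seed
  L <- cfg$genome_length
  slot <- cfg$gene_length + cfg$promoter_width
  if (cfg$n_genes * slot > L) stop("genes do not fit in the genome")
  withr::local_seed(stage_seed(seed, "genome"))
  # gene slots: random gaps via sorted uniform draws of the slack
  slack <- L - cfg$n_genes * slot
  cuts <- sort(sample.int(slack + 1L, cfg$n_genes, replace = TRUE) - 1L)
  slot_start <- cuts + (seq_len(cfg$n_genes) - 1L) * slot
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  # slot layout: [promoter][transcript] on +, mirrored on -
  gene_start <- ifelse(strand == "+", slot_start + cfg$promoter_width, slot_start)
  gene_end <- gene_start + cfg$gene_length
  prom_start <- ifelse(strand == "+", slot_start, gene_end)
  prom_end <- prom_start + cfg$promoter_width
  tss_pos <- ifelse(strand == "+", gene_start, gene_end - 1L)

  base_at <- c("A", "T")
  base_gc <- c("G", "C")
  is_gc <- stats::rbinom(L, 1L, cfg$gc_background)
  for (i in seq_len(cfg$n_genes)) {
    idx <- (prom_start[i] + 1L):prom_end[i]
    is_gc[idx] <- stats::rbinom(length(idx), 1L, cfg$gc_promoter)
  }
  pick <- stats::rbinom(L, 1L, 0.5) + 1L
  bases <- ifelse(is_gc == 1L, base_gc[pick], base_at[pick])
  genome <- genome_seq(c(chrS = paste(bases, collapse = "")), circular = TRUE)

  ids <- sprintf("gene%03d", seq_len(cfg$n_genes))
  genes <- interval_tbl("chrS", gene_start, gene_end, strand, ids, 0, genome)
  promoters <- interval_tbl("chrS", prom_start, prom_end, strand,
                            paste0(ids, "_prom"), 0, genome)
  tss <- tibble::tibble(
    tss_id = paste0(ids, "_tss"), contig = "chrS",
    position = as.integer(tss_pos), strand = strand,
    reads = stats::rpois(cfg$n_genes, 50) + 1L, gene = ids
  ) |> dplyr::arrange(.data$position)
  list(genome = genome, genes = genes, promoters = promoters, tss = tss)
}

#' Simulate oligomeric histone placements
#'
#' Tetramer nucleation sites are drawn with probability proportional
#' to `exp(beta_gc * GC61)` (GC fraction of the 61 bp window centered
#' on the footprint midpoint), rejecting overlaps, until the target
#' density is reached. Each particle then makes `r_max - 1` extension
#' attempts; an attempt picks a side uniformly and succeeds with
#' probability `p_extend * (1 - alpha * AT_flank)` where `AT_flank` is
#' the AT fraction of the adjacent `step` bp on that side; a collision
#' with another particle ends extension permanently.
#'
#' @param sim_genome Result of [simulate_genome()] (or a list with a
#'   `genome` element).
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @return List: `placements` (tibble contig, start, end, rank),
#'   `occupancy` (per-base 0/1 protection vector), `config`.
#' @export
simulate_placements <- function(sim_genome, config = sim_config(), seed = NULL) {
  cfg <- config
  seed <- if (is.null(seed)) cfg$seed else seed
  genome <- sim_genome$genome
  id <- names(genome$seqs)[1]
  seqv <- strsplit(genome$seqs[[id]], "")[[1]]
  L <- length(seqv)
  is_gc <- as.numeric(seqv %in% c("G", "C"))
  gc61 <- gc_window(is_gc, 61L, circular = genome$circular[[id]])
  wts <- exp(cfg$beta_gc * gc61)
  n_target <- as.integer(round(cfg$density * L / 1000))
  withr::local_seed(stage_seed(seed, "placements"))

  occupied <- logical(L)
  half <- cfg$f0 %/% 2L
  starts <- integer(n_target); ranks <- integer(n_target); ends <- integer(n_target)
  n_placed <- 0L
  attempts <- 0L
  max_attempts <- 60L * n_target
  while (n_placed < n_target && attempts < max_attempts) {
    m <- min(4L * (n_target - n_placed), 20000L)
    cand <- sample.int(L, m, replace = TRUE, prob = wts)
    attempts <- attempts + m
    for (ct in cand) {
      if (n_placed >= n_target) break
      s <- (ct - 1L) - half          # 0-based footprint start
      idx <- (s + seq_len(cfg$f0) - 1L) %% L + 1L
      if (any(occupied[idx])) next
      occupied[idx] <- TRUE
      n_placed <- n_placed + 1L
      starts[n_placed] <- s
      ends[n_placed] <- s + cfg$f0
      ranks[n_placed] <- 1L
    }
  }
  if (n_placed < n_target) {
    warning("target density unattainable; placed ", n_placed, " of ", n_target)
    starts <- starts[seq_len(n_placed)]
    ends <- ends[seq_len(n_placed)]
    ranks <- ranks[seq_len(n_placed)]
  }

  is_at <- 1 - is_gc
  at_frac <- function(from0, len) {
    # AT fraction of 0-based [from0, from0+len)
    idx <- (from0 + seq_len(len) - 1L) %% L + 1L
    mean(is_at[idx])
  }
  for (i in seq_len(n_placed)) {
    for (a in seq_len(cfg$r_max - 1L)) {
      side <- sample(c(-1L, 1L), 1L)
      if (side < 0) {
        flank0 <- starts[i] - cfg$step
        idx <- (flank0 + seq_len(cfg$step) - 1L) %% L + 1L
      } else {
        flank0 <- ends[i]
        idx <- (flank0 + seq_len(cfg$step) - 1L) %% L + 1L
      }
      if (any(occupied[idx])) break    # collision: extension over for good
      p <- cfg$p_extend * (1 - cfg$alpha * mean(is_at[idx]))
      if (stats::runif(1) < p) {
        occupied[idx] <- TRUE
        if (side < 0) starts[i] <- starts[i] - cfg$step else ends[i] <- ends[i] + cfg$step
        ranks[i] <- ranks[i] + 1L
      }
    }
  }

  placements <- tibble::tibble(
    contig = id,
    start = starts %% L,
    end = starts %% L + (ends - starts),
    rank = ranks
  ) |> dplyr::arrange(.data$start)
  occ <- as.numeric(occupied)
  list(placements = placements, occupancy = stats::setNames(list(occ), id),
       config = cfg)
}

# snap 0-based cut coordinates toward the nearest A/T base (within max_d)
snap_to_at <- function(pos0, is_at, L, max_d = 8L) {
  out <- pos0
  todo <- rep(TRUE, length(pos0))
  for (d in 0:max_d) {
    if (!any(todo)) break
    for (off in unique(c(d, -d))) {
      cand <- (pos0[todo] + off) %% L
      hit <- is_at[cand + 1L] == 1
      idx <- which(todo)[hit]
      out[idx] <- (pos0[idx] + off) %% L
      todo[idx] <- FALSE
    }
  }
  out
}

#' Simulate MNase digestion of placed particles
#'
#' Each particle emits `Poisson(mu)` fragments. A fragment starts as
#' the particle's protected interval; each end is independently
#' jittered by a rounded Normal(0, sigma), then snapped (with
#' probability `w_at`) to the nearest position whose base is A or T,
#' mimicking the nuclease's AT preference. Lengths are clipped to a
#' minimum of 20 bp.
#'
#' @param sim_placements Result of [simulate_placements()].
#' @param sim_genome Result of [simulate_genome()].
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @param n_fragments Optional total fragment target; when given, the
#'   per-particle mean is scaled so the expected yield matches it.
#' @return Fragment tibble (contig, start, end, strand, name, score, length).
#' @export
simulate_digest <- function(sim_placements, sim_genome, config = sim_config(),
                            seed = NULL, n_fragments = NULL) {
  cfg <- config
  seed <- if (is.null(seed)) cfg$seed else seed
  genome <- sim_genome$genome
  id <- names(genome$seqs)[1]
  seqv <- strsplit(genome$seqs[[id]], "")[[1]]
  L <- length(seqv)
  is_at <- as.numeric(seqv %in% c("A", "T"))
  pl <- sim_placements$placements
  mu <- if (is.null(n_fragments)) cfg$mu else n_fragments / nrow(pl)
  withr::local_seed(stage_seed(seed, "digest"))
  n_per <- stats::rpois(nrow(pl), mu)
  n <- sum(n_per)
  s0 <- rep(pl$start, n_per)
  e0 <- rep(pl$end, n_per)
  s <- s0 + round(stats::rnorm(n, 0, cfg$sigma))
  e <- e0 + round(stats::rnorm(n, 0, cfg$sigma))
  snap <- stats::runif(n) < cfg$w_at
  if (any(snap)) s[snap] <- snap_to_at(s[snap] %% L, is_at, L)
  # for the right cut the flanking (first unprotected) base is at e
  if (any(snap)) e[snap] <- snap_to_at(e[snap] %% L, is_at, L) +
      (e[snap] %/% L) * L
  len <- pmax(e - s, 20L)
  s <- s %% L
  tibble::tibble(contig = id, start = as.integer(s),
                 end = as.integer(s + len), strand = ".",
                 name = ".", score = 0, length = as.integer(len)) |>
    dplyr::arrange(.data$start)
}

#' Simulate the empty-vector (EV) control digest
#'
#' EV fragments carry the nuclease's sequence bias but no footprint
#' structure: lengths follow a smooth Gamma-shaped law over 20-160 bp
#' (no 30 bp ladder), and start positions are drawn with weight
#' `1 + w_at * AT61` so coverage tracks local AT content.
#'
#' @param sim_genome Result of [simulate_genome()].
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @param n_fragments Optional override of `config$ev_fragments`.
#' @return Fragment tibble as in [simulate_digest()].
#' @export
simulate_ev <- function(sim_genome, config = sim_config(), seed = NULL,
                        n_fragments = NULL) {
  cfg <- config
  seed <- if (is.null(seed)) cfg$seed else seed
  genome <- sim_genome$genome
  id <- names(genome$seqs)[1]
  seqv <- strsplit(genome$seqs[[id]], "")[[1]]
  L <- length(seqv)
  is_at <- as.numeric(seqv %in% c("A", "T"))
  at61 <- gc_window(is_at, 61L, circular = genome$circular[[id]])
  n <- if (is.null(n_fragments)) cfg$ev_fragments else n_fragments
  withr::local_seed(stage_seed(seed, "ev"))
  wts <- 1 + cfg$w_at * at61
  s <- sample.int(L, n, replace = TRUE, prob = wts) - 1L
  len <- pmin(pmax(round(stats::rgamma(n, shape = 5, scale = 14)) + 20L, 20L), 160L)
  tibble::tibble(contig = id, start = as.integer(s),
                 end = as.integer(s + len), strand = ".",
                 name = ".", score = 0, length = as.integer(len)) |>
    dplyr::arrange(.data$start)
}

#' Mean true occupancy around each TSS
#' @param sim_placements Result of [simulate_placements()].
#' @param tss TSS tibble from [simulate_genome()].
#' @param halfwidth Window half-width in bp (window = 2*halfwidth + 1).
#' @return Tibble gene, tss_id, occ_tss.
#' @export
true_tss_occupancy <- function(sim_placements, tss, halfwidth = 25L) {
  occ <- sim_placements$occupancy[[1]]
  L <- length(occ)
  o <- vapply(tss$position, function(p) {
    idx <- (p + (-halfwidth:halfwidth)) %% L + 1L
    mean(occ[idx])
  }, numeric(1))
  tibble::tibble(gene = tss$gene, tss_id = tss$tss_id, occ_tss = o)
}

#' Simulate occupancy-coupled differential expression and a compendium
#'
#' Baseline log2 expression is Normal(8, 1) per gene. The
#' histone-binding strain's true log2 fold change is
#' `-gamma * standardize(occ_tss)` plus, for a random 10% of genes, a
#' systemic shift shared with a non-binding control strain (exercising
#' the both-strains exclusion rule), plus Normal(0, 0.25) noise.
#' Replicate counts are negative binomial with dispersion `phi`; the
#' DE estimate is the log2 ratio of replicate means with BH-adjusted
#' two-sample t p-values on log2 counts. The compendium holds
#' `n_compendium` random comparison vectors plus one planted vector
#' correlated (rho 0.5) with the binding-strain response.
#'
#' @param occ_tss Tibble from [true_tss_occupancy()].
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @return List: `de_binding`, `de_nonbinding` (tibbles gene, log2fc,
#'   padj, base_mean), `counts` (matrix genes x samples),
#'   `compendium` (tibble gene + one column per comparison),
#'   `planted_comparison` (its column name), `truth` (per-gene tibble).
#' @export
simulate_expression <- function(occ_tss, config = sim_config(), seed = NULL) {
  cfg <- config
  seed <- if (is.null(seed)) cfg$seed else seed
  withr::local_seed(stage_seed(seed, "expression"))
  g <- occ_tss$gene
  n <- length(g)
  z <- as.numeric(scale(occ_tss$occ_tss))
  if (any(!is.finite(z))) z <- rep(0, n)
  shift <- numeric(n)
  sys_idx <- sample.int(n, max(1L, round(0.1 * n)))
  shift[sys_idx] <- stats::rnorm(length(sys_idx), 0, 1.5)
  lfc_bind <- -cfg$gamma * z + shift + stats::rnorm(n, 0, 0.25)
  lfc_nonb <- shift + stats::rnorm(n, 0, 0.25)
  base <- stats::rnorm(n, 8, 1)

  draw_counts <- function(log2_mean) {
    mu <- 2^log2_mean
    matrix(stats::rnbinom(n * cfg$n_replicates, mu = rep(mu, cfg$n_replicates),
                          size = 1 / cfg$phi),
           nrow = n)
  }
  de_from_counts <- function(ctrl, trt) {
    est <- log2(rowMeans(trt) + 0.5) - log2(rowMeans(ctrl) + 0.5)
    p <- vapply(seq_len(n), function(i) {
      a <- log2(ctrl[i, ] + 1); b <- log2(trt[i, ] + 1)
      if (stats::sd(c(a, b)) == 0) return(1)
      stats::t.test(b, a)$p.value
    }, numeric(1))
    tibble::tibble(gene = g, log2fc = est, padj = stats::p.adjust(p, "BH"),
                   base_mean = rowMeans(cbind(ctrl, trt)))
  }
  ctrl1 <- draw_counts(base); trt1 <- draw_counts(base + lfc_bind)
  ctrl2 <- draw_counts(base); trt2 <- draw_counts(base + lfc_nonb)
  de_bind <- de_from_counts(ctrl1, trt1)
  de_nonb <- de_from_counts(ctrl2, trt2)

  zd <- as.numeric(scale(de_bind$log2fc))
  comp <- matrix(stats::rnorm(n * cfg$n_compendium), nrow = n)
  planted_col <- sample.int(cfg$n_compendium, 1)
  comp[, planted_col] <- 0.5 * zd + sqrt(1 - 0.25) * stats::rnorm(n)
  colnames(comp) <- sprintf("cmp%03d", seq_len(cfg$n_compendium))
  compendium <- tibble::as_tibble(comp)
  compendium <- dplyr::bind_cols(tibble::tibble(gene = g), compendium)

  counts <- cbind(ctrl1, trt1)
  rownames(counts) <- g
  colnames(counts) <- c(paste0("ctrl", seq_len(cfg$n_replicates)),
                        paste0("hist", seq_len(cfg$n_replicates)))
  list(de_binding = de_bind, de_nonbinding = de_nonb, counts = counts,
       compendium = compendium,
       planted_comparison = colnames(comp)[planted_col],
       truth = tibble::tibble(gene = g, occ_z = z, lfc_true = lfc_bind,
                              systemic = seq_len(n) %in% sys_idx))
}

#' Run the full synthetic study
#'
#' Convenience wrapper chaining genome, placements, digestion, EV
#' control and expression simulation under one configuration.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return List with elements genome, genes, promoters, tss,
#'   placements, occupancy, fragments, ev_fragments, occ_tss,
#'   expression, config.
#' @export
simulate_study <- function(config = sim_config(), seed = NULL) {
  seed <- if (is.null(seed)) config$seed else seed
  sg <- simulate_genome(config, seed)
  sp <- simulate_placements(sg, config, seed)
  fr <- simulate_digest(sp, sg, config, seed)
  ev <- simulate_ev(sg, config, seed)
  ot <- true_tss_occupancy(sp, sg$tss)
  ex <- simulate_expression(ot, config, seed)
  c(sg, sp["placements"], list(occupancy = sp$occupancy), list(
    fragments = fr, ev_fragments = ev, occ_tss = ot, expression = ex,
    config = config, seed = seed
  ))
}
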