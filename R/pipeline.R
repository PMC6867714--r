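#' Default pipeline configuration
#'
#' Nested list of every tunable the pipeline exposes, with the
#' package's documented defaults. A run takes either the `simulate`
#' block (synthetic study, the default) or a `paths` block pointing at
#' real files (genome FASTA, fragment BEDs, TSS/DE/compendium TSVs) —
#' exactly one of the two.
#'
#' @param seed Global seed fanned out deterministically to stages.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = unclass(sim_config(seed = as.integer(seed))),
    paths = NULL,
    stages = list(footprints = TRUE, seqmodel = TRUE, profiles = TRUE,
                  link = TRUE),
    occupancy = list(
      size_class_centers = c(60L, 90L, 120L, 150L),
      size_class_tol = 5L,
      scale_libraries = FALSE,
      window_width = 60L, window_step = 30L,
      tss_profile_halfwidth = 500L,
      origin = 0L, terminus = NULL,
      regional_window = 200L, regional_step = 200L,
      moving_span = 500L, moving_step = 20L
    ),
    footprints = list(kappa = 0.1, threshold_quantile = 0.3,
                      merge_frac = 0.85, flank = 30L, match_tol = 5L),
    seqmodel = list(k_set = 1:4, window = 121L, size_class = 120L,
                    stride = 10L, train_fraction = 1 / 6, nfolds = 10L,
                    log2_response = FALSE),
    link = list(alpha = 0.05, control_halfwidth = 25L, min_group = 3L,
                cosine = FALSE)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_config()]; unknown top-level
#' keys are rejected.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config(seed = user$seed %||% 1L)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  cfg <- merge_lists(base, user)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  has_sim <- !is.null(cfg$simulate)
  has_paths <- !is.null(cfg$paths)
  if (has_sim == has_paths) {
    stop("configuration must provide exactly one of 'simulate' and 'paths'")
  }
  if (has_sim) {
    sc <- cfg$simulate
    cfg$simulate <- do.call(sim_config, sc[names(sc) %in%
                                             names(formals(sim_config))])
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the footprint pipeline
#'
#' Executes the stages in dependency order — simulate (or load) →
#' coverage → normalize → footprints → sequence model → profiles →
#' transcription link — and writes every result table as TSV into
#' `out_dir` with the configuration echoed alongside, so a rerun with
#' the same config and seed is bit-identical.
#'
#' @param config Configuration list (see [default_config()]); paths
#'   mode expects `config$paths` with elements genome, fragments, ev,
#'   tss, genes, promoters, de_binding, de_nonbinding, compendium.
#' @param out_dir Output directory (created; TSV outputs only).
#' @return A `run_report` list with the per-stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- validate_config(config)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  report <- list(seed = cfg$seed, config = cfg)

  if (!is.null(cfg$simulate)) {
    study <- simulate_study(cfg$simulate, cfg$seed)
  } else {
    p <- cfg$paths
    genome <- read_fasta(p$genome)
    study <- list(
      genome = genome,
      fragments = read_bed(p$fragments, "fragments", genome),
      ev_fragments = read_bed(p$ev, "fragments", genome),
      genes = read_bed(p$genes, genome = genome),
      promoters = read_bed(p$promoters, genome = genome),
      tss = readr::read_tsv(p$tss, show_col_types = FALSE),
      expression = list(
        de_binding = readr::read_tsv(p$de_binding, show_col_types = FALSE),
        de_nonbinding = readr::read_tsv(p$de_nonbinding,
                                        show_col_types = FALSE),
        compendium = readr::read_tsv(p$compendium, show_col_types = FALSE))
    )
  }
  genome <- study$genome
  oc <- cfg$occupancy

  ev_cov <- coverage_track(study$ev_fragments, genome, label = "EV")
  pooled_cov <- coverage_track(study$fragments, genome, label = "strain")
  classes <- oc$size_class_centers
  tracks <- lapply(classes, function(cc) {
    normalize_track(
      coverage_track(study$fragments, genome,
                     length_filter = c(cc - oc$size_class_tol,
                                       cc + oc$size_class_tol),
                     label = paste0("strain_", cc)),
      ev_cov, scale_libraries = oc$scale_libraries)
  })
  names(tracks) <- as.character(classes)
  tracks$pooled <- normalize_track(pooled_cov, ev_cov,
                                   scale_libraries = oc$scale_libraries)
  large <- classes[classes >= 90]
  tracks$`90plus` <- normalize_track(
    coverage_track(study$fragments, genome,
                   length_filter = c(min(large) - oc$size_class_tol,
                                     max(large) + oc$size_class_tol),
                   label = "strain_90plus"),
    ev_cov, scale_libraries = oc$scale_libraries)
  report$tracks <- tracks
  report$ladder <- ladder_peaks(study$fragments$length,
                                study$ev_fragments$length)

  if (isTRUE(cfg$stages$footprints)) {
    id <- names(genome$seqs)[1]
    sm <- fft_smooth(pooled_cov$track[[id]], cfg$footprints$kappa)
    calls <- call_peaks(sm, cfg$footprints$threshold_quantile, contig = id,
                        merge_frac = cfg$footprints$merge_frac)
    report$footprints <- list(
      calls = calls,
      extension = extension_vs_flank(calls, genome, cfg$footprints$flank))
    if (!is.null(study$placements)) {
      report$footprints$recovery <- match_calls(calls, study$placements,
                                                cfg$footprints$match_tol)
    }
  }

  if (isTRUE(cfg$stages$seqmodel)) {
    sq <- cfg$seqmodel
    id <- names(genome$seqs)[1]
    L <- contig_lengths(genome)[[id]]
    pos <- seq(0L, L - 1L, by = sq$stride)
    feats <- kmer_features(genome, pos, sq$k_set, sq$window, id)
    resp_track <- tracks[[as.character(sq$size_class)]]
    resp <- resp_track$track[[id]][as.integer(rownames(feats)) + 1L]
    model <- fit_sparse(feats, resp, L, sq$train_fraction, sq$nfolds,
                        sq$log2_response)
    report$seqmodel <- list(
      model = model,
      eval_test = evaluate_model(model, feats, resp, "test"),
      eval_train = evaluate_model(model, feats, resp, "train"))
  }

  if (isTRUE(cfg$stages$profiles)) {
    report$profiles <- list(
      tss = tss_profile(study$fragments, study$tss, genome,
                        D = oc$tss_profile_halfwidth),
      gene_gc = gene_gc_occupancy(genome, study$genes, tracks$pooled))
    gg <- report$profiles$gene_gc$genes
    report$profiles$moving <- suppressWarnings(
      moving_gc_occupancy(gg, min(oc$moving_span, nrow(gg)), oc$moving_step))
  }

  if (isTRUE(cfg$stages$link) && !is.null(study$expression)) {
    lk <- cfg$link
    groups <- exclusion_filter(study$expression$de_binding,
                               study$expression$de_nonbinding, lk$alpha)
    assoc <- window_occupancy(
      groups, tracks, study$tss, study$promoters, study$genes,
      start_codon_offset = if (!is.null(cfg$simulate))
        cfg$simulate$utr_length else 0L,
      control_halfwidth = lk$control_halfwidth, min_group = lk$min_group)
    sims <- compendium_similarity(study$expression$de_binding,
                                  study$expression$compendium,
                                  cosine = lk$cosine)
    report$link <- list(groups = groups, association = assoc,
                        similarity = sims)
  }

  if (!is.null(out_dir)) write_report(report, study, out_dir)
  class(report) <- "run_report"
  report
}

write_tsv_q <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_report <- function(report, study, out_dir) {
  yaml::write_yaml(config_for_echo(report$config),
                   file.path(out_dir, "config.yaml"))
  write_tsv_q(report$ladder$peaks, file.path(out_dir, "ladder_peaks.tsv"))
  if (!is.null(report$footprints)) {
    write_tsv_q(report$footprints$calls, file.path(out_dir, "footprints.tsv"))
  }
  if (!is.null(report$seqmodel)) {
    write_tsv_q(tidy(report$seqmodel$model),
                file.path(out_dir, "kmer_coefficients.tsv"))
    write_tsv_q(report$seqmodel$eval_test$univariate,
                file.path(out_dir, "kmer_univariate.tsv"))
  }
  if (!is.null(report$profiles)) {
    write_tsv_q(tidy(report$profiles$tss), file.path(out_dir, "tss_profile.tsv"))
    write_tsv_q(report$profiles$gene_gc$genes,
                file.path(out_dir, "gene_gc_occupancy.tsv"))
  }
  if (!is.null(report$link)) {
    write_tsv_q(report$link$association$tests,
                file.path(out_dir, "occupancy_association.tsv"))
    write_tsv_q(report$link$similarity,
                file.path(out_dir, "compendium_similarity.tsv"))
  }
  invisible(out_dir)
}

config_for_echo <- function(cfg) {
  cfg$simulate <- unclass(cfg$simulate)
  rapply(cfg, function(x) x, how = "replace")
}

#' Write a complete synthetic input set to disk
#'
#' Generates one synthetic study and writes every pipeline input in
#' its on-disk format: genome FASTA; fragment, gene, promoter and
#' NAP-like-region BEDs; TSS, DE and compendium TSVs; and the YAML
#' configuration. `scale = "tiny"` (20 kb) is for tests and examples,
#' `"default"` (200 kb) for realistic runs.
#'
#' @param out_dir Target directory; must be empty unless `force`.
#' @param scale `"tiny"` or `"default"`.
#' @param seed Seed.
#' @param force Overwrite a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
make_fixtures <- function(out_dir, scale = c("tiny", "default"), seed = 1L,
                          force = FALSE) {
  scale <- match.arg(scale)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory not empty (use force = TRUE): ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- if (scale == "tiny") tiny_sim_config(seed) else sim_config(seed = seed)
  study <- simulate_study(cfg, seed)
  write_fasta(study$genome, file.path(out_dir, "genome.fa"))
  write_bed(study$fragments, file.path(out_dir, "fragments.bed"))
  write_bed(study$ev_fragments, file.path(out_dir, "ev_fragments.bed"))
  write_bed(study$genes, file.path(out_dir, "genes.bed"))
  write_bed(study$promoters, file.path(out_dir, "promoters.bed"))
  # NAP-like bound regions: alternate gene bodies stand in for a
  # protein-bound region set
  nap <- study$genes[seq(1, nrow(study$genes), by = 2), ]
  write_bed(nap, file.path(out_dir, "nap_regions.bed"))
  write_tsv_q(study$tss, file.path(out_dir, "tss.tsv"))
  write_tsv_q(study$expression$de_binding,
              file.path(out_dir, "de_binding.tsv"))
  write_tsv_q(study$expression$de_nonbinding,
              file.path(out_dir, "de_nonbinding.tsv"))
  write_tsv_q(study$expression$compendium,
              file.path(out_dir, "compendium.tsv"))
  yaml::write_yaml(list(seed = seed, simulate = unclass(cfg)),
                   file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Desk-scale simulation configuration for tests and examples
#' @param seed Seed.
#' @return A `sim_config` over a 20 kb genome with 15 genes.
#' @export
tiny_sim_config <- function(seed = 1L) {
  sim_config(genome_length = 20000L, n_genes = 15L, gene_length = 600L,
             seed = as.integer(seed))
}
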