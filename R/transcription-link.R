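#' Group genes by differential expression, excluding systemic responders
#'
#' Genes significantly changed in the same direction in both the
#' histone-binding strain and a non-binding control strain respond to
#' histone expression itself rather than to DNA binding, and are
#' excluded. Remaining genes are grouped by the binding-strain table:
#' up (`padj < alpha`, log2FC > 0), down (`padj < alpha`, log2FC < 0),
#' unchanged otherwise.
#'
#' @param de_binding,de_nonbinding DE tibbles (gene, log2fc, padj).
#' @param alpha Significance cutoff on adjusted p-values.
#' @return Tibble gene, log2fc, padj, excluded, group
#'   (factor up/down/unchanged, NA for excluded genes).
#' @export
exclusion_filter <- function(de_binding, de_nonbinding, alpha = 0.05) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(de_binding)))
  if (anyDuplicated(de_binding$gene)) stop("duplicate gene ids")
  joined <- dplyr::inner_join(de_binding, de_nonbinding, by = "gene",
                              suffix = c("", "_nb"))
  if (nrow(joined) == 0) stop("no shared genes between the two tables")
  joined |>
    dplyr::mutate(
      sig = .data$padj < alpha,
      sig_nb = .data$padj_nb < alpha,
      excluded = .data$sig & .data$sig_nb &
        sign(.data$log2fc) == sign(.data$log2fc_nb) & .data$log2fc != 0,
      group = factor(
        dplyr::case_when(
          .data$excluded ~ NA_character_,
          .data$sig & .data$log2fc > 0 ~ "up",
          .data$sig & .data$log2fc < 0 ~ "down",
          TRUE ~ "unchanged"
        ),
        levels = c("up", "down", "unchanged"))
    ) |>
    dplyr::select("gene", "log2fc", "padj", "excluded", "group")
}

# per-gene mean occupancy for one window definition over one track
window_mean_occ <- function(track, contig, start, end) {
  v <- track$track[[contig]]
  interval_mean(v, start, end)
}

#' Occupancy of DE groups at promoter-anchored windows
#'
#' Computes, per gene, mean normalized occupancy at five window types
#' — the single TSS base, TSS +/- 25 bp, the annotated promoter, the
#' gene body, and a 51 bp control window centered on the start codon —
#' for each supplied size-class track, and compares the down vs up
#' group per (window, size class) cell with a two-sided
#' Mann-Whitney/Wilcoxon rank-sum test.
#'
#' @param groups Tibble from [exclusion_filter()].
#' @param tracks Named list of `normalized_track`s (e.g. `"60"`,
#'   `"90"`, `"120"`, `"150"`, `"pooled"`, `"90plus"`).
#' @param tss TSS tibble (gene, contig, position, strand).
#' @param promoters Promoter interval tibble (`name` = gene promoter id
#'   `"<gene>_prom"` or matched via the `gene` column if present).
#' @param genes Gene interval tibble (`name` = gene id).
#' @param start_codon_offset Distance TSS -> start codon in bp along
#'   the transcript (0 if gene intervals start at the CDS).
#' @param control_halfwidth Half-width of the start-codon window
#'   (51 bp window = 25).
#' @param min_group Suppress tests when a group is smaller than this.
#' @return An `occupancy_association`: list with `per_gene` (long
#'   tibble), `tests` (tibble window, size_class, n_up, n_down,
#'   mean_up, mean_down, statistic, p).
#' @export
window_occupancy <- function(groups, tracks, tss, promoters, genes,
                             start_codon_offset = 0L,
                             control_halfwidth = 25L, min_group = 3L) {
  if (!"gene" %in% names(promoters)) {
    promoters$gene <- sub("_prom$", "", promoters$name)
  }
  gene_int <- genes[c("contig", "start", "end", "strand", "name")]
  names(gene_int)[5] <- "gene"
  info <- groups |>
    dplyr::inner_join(tss[c("gene", "contig", "position", "strand")],
                      by = "gene") |>
    dplyr::inner_join(gene_int, by = c("gene", "contig"),
                      suffix = c("", "_gene")) |>
    dplyr::inner_join(promoters[c("gene", "start", "end")], by = "gene",
                      suffix = c("", "_prom"))
  n_dropped <- nrow(groups) - nrow(info)
  # start codon sits start_codon_offset bp into the transcript
  info$codon <- ifelse(info$strand == "+",
                       info$position + start_codon_offset,
                       info$position - start_codon_offset)
  windows <- list(
    tss_point = function(g) c(g$position, g$position + 1L),
    tss_pm25 = function(g) c(g$position - 25L, g$position + 26L),
    promoter = function(g) c(g$start_prom, g$end_prom),
    gene_body = function(g) c(g$start, g$end),
    start_codon = function(g) c(g$codon - control_halfwidth,
                                g$codon + control_halfwidth + 1L)
  )
  per_gene <- purrr::map_dfr(names(tracks), function(cl) {
    purrr::map_dfr(names(windows), function(w) {
      occ <- vapply(seq_len(nrow(info)), function(i) {
        g <- info[i, ]
        se <- windows[[w]](g)
        L <- length(tracks[[cl]]$track[[g$contig]])
        window_mean_occ(tracks[[cl]], g$contig, se[1] %% L,
                        se[1] %% L + (se[2] - se[1]))
      }, numeric(1))
      tibble::tibble(gene = info$gene, group = info$group,
                     excluded = info$excluded,
                     window = w, size_class = cl, mean_occ = occ)
    })
  })
  tests <- per_gene |>
    dplyr::filter(!.data$excluded, !is.na(.data$group)) |>
    dplyr::group_by(.data$window, .data$size_class) |>
    dplyr::group_modify(function(df, key) {
      up <- df$mean_occ[df$group == "up"]
      down <- df$mean_occ[df$group == "down"]
      testable <- length(up) >= min_group && length(down) >= min_group
      wt <- if (testable)
        suppressWarnings(stats::wilcox.test(down, up)) else NULL
      tibble::tibble(
        n_up = length(up), n_down = length(down),
        mean_up = mean(up), mean_down = mean(down),
        statistic = if (testable) unname(wt$statistic) else NA_real_,
        p = if (testable) wt$p.value else NA_real_)
    }) |>
    dplyr::ungroup()
  structure(list(per_gene = per_gene, tests = tests, n_dropped = n_dropped),
            class = "occupancy_association")
}

#' @export
print.occupancy_association <- function(x, ...) {
  cat("<occupancy_association> down-vs-up rank-sum tests:\n")
  print(x$tests)
  invisible(x)
}

#' Similarity of a differential-expression vector to a compendium
#'
#' Raw dot product of the query log2 fold changes with each compendium
#' comparison over their shared genes (comparisons sharing fewer than
#' `min_shared` genes are skipped); the Spearman correlation of the
#' paired vectors is reported alongside. `cosine` rescales the dot
#' product by both norms.
#'
#' @param de DE tibble (gene, log2fc).
#' @param compendium Tibble: `gene` column plus one numeric column per
#'   comparison.
#' @param min_shared Minimum shared genes per comparison.
#' @param cosine Normalize to cosine similarity.
#' @return Tibble comparison, similarity, rho, n_shared, ranked by
#'   descending similarity.
#' @export
compendium_similarity <- function(de, compendium, min_shared = 1L,
                                  cosine = FALSE) {
  stopifnot("gene" %in% names(compendium))
  comps <- setdiff(names(compendium), "gene")
  joined <- dplyr::inner_join(de[c("gene", "log2fc")], compendium, by = "gene")
  rows <- purrr::map_dfr(comps, function(cn) {
    v <- joined[[cn]]
    d <- joined$log2fc
    okv <- !is.na(v) & !is.na(d)
    if (sum(okv) < min_shared) return(tibble::tibble())
    s <- sum(d[okv] * v[okv])
    if (cosine) s <- s / (sqrt(sum(d[okv]^2)) * sqrt(sum(v[okv]^2)))
    tibble::tibble(
      comparison = cn, similarity = s,
      rho = suppressWarnings(stats::cor(d[okv], v[okv], method = "spearman")),
      n_shared = sum(okv))
  })
  dplyr::arrange(rows, dplyr::desc(.data$similarity))
}

#' Split a DE vector into up- and down-regulation components
#'
#' Restriction of the log2 fold changes to positive (up) and negative
#' (down) entries, zeros elsewhere; the two components sum back to the
#' original vector and give the two similarity axes of an up/down
#' compendium comparison.
#'
#' @param de DE tibble (gene, log2fc).
#' @return List of two DE tibbles, `up` and `down`.
#' @export
direction_split <- function(de) {
  list(
    up = dplyr::mutate(de, log2fc = pmax(.data$log2fc, 0)),
    down = dplyr::mutate(de, log2fc = pmin(.data$log2fc, 0))
  )
}
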