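all_kmers <- function(k_set = 1:4) {
  unlist(lapply(k_set, function(k) {
    do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                    stringsAsFactors = FALSE)))
  }))
}

# base-4 encoding of k-mer start positions; NA where any base is N
kmer_ids <- function(code, k, circular, L) {
  n <- if (circular) L else L - k + 1L
  idx <- function(j) if (circular) code[((seq_len(n) - 1L + j) %% L) + 1L]
    else code[seq_len(n) + j]
  id <- idx(0L)
  if (k > 1) for (j in seq_len(k - 1L)) id <- id * 4L + idx(j)
  id
}

#' K-mer composition features around genome positions
#'
#' For each position, counts of every k-mer (k in `k_set`, forward
#' strand, no reverse-complement collapsing) inside the odd-width
#' window centered on it. With `k_set = 1:4` this yields
#' 4 + 16 + 64 + 256 = 340 features. Windows containing N are dropped
#' and reported via the `"excluded"` attribute.
#'
#' @param genome A `genome_seq`.
#' @param positions 0-based center positions (single contig).
#' @param k_set K-mer sizes.
#' @param window Odd window width in bp (61, 91 or 121 pair with the
#'   60/90/120 bp size classes).
#' @param contig Contig id; default the first.
#' @return Numeric matrix positions x k-mers, rownames the positions;
#'   attribute `"excluded"` lists dropped positions.
#' @export
kmer_features <- function(genome, positions, k_set = 1:4, window = 121L,
                          contig = names(genome$seqs)[1]) {
  if (window %% 2 == 0) stop("window width must be odd")
  seqv <- strsplit(genome$seqs[[contig]], "")[[1]]
  L <- length(seqv)
  circ <- genome$circular[[contig]]
  h <- (window - 1L) %/% 2L
  if (!circ && any(positions < h | positions > L - 1L - h)) {
    stop("positions within window/2 of a linear contig edge")
  }
  code <- match(seqv, c("A", "C", "G", "T")) - 1L  # NA for N
  ids_by_k <- lapply(k_set, function(k) kmer_ids(code, k, circ, L))
  names(ids_by_k) <- as.character(k_set)
  kmers <- all_kmers(k_set)
  out <- matrix(0, nrow = length(positions), ncol = length(kmers),
                dimnames = list(positions, kmers))
  ok <- rep(TRUE, length(positions))
  for (i in seq_along(positions)) {
    p <- positions[i]
    row <- numeric(0)
    for (k in k_set) {
      ids <- ids_by_k[[as.character(k)]]
      s0 <- p - h                      # window start, 0-based
      n_sub <- window - k + 1L
      ii <- if (circ) ((s0 + seq_len(n_sub) - 1L) %% L) + 1L
        else s0 + seq_len(n_sub)
      sub <- ids[ii]
      if (anyNA(sub)) { ok[i] <- FALSE; break }
      row <- c(row, tabulate(sub + 1L, nbins = 4^k))
    }
    if (ok[i]) out[i, ] <- row
  }
  res <- out[ok, , drop = FALSE]
  attr(res, "excluded") <- positions[!ok]
  attr(res, "window") <- window
  res
}

#' Fit a sparse (L1) k-mer model of occupancy
#'
#' LASSO regression of normalized occupancy on k-mer composition.
#' Training uses only positions in the contiguous genome prefix
#' `[0, floor(L * train_fraction))` — one sixth by default, matching
#' the convention of training on the first sixth of the chromosome —
#' with the penalty chosen by cross-validation over contiguous blocks
#' inside the prefix (limiting spatial leakage). Features are
#' standardized internally; coefficients are reported on the original
#' count scale.
#'
#' @param features Matrix from [kmer_features()], rownames = positions.
#' @param response Numeric response per row (normalized occupancy).
#' @param genome_length Contig length L (bp).
#' @param train_fraction Fraction of the genome used for training.
#' @param nfolds Cross-validation folds (contiguous blocks).
#' @param log2_response Model `log2(response + 0.5)` instead.
#' @param lambda Optional fixed penalty (skips cross-validation).
#' @return A `sparse_occ_model`: list with `fit` (glmnet), `lambda`,
#'   `coefficients` (tibble term, estimate), `intercept`,
#'   `train_end` (prefix end, bp), `train_rows`, `log2_response`.
#' @export
fit_sparse <- function(features, response, genome_length,
                       train_fraction = 1 / 6, nfolds = 10L,
                       log2_response = FALSE, lambda = NULL) {
  stopifnot(nrow(features) == length(response))
  if (log2_response) response <- log2(response + 0.5)
  if (stats::sd(response) == 0) stop("constant response; nothing to fit")
  pos <- as.integer(rownames(features))
  t_end <- train_prefix_end(genome_length, train_fraction)
  tr <- which(pos < t_end)
  if (length(tr) < nfolds * 2) stop("too few training positions")
  x <- features[tr, , drop = FALSE]
  y <- response[tr]
  ord <- order(pos[tr])
  foldid <- integer(length(tr))
  foldid[ord] <- rep(seq_len(nfolds),
                     each = ceiling(length(tr) / nfolds))[seq_along(tr)]
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                            standardize = TRUE)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, y, alpha = 1, standardize = TRUE)
  }
  cf <- as.matrix(stats::coef(fit, s = lambda))
  structure(list(
    fit = fit, lambda = lambda,
    coefficients = tibble::tibble(term = rownames(cf)[-1],
                                  estimate = cf[-1, 1]),
    intercept = cf[1, 1], train_end = t_end, train_rows = length(tr),
    log2_response = log2_response
  ), class = "sparse_occ_model")
}

#' Training-prefix end under the one-sixth convention
#' @param genome_length Contig length L in bp.
#' @param fraction Training fraction.
#' @return `floor(L * fraction)` (the first excluded coordinate).
#' @export
train_prefix_end <- function(genome_length, fraction = 1 / 6) {
  as.integer(floor(genome_length * fraction))
}

#' @export
print.sparse_occ_model <- function(x, ...) {
  nz <- sum(x$coefficients$estimate != 0)
  cat("<sparse_occ_model> lambda = ", signif(x$lambda, 4), ", ", nz,
      " nonzero of ", nrow(x$coefficients), " k-mer coefficients; trained on [0, ",
      x$train_end, ") (", x$train_rows, " positions)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of a sparse occupancy model
#' @param x A `sparse_occ_model`.
#' @param ... Unused.
#' @return Tibble term, estimate (intercept excluded).
#' @method tidy sparse_occ_model
#' @export
tidy.sparse_occ_model <- function(x, ...) x$coefficients

#' One-row model summary
#' @param x A `sparse_occ_model`.
#' @param ... Unused.
#' @return Tibble lambda, n_nonzero, n_features, train_end, train_rows.
#' @method glance sparse_occ_model
#' @export
glance.sparse_occ_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda,
                 n_nonzero = sum(x$coefficients$estimate != 0),
                 n_features = nrow(x$coefficients),
                 train_end = x$train_end, train_rows = x$train_rows)
}

#' Predict occupancy from k-mer features
#' @param object A `sparse_occ_model`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Numeric predictions (on the response scale given at fit time).
#' @export
predict.sparse_occ_model <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, newx = newdata, s = object$lambda))
}

#' Evaluate a sparse occupancy model on a held-out region
#'
#' Spearman correlation of predicted and observed occupancy on rows
#' disjoint from the training prefix, plus genome-wide univariate
#' per-k-mer Spearman correlations with the response ("individually
#' most informative" k-mers) and the 20 most positive / most negative.
#'
#' @param model A `sparse_occ_model`.
#' @param features Feature matrix (rownames = positions).
#' @param response Observed occupancy per row.
#' @param region `"test"` (rows at/after the training boundary;
#'   rows inside it are rejected) or `"train"`.
#' @return A `model_eval`: list with `rho`, `p`, `region`, `n`,
#'   `univariate` (tibble term, rho), `top20`, `bottom20`.
#' @export
evaluate_model <- function(model, features, response,
                           region = c("test", "train")) {
  region <- match.arg(region)
  pos <- as.integer(rownames(features))
  idx <- if (region == "test") which(pos >= model$train_end)
    else which(pos < model$train_end)
  if (region == "test" && any(pos[idx] < model$train_end)) {
    stop("evaluation rows overlap the training region")
  }
  if (length(idx) == 0) stop("no rows in the requested region")
  obs <- response[idx]
  if (model$log2_response) obs <- log2(obs + 0.5)
  pred <- predict(model, features[idx, , drop = FALSE])
  ct <- suppressWarnings(stats::cor.test(pred, obs, method = "spearman"))
  rr <- rank(response)
  uni <- stats::cor(apply(features, 2, rank), rr)
  uni_tb <- tibble::tibble(term = colnames(features), rho = as.numeric(uni)) |>
    dplyr::arrange(dplyr::desc(.data$rho))
  structure(list(
    rho = unname(ct$estimate), p = ct$p.value, region = region,
    n = length(idx), univariate = uni_tb,
    top20 = utils::head(uni_tb, 20), bottom20 = utils::tail(uni_tb, 20)
  ), class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat("<model_eval> ", x$region, " rho = ", signif(x$rho, 3),
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

complement_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Read-internal nucleotide enrichment profile
#'
#' Position-by-base frequencies across all fragments of one exact
#' length (forward genome strand), expressed as enrichment over the
#' genome-wide base composition. Histone-protected fragments show
#' dyad-symmetric enrichment: position p of base b mirrors position
#' len+1-p of the complementary base. The symmetry score is the mean
#' absolute difference of those paired enrichments (0 = perfectly
#' symmetric).
#'
#' @param fragments Fragment tibble.
#' @param genome A `genome_seq`.
#' @param exact_length Only fragments of exactly this length contribute.
#' @return A `nuc_profile`: list with `enrichment` (len x 4 matrix),
#'   `freq`, `background`, `n_fragments`, `symmetry_score`.
#' @export
read_internal_profile <- function(fragments, genome, exact_length = 60L) {
  fr <- fragments[fragments$length == exact_length, ]
  if (nrow(fr) == 0) {
    warning("no fragments of length ", exact_length)
    return(structure(list(enrichment = NULL, freq = NULL, background = NULL,
                          n_fragments = 0L, symmetry_score = NA_real_),
                     class = "nuc_profile"))
  }
  if (nrow(fr) < 100) warning("only ", nrow(fr), " fragments; profile noisy")
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, nrow = exact_length, ncol = 4,
                   dimnames = list(NULL, bases))
  bg_counts <- stats::setNames(numeric(4), bases)
  for (id in unique(fr$contig)) {
    seqv <- strsplit(genome$seqs[[id]], "")[[1]]
    L <- length(seqv)
    tb <- table(factor(seqv, levels = bases))
    bg_counts <- bg_counts + as.numeric(tb)
    sub <- fr[fr$contig == id, ]
    for (i in seq_len(nrow(sub))) {
      idx <- (sub$start[i] + seq_len(exact_length) - 1L) %% L + 1L
      b <- seqv[idx]
      m <- match(b, bases)
      keep <- !is.na(m)
      counts[cbind(which(keep), m[keep])] <-
        counts[cbind(which(keep), m[keep])] + 1
    }
  }
  freq <- counts / pmax(rowSums(counts), 1)
  background <- bg_counts / sum(bg_counts)
  enr <- sweep(freq, 2, background, "/")
  mirror <- enr[rev(seq_len(exact_length)), complement_base[bases]]
  colnames(mirror) <- bases
  sym <- mean(abs(enr - mirror))
  structure(list(enrichment = enr, freq = freq, background = background,
                 n_fragments = nrow(fr), symmetry_score = sym),
            class = "nuc_profile")
}

#' Tidy a read-internal profile
#' @param x A `nuc_profile`.
#' @param ... Unused.
#' @return Tibble position, base, enrichment.
#' @method tidy nuc_profile
#' @export
tidy.nuc_profile <- function(x, ...) {
  if (is.null(x$enrichment)) return(tibble::tibble())
  tibble::as_tibble(x$enrichment) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    tidyr::pivot_longer(-"position", names_to = "base",
                        values_to = "enrichment")
}
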