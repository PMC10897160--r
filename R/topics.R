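## Topic modeling of circle-read bin matrices.
##
## Cells are documents, fixed-width genomic bins are the vocabulary and
## circle reads are tokens. Latent Dirichlet allocation (collapsed Gibbs
## sampling, symmetric priors alpha = 50/K and beta = 0.1) decomposes
## the cells x bins matrix into cells x topics and topics x bins
## distributions; topics summarize co-occurring eccDNA regions.

#' Build the cells x bins count matrix
#'
#' Counts, per cell, the reads falling (by midpoint) inside the cell's
#' own CPRs, in fixed genomic bins. Reads outside the cell's CPRs are
#' excluded, bins with no counts in any cell are dropped, and a per-cell
#' normalized copy is kept alongside the raw counts.
#'
#' @param cell_reads named list of per-cell read GRanges.
#' @param cell_cprs named list of per-cell CPR GRanges (same names).
#' @param seqinfo Seqinfo of the active genome.
#' @param bin_size bin width in bp (default 2000).
#' @param contigs contigs to tile (default: all but none excluded).
#' @return `ecc_bin_matrix`: list with `counts` (integer matrix cells x
#'   bins), `norm` (rows divided by their totals), `bins` (GRanges
#'   catalog) and `cells`. Cells with zero in-CPR reads are dropped with
#'   a message.
#' @export
build_bin_matrix <- function(cell_reads, cell_cprs, seqinfo,
                             bin_size = 2000L,
                             contigs = GenomeInfoDb::seqnames(seqinfo)) {
  stopifnot(length(cell_reads) == length(cell_cprs))
  cells <- names(cell_reads) %||% sprintf("cell%03d", seq_along(cell_reads))
  sl <- seqlengths(seqinfo)[contigs]
  tiles <- unlist(tileGenome(sl, tilewidth = bin_size))
  mat <- matrix(0L, nrow = length(cells), ncol = length(tiles),
                dimnames = list(cells, NULL))
  for (i in seq_along(cells)) {
    mid <- midpoints(cell_reads[[i]])
    keep <- overlapsAny(mid, cell_cprs[[i]], ignore.strand = TRUE)
    mat[i, ] <- countOverlaps(tiles, mid[keep], ignore.strand = TRUE)
  }
  nz_cells <- rowSums(mat) > 0
  if (!all(nz_cells)) {
    message("dropping ", sum(!nz_cells), " cell(s) with zero in-CPR reads")
    mat <- mat[nz_cells, , drop = FALSE]
    cells <- cells[nz_cells]
  }
  nz_bins <- colSums(mat) > 0
  mat <- mat[, nz_bins, drop = FALSE]
  bins <- tiles[nz_bins]
  structure(list(counts = mat, norm = mat / pmax(1L, rowSums(mat)),
                 bins = bins, cells = cells),
            class = "ecc_bin_matrix")
}

#' Fit an LDA topic model
#'
#' Collapsed Gibbs sampling on an integer count matrix; deterministic
#' for a fixed seed.
#'
#' @param counts integer matrix (cells x bins) or an `ecc_bin_matrix`.
#' @param n_topics number of topics (>= 1).
#' @param alpha,beta symmetric Dirichlet hyperparameters; defaults
#'   50/n_topics and 0.1.
#' @param n_iter Gibbs sweeps (default 200).
#' @param seed integer seed.
#' @return `ecc_topic_model`: list with `n_topics`, `theta` (cells x
#'   topics, rows sum to 1), `phi` (topics x bins, rows sum to 1),
#'   `loglik` trace, `perplexity`, and the call parameters.
#' @export
fit_lda <- function(counts, n_topics, alpha = 50 / n_topics, beta = 0.1,
                    n_iter = 200L, seed = 1L) {
  if (inherits(counts, "ecc_bin_matrix")) counts <- counts$counts
  stopifnot(n_topics >= 1, is.matrix(counts))
  if (n_topics > ncol(counts)) {
    stop("n_topics exceeds the number of bins")
  }
  storage.mode(counts) <- "integer"
  set.seed(seed)
  fit <- lda_gibbs_cpp(counts, as.integer(n_topics), alpha, beta,
                       as.integer(n_iter))
  rownames(fit$theta) <- rownames(counts)
  structure(list(n_topics = n_topics, theta = fit$theta, phi = fit$phi,
                 loglik = fit$loglik, perplexity = fit$perplexity,
                 n_tokens = fit$n_tokens, alpha = alpha, beta = beta,
                 n_iter = n_iter, seed = seed),
            class = "ecc_topic_model")
}

#' Select the number of topics
#'
#' Fits (or accepts) models over a grid of topic numbers and reports the
#' final log likelihood, its discrete second derivative and the
#' perplexity per grid point. The chosen model sits at the elbow: the
#' interior grid point with the most negative curvature (largest drop in
#' likelihood gain); a flat curve falls back to the lowest perplexity.
#'
#' @param models list of `ecc_topic_model` fits over increasing
#'   `n_topics` (>= 3 grid points).
#' @return list with `table` (data.frame n_topics, loglik, d2, perplexity)
#'   and `best` (selected n_topics).
#' @export
select_model <- function(models) {
  if (length(models) < 3) stop("need at least 3 grid points")
  k <- vapply(models, `[[`, numeric(1), "n_topics")
  stopifnot(!is.unsorted(k))
  ll <- vapply(models, function(m) tail(m$loglik, 1L), numeric(1))
  px <- vapply(models, `[[`, numeric(1), "perplexity")
  d2 <- rep(NA_real_, length(k))
  d2[2:(length(k) - 1)] <- diff(ll, differences = 2)
  tab <- data.frame(n_topics = k, loglik = ll, d2 = d2, perplexity = px)
  interior <- which(!is.na(d2))
  span <- diff(range(d2[interior]))
  if (!is.finite(span) || span < 1e-8) {
    best <- k[which.min(px)]
  } else {
    cand <- interior[d2[interior] == min(d2[interior])]
    if (length(cand) > 1) cand <- cand[which.min(px[cand])]
    best <- k[cand]
  }
  list(table = tab, best = best)
}

#' Signature regions of each topic
#'
#' Bins whose topic loading exceeds the per-topic score quantile are
#' merged into regions (adjacent bins join); regions can optionally be
#' matched against an annotation set requiring a minimum reciprocal
#' overlap.
#'
#' @param model `ecc_topic_model`.
#' @param bins GRanges bin catalog (columns of the matrix the model was
#'   fitted on).
#' @param score_quantile per-topic loading quantile above which a bin is
#'   selected (default 0.975).
#' @param annotations optional GRanges to match against.
#' @param min_overlap minimum reciprocal overlap for an annotation match
#'   (default 0.4).
#' @return named list (one GRanges per topic); when annotations are
#'   given each GRanges carries a logical `matched` column.
#' @export
topic_regions <- function(model, bins, score_quantile = 0.975,
                          annotations = NULL, min_overlap = 0.4) {
  stopifnot(length(bins) == ncol(model$phi))
  out <- lapply(seq_len(model$n_topics), function(k) {
    load <- model$phi[k, ]
    sel <- load > quantile(load, score_quantile)
    regions <- reduce(bins[sel], ignore.strand = TRUE)
    if (!is.null(annotations) && length(regions)) {
      ro <- reciprocal_overlap(regions, annotations)
      matched <- logical(length(regions))
      matched[unique(ro$query[ro$ro >= min_overlap])] <- TRUE
      mcols(regions)$matched <- matched
    }
    regions
  })
  names(out) <- sprintf("topic%d", seq_len(model$n_topics))
  out
}

#' Differential topics between two cell groups
#'
#' Per topic: linear fold change of group means of the cell-topic
#' contributions and a two-sided rank-sum p value, Benjamini-Hochberg
#' adjusted across topics. A topic is selected when the adjusted p falls
#' below `padj_threshold` and the fold change (larger group over
#' smaller) exceeds `fc_threshold`.
#'
#' @param theta cells x topics matrix (or an `ecc_topic_model`).
#' @param groups factor/character of length nrow(theta) with two levels,
#'   each with at least 3 cells.
#' @param fc_threshold,padj_threshold selection thresholds (defaults 2
#'   and 0.5).
#' @return data.frame (topic, mean_a, mean_b, fold_change, p, padj,
#'   selected).
#' @export
differential_topics <- function(theta, groups, fc_threshold = 2,
                                padj_threshold = 0.5) {
  if (inherits(theta, "ecc_topic_model")) theta <- theta$theta
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == nrow(theta))
  if (any(table(groups) < 3)) stop("each group needs at least 3 cells")
  ga <- levels(groups)[1]; gb <- levels(groups)[2]
  rows <- lapply(seq_len(ncol(theta)), function(k) {
    xa <- theta[groups == ga, k]
    xb <- theta[groups == gb, k]
    fc <- mean(xa) / mean(xb)
    p <- suppressWarnings(wilcox.test(xa, xb)$p.value)
    data.frame(topic = k, mean_a = mean(xa), mean_b = mean(xb),
               fold_change = fc, p = p)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out$selected <- out$padj < padj_threshold &
    pmax(out$fold_change, 1 / out$fold_change) > fc_threshold
  out
}

#' Write a topic model to disk
#'
#' Cell-topic and topic-bin matrices as TSV plus a JSON metadata file;
#' the bin matrix itself can be exported as sparse MTX triplets with a
#' bin BED and a cell list.
#'
#' @param model `ecc_topic_model`.
#' @param dir output directory (created if needed).
#' @param bin_matrix optional `ecc_bin_matrix` to export alongside.
#' @export
write_topic_model <- function(model, dir, bin_matrix = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(model$theta, file.path(dir, "cell_topic.tsv"),
              sep = "\t", quote = FALSE)
  write.table(model$phi, file.path(dir, "topic_bin.tsv"),
              sep = "\t", quote = FALSE)
  jsonlite::write_json(
    model[c("n_topics", "alpha", "beta", "n_iter", "seed", "perplexity")],
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(bin_matrix)) {
    m <- bin_matrix$counts
    idx <- which(m > 0, arr.ind = TRUE)
    hdr <- c("%%MatrixMarket matrix coordinate integer general",
             paste(nrow(m), ncol(m), nrow(idx)))
    writeLines(c(hdr, paste(idx[, 1], idx[, 2], m[idx])),
               file.path(dir, "bin_matrix.mtx"))
    bins <- bin_matrix$bins
    write.table(data.frame(as.character(seqnames(bins)),
                           start(bins) - 1L, end(bins)),
                file.path(dir, "bins.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    writeLines(bin_matrix$cells, file.path(dir, "cells.tsv"))
  }
  invisible(dir)
}

#' Adjusted Rand index
#'
#' Agreement between two partitions corrected for chance; 1 means
#' identical clusterings. Used to score planted-partition recovery by
#' dominant topic.
#'
#' @param a,b cluster label vectors of equal length.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
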