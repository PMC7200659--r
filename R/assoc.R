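#' Ward hierarchical clustering of sample divergence vectors
#'
#' Clusters samples represented as binned divergence vectors (e.g. mean HD
#' at DMP positions per 2-kb window) using Ward's method on Euclidean
#' distances (the `ward.D2` variant: squared-update agglomeration on
#' unsquared input distances).
#'
#' @param mat A `bin_matrix` or a plain samples-by-features numeric
#'   matrix with sample rownames.
#' @param method Agglomeration method (default `"ward.D2"`; `"ward.D"`
#'   available).
#' @return A `cluster_result`: list with `hclust`, `merge_heights`,
#'   `leaf_order` (labels in dendrogram order).
#' @export
hierarchical_cluster <- function(mat, method = "ward.D2") {
  m <- if (inherits(mat, "bin_matrix")) as.matrix(mat) else mat
  if (nrow(m) < 3L) abort("need >= 3 samples to cluster")
  if (all(m == 0)) {
    rlang::warn("all-zero matrix: every merge is at height 0")
  }
  hc <- hclust(dist(m), method = method)
  structure(
    list(hclust = hc, merge_heights = hc$height,
         leaf_order = hc$labels[hc$order]),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$leaf_order), " leaves; top merge ",
      "height ", signif(max(x$merge_heights), 4), "\n", sep = "")
  invisible(x)
}

#' Clade assignments at a cut count
#'
#' @param cl A `cluster_result`.
#' @param k Number of clades.
#' @return Named integer vector of clade ids per sample.
#' @export
cut_clades <- function(cl, k) {
  stats::cutree(cl$hclust, k = k)
}

#' Export a clustering as a Newick tree string
#'
#' @param cl A `cluster_result`.
#' @return Newick string.
#' @export
as_newick <- function(cl) {
  ape::write.tree(ape::as.phylo(cl$hclust))
}

#' PCA followed by linear discriminant classification
#'
#' Centers and scales the feature matrix, projects onto the fewest
#' principal components explaining `var_explained` of the variance, and
#' fits a linear discriminant on the component scores. Generalization is
#' reported as leave-one-out accuracy with the whole pipeline (scaling,
#' PCA, LDA) refit in every fold.
#'
#' @param mat Samples x features numeric matrix (rownames = sample ids) or
#'   `bin_matrix`.
#' @param labels Class label per sample (factor or character).
#' @param var_explained Cumulative variance target (default 0.9).
#' @return A `pca_lda_result`: `projections` (scores), `ncomp`,
#'   `loo_accuracy`, `loo_pred`, `labels`.
#' @export
pca_lda <- function(mat, labels, var_explained = 0.9) {
  m <- if (inherits(mat, "bin_matrix")) as.matrix(mat) else mat
  labels <- factor(labels)
  stopifnot(nrow(m) == length(labels))
  if (nlevels(labels) < 2L) abort("need >= 2 classes")
  if (any(table(labels) < 2L)) {
    rlang::warn("classes with a single sample: their LOO folds are skipped")
  }
  project <- function(train_x, test_x) {
    keep <- apply(train_x, 2, stats::sd) > 0
    train_x <- train_x[, keep, drop = FALSE]
    test_x <- test_x[, keep, drop = FALSE]
    pc <- prcomp(train_x, center = TRUE, scale. = TRUE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ncomp <- max(1L, min(which(cum >= var_explained)))
    ncomp <- min(ncomp, nrow(train_x) - 1L)
    list(train = pc$x[, seq_len(ncomp), drop = FALSE],
         test = predict(pc, test_x)[, seq_len(ncomp), drop = FALSE],
         ncomp = ncomp)
  }
  full <- project(m, m)
  fit <- suppressWarnings(MASS::lda(full$train, grouping = labels))
  n <- nrow(m)
  pred <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tr_lab <- labels[-i]
    if (min(table(droplevels(tr_lab))) < 2L || labels[i] %in%
          names(which(table(labels) < 2L))) {
      next
    }
    pr <- project(m[-i, , drop = FALSE], m[i, , drop = FALSE])
    f <- tryCatch(
      suppressWarnings(MASS::lda(pr$train, grouping = droplevels(tr_lab))),
      error = function(e) NULL
    )
    if (!is.null(f)) {
      pred[i] <- as.character(predict(f, pr$test)$class)
    }
  }
  scored <- !is.na(pred)
  structure(
    list(projections = full$train, ncomp = full$ncomp, lda = fit,
         labels = labels, loo_pred = pred,
         loo_accuracy = mean(pred[scored] == as.character(labels)[scored])),
    class = "pca_lda_result"
  )
}

#' @export
print.pca_lda_result <- function(x, ...) {
  cat("<pca_lda_result> ", x$ncomp, " components; LOO accuracy = ",
      signif(x$loo_accuracy, 3), "\n", sep = "")
  invisible(x)
}

# Linear-by-linear (Mantel-Haenszel trend) statistic on two ordinal
# score vectors: M^2 = (N - 1) r^2, chi-squared with 1 df.
linear_by_linear <- function(u, v) {
  n <- length(u)
  r <- stats::cor(u, v)
  m2 <- (n - 1) * r^2
  list(stat = m2, p = stats::pchisq(m2, df = 1, lower.tail = FALSE))
}

#' Association between per-gene methylation divergence and expression
#'
#' Restricted to genes with positive methylation divergence (MD), computes
#' Spearman's rank correlation of MD with the expression divergence
#' `|log2fc|` separately for upregulated (`log2fc > 0`) and downregulated
#' (`log2fc < 0`) genes, and a linear-by-linear association test on
#' equal-frequency rank-binned `n_bins x n_bins` grids of MD vs `|log2fc|`
#' over all joined genes (`M^2 = (N-1) r^2` of the bin scores, chi-squared
#' with 1 df).
#'
#' @param md Tibble `gene_id, md`.
#' @param expression Tibble `gene_id, log2fc, padj`.
#' @param n_bins Number of equal-frequency bins per axis (default 10).
#' @return An `association_result`: `spearman_rho_up`,
#'   `spearman_rho_down`, `lbl_stat`, `lbl_p`, `n_genes`, `n_up`,
#'   `n_down`.
#' @export
md_expression_assoc <- function(md, expression, n_bins = 10) {
  joined <- md |>
    filter(.data$md > 0) |>
    inner_join(expression, by = "gene_id") |>
    filter(.data$log2fc != 0) |>
    mutate(expr_div = abs(.data$log2fc))
  if (nrow(joined) < n_bins) abort("too few genes with positive MD")
  rho_stratum <- function(df, label) {
    if (nrow(df) < 10L) {
      rlang::warn(paste0("fewer than 10 ", label,
                         " genes: rho is unstable"))
    }
    if (nrow(df) < 2L) return(NA_real_)
    stats::cor(df$md, df$expr_div, method = "spearman")
  }
  up <- filter(joined, .data$log2fc > 0)
  down <- filter(joined, .data$log2fc < 0)
  bins <- function(x) {
    as.integer(cut(rank(x, ties.method = "average"),
                   breaks = n_bins, labels = FALSE, include.lowest = TRUE))
  }
  lbl <- linear_by_linear(bins(joined$md), bins(joined$expr_div))
  structure(
    list(spearman_rho_up = rho_stratum(up, "upregulated"),
         spearman_rho_down = rho_stratum(down, "downregulated"),
         lbl_stat = lbl$stat, lbl_p = lbl$p,
         n_genes = nrow(joined), n_up = nrow(up), n_down = nrow(down)),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> n = ", x$n_genes, "; Spearman rho (up) = ",
      signif(x$spearman_rho_up, 3), ", (down) = ",
      signif(x$spearman_rho_down, 3), "; M^2 = ", signif(x$lbl_stat, 4),
      " (p = ", format.pval(x$lbl_p), ")\n", sep = "")
  invisible(x)
}

#' Genes within a distance of any interval
#'
#' Interval join used e.g. to find genes within ±1 kb of differential
#' sRNA clusters: a gene qualifies if its body overlaps or lies within
#' `dist` bp of any query interval.
#'
#' @param intervals Tibble `chrom, start, end`.
#' @param annotation Annotation tibble (genic features used).
#' @param dist Maximum gap in bp (default 1000; overlap counts).
#' @return Character vector of gene ids.
#' @export
interval_join <- function(intervals, annotation, dist = 1000) {
  genes <- filter(annotation, .data$feature_class == "genic")
  if (nrow(genes) == 0L || nrow(intervals) == 0L) return(character())
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  i_gr <- GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start, intervals$end)
  )
  d <- GenomicRanges::distanceToNearest(g_gr, i_gr, ignore.strand = TRUE)
  gap <- rep(Inf, length(g_gr))
  gap[S4Vectors::queryHits(d)] <- S4Vectors::elementMetadata(d)$distance
  sort(genes$feature_id[gap <= dist])
}

#' Overlap between two gene sets
#'
#' @param a,b Character vectors.
#' @return List: `n` (intersection size), `frac_a`, `frac_b`,
#'   `intersection`.
#' @export
set_overlap <- function(a, b) {
  i <- intersect(a, b)
  list(n = length(i),
       frac_a = if (length(a) > 0) length(i) / length(a) else NA_real_,
       frac_b = if (length(b) > 0) length(i) / length(b) else NA_real_,
       intersection = sort(i))
}
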