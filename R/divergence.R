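#' Per-site methylation level
#'
#' Maximum-likelihood methylation proportion `n_meth / (n_meth + n_unmeth)`.
#' An optional Jeffreys-style pseudo-count is available but off by default:
#' the downstream >20% level-difference filter dominates low-coverage noise,
#' so the plain proportion is used throughout.
#'
#' @param n_meth,n_unmeth Methylated / unmethylated read counts (vectors).
#' @param pseudo Pseudo-count added to each of the two cells (default 0).
#' @return Numeric vector of levels in `[0, 1]`.
#' @export
methylation_level <- function(n_meth, n_unmeth, pseudo = 0) {
  if (any(n_meth + n_unmeth < 1)) {
    abort("zero-coverage site: filter coverage before computing levels")
  }
  (n_meth + pseudo) / (n_meth + n_unmeth + 2 * pseudo)
}

#' Signed methylation level difference (TV)
#'
#' The per-site total-variation statistic: individual level minus
#' reference-centroid level. Its sign defines direction downstream
#' (hypermethylated if positive, hypomethylated if negative).
#'
#' @param p_hat Individual methylation level.
#' @param q_hat Reference-centroid methylation level.
#' @return `p_hat - q_hat`, in `[-1, 1]`.
#' @export
tv_difference <- function(p_hat, q_hat) {
  stopifnot(all(p_hat >= 0 & p_hat <= 1), all(q_hat >= 0 & q_hat <= 1))
  p_hat - q_hat
}

#' Coverage-weighted Hellinger divergence between two methylation levels
#'
#' \deqn{HD = 2 w [(\sqrt{\hat p} - \sqrt{\hat q})^2 +
#'   (\sqrt{1-\hat p} - \sqrt{1-\hat q})^2], \quad
#'   w = \frac{n_1 n_2}{n_1 + n_2}}
#'
#' where \eqn{\hat p} is the individual level with coverage \eqn{n_1} and
#' \eqn{\hat q} the reference level with coverage \eqn{n_2}. HD is zero iff
#' the two levels agree, symmetric in its arguments, and scales linearly in
#' the harmonic coverage weight `w`, so deeply covered disagreements score
#' higher than shallow ones.
#'
#' @param p_hat,n_sample Individual level and coverage.
#' @param q_hat,n_ref Reference level and (pooled) coverage.
#' @return Non-negative numeric vector.
#' @export
hellinger_divergence <- function(p_hat, n_sample, q_hat, n_ref) {
  stopifnot(all(p_hat >= 0 & p_hat <= 1), all(q_hat >= 0 & q_hat <= 1),
            all(n_sample >= 1), all(n_ref >= 1))
  w <- n_sample * n_ref / (n_sample + n_ref)
  2 * w * ((sqrt(p_hat) - sqrt(q_hat))^2 +
             (sqrt(1 - p_hat) - sqrt(1 - q_hat))^2)
}

#' Pool reference samples into a per-site centroid
#'
#' Sums methylated and unmethylated counts element-wise over the reference
#' (wild-type) samples at each `(chrom, pos, strand)` and records the
#' centroid level `q_hat`. A site present in any reference sample
#' contributes; sites absent from all references are (by construction)
#' excluded.
#'
#' @param counts Multi-sample count tibble.
#' @param ref_samples Character vector of sample ids to pool (default: all
#'   samples present). At least 2 are required.
#' @return Tibble `chrom, pos, strand, context, n_meth_ref, n_unmeth_ref,
#'   q_hat`.
#' @export
pool_reference <- function(counts, ref_samples = NULL) {
  if (is.null(ref_samples)) ref_samples <- unique(counts$sample_id)
  if (length(ref_samples) < 2L) {
    abort("pool_reference needs >= 2 reference samples (a single sample is not a population centroid)")
  }
  counts |>
    filter(.data$sample_id %in% ref_samples) |>
    group_by(.data$chrom, .data$pos, .data$strand, .data$context) |>
    summarise(
      n_meth_ref = sum(.data$n_meth),
      n_unmeth_ref = sum(.data$n_unmeth),
      .groups = "drop"
    ) |>
    mutate(q_hat = .data$n_meth_ref / (.data$n_meth_ref + .data$n_unmeth_ref))
}

#' Per-site divergence of each sample against a reference centroid
#'
#' Joins each sample's counts to the pooled centroid on
#' `(chrom, pos, strand)` and computes the level `p_hat`, the signed level
#' difference `tv`, and the coverage-weighted Hellinger divergence `hd`.
#' Sites missing in either the sample or the centroid are dropped (no
#' imputation).
#'
#' @param counts Multi-sample count tibble (samples to compare).
#' @param centroid Output of [pool_reference()].
#' @return Tibble `sample_id, chrom, pos, strand, context, n_sample, n_ref,
#'   p_hat, q_hat, tv, hd`.
#' @export
divergence_table <- function(counts, centroid) {
  counts |>
    inner_join(
      select(centroid, "chrom", "pos", "strand",
             "n_meth_ref", "n_unmeth_ref", "q_hat"),
      by = c("chrom", "pos", "strand")
    ) |>
    mutate(
      n_sample = .data$n_meth + .data$n_unmeth,
      n_ref = .data$n_meth_ref + .data$n_unmeth_ref,
      p_hat = .data$n_meth / .data$n_sample,
      tv = .data$p_hat - .data$q_hat,
      hd = hellinger_divergence(.data$p_hat, .data$n_sample,
                                .data$q_hat, .data$n_ref)
    ) |>
    select("sample_id", "chrom", "pos", "strand", "context",
           "n_sample", "n_ref", "p_hat", "q_hat", "tv", "hd")
}

#' Genome-wide methylation level per context and sample
#'
#' The coverage-weighted level \eqn{\sum mC / \sum (mC + uC)} per cytosine
#' context, the usual genome-wide summary used to confirm global epigenomic
#' activity. Contexts absent from a sample are simply absent from the
#' output (missing, not zero).
#'
#' @param counts Multi-sample count tibble with `context`.
#' @return Tibble `sample_id, context, n_sites, level`.
#' @export
context_summary <- function(counts) {
  counts |>
    filter(!is.na(.data$context)) |>
    group_by(.data$sample_id, .data$context) |>
    summarise(
      n_sites = n(),
      level = sum(.data$n_meth) / sum(.data$n_meth + .data$n_unmeth),
      .groups = "drop"
    )
}

#' Bin per-site divergence into a samples-by-bins matrix
#'
#' Tiles each chromosome with non-overlapping windows (left-closed, 1-based:
#' bin `k` covers `[k*width + 1, (k+1)*width]`) and summarises per sample
#' and bin either
#' * `mean_hd_at_dmps` — the mean Hellinger divergence over the supplied
#'   DMP positions falling in the bin (0 for bins without DMPs), the
#'   vector representation used for hierarchical clustering of individuals;
#' * `sum_abs_level_diff` — the sum of `|tv|` over (differentially
#'   methylated) sites in the bin, the heatmap statistic.
#'
#' @param div Divergence tibble from [divergence_table()].
#' @param positions Optional tibble `chrom, pos` restricting to a DMP set;
#'   required for `mean_hd_at_dmps`.
#' @param width Bin width in bp (default 2000).
#' @param statistic One of `"mean_hd_at_dmps"`, `"sum_abs_level_diff"`.
#' @return A `bin_matrix` object: samples x bins numeric matrix with bin
#'   metadata; use `as.matrix()` to extract the matrix.
#' @export
bin_matrix <- function(div, positions = NULL, width = 2000,
                       statistic = c("mean_hd_at_dmps", "sum_abs_level_diff")) {
  statistic <- match.arg(statistic)
  stopifnot(width >= 1)
  if (statistic == "mean_hd_at_dmps" && is.null(positions)) {
    abort("mean_hd_at_dmps requires a DMP position set")
  }
  sub <- div
  if (!is.null(positions)) {
    sub <- semi_join(div, distinct(positions, .data$chrom, .data$pos),
                     by = c("chrom", "pos"))
  }
  # complete tiling over the extent of the full divergence table
  extents <- div |>
    group_by(.data$chrom) |>
    summarise(max_pos = max(.data$pos), .groups = "drop")
  bins <- extents |>
    mutate(bin_idx = purrr::map(.data$max_pos,
                                ~ seq_len(ceiling(.x / width)) - 1L)) |>
    tidyr::unnest("bin_idx") |>
    mutate(
      bin_start = .data$bin_idx * width + 1L,
      bin_end = (.data$bin_idx + 1L) * width,
      bin_id = paste0(.data$chrom, ":", .data$bin_start, "-", .data$bin_end)
    ) |>
    select("chrom", "bin_start", "bin_end", "bin_id")
  samples <- sort(unique(div$sample_id))
  stat_tab <- sub |>
    mutate(bin_id = paste0(.data$chrom, ":",
                           ((.data$pos - 1L) %/% width) * width + 1L, "-",
                           ((.data$pos - 1L) %/% width + 1L) * width)) |>
    group_by(.data$sample_id, .data$bin_id) |>
    summarise(
      value = if (statistic == "mean_hd_at_dmps") mean(.data$hd)
              else sum(abs(.data$tv)),
      .groups = "drop"
    )
  mat <- matrix(0, nrow = length(samples), ncol = nrow(bins),
                dimnames = list(samples, bins$bin_id))
  idx <- cbind(match(stat_tab$sample_id, samples),
               match(stat_tab$bin_id, bins$bin_id))
  keep <- !is.na(idx[, 2])
  mat[idx[keep, , drop = FALSE]] <- stat_tab$value[keep]
  structure(
    list(matrix = mat, bins = bins, width = width, statistic = statistic),
    class = "bin_matrix"
  )
}

#' @export
as.matrix.bin_matrix <- function(x, ...) x$matrix

#' @export
print.bin_matrix <- function(x, ...) {
  cat("<bin_matrix> ", nrow(x$matrix), " samples x ", ncol(x$matrix),
      " bins (", x$width, " bp, ", x$statistic, ")\n", sep = "")
  invisible(x)
}

#' Aggregate methylation divergence per gene
#'
#' Sums (default) or averages the Hellinger divergence over each gene's
#' extended region, giving the per-gene methylation divergence (MD) used in
#' expression-association analysis.
#'
#' @param div Divergence tibble.
#' @param annotation Annotation tibble with extended gene regions.
#' @param stat `"sum"` (default) or `"mean"`.
#' @return Tibble `gene_id, md` (one row per gene with any covered site).
#' @export
md_per_gene <- function(div, annotation, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  genes <- filter(annotation, .data$feature_class == "genic")
  hits <- join_sites_to_regions(
    distinct(div, .data$chrom, .data$pos, .keep_all = TRUE) |>
      select("chrom", "pos"),
    genes, use_extended = TRUE
  )
  div |>
    inner_join(hits, by = c("chrom", "pos"), relationship = "many-to-many") |>
    group_by(gene_id = .data$feature_id) |>
    summarise(md = if (stat == "sum") sum(.data$hd) else mean(.data$hd),
              .groups = "drop")
}

# Interval join of point sites to annotation regions via IRanges.
# Returns tibble chrom, pos, feature_id (one row per overlap).
join_sites_to_regions <- function(sites, regions, use_extended = FALSE) {
  if (nrow(sites) == 0L || nrow(regions) == 0L) {
    return(tibble(chrom = character(), pos = integer(),
                  feature_id = character()))
  }
  s <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos, sites$pos))
  start <- if (use_extended) regions$extended_start else regions$start
  end <- if (use_extended) regions$extended_end else regions$end
  r <- GenomicRanges::GRanges(regions$chrom, IRanges::IRanges(start, end))
  ov <- GenomicRanges::findOverlaps(s, r, ignore.strand = TRUE)
  tibble(
    chrom = sites$chrom[S4Vectors::queryHits(ov)],
    pos = sites$pos[S4Vectors::queryHits(ov)],
    feature_id = regions$feature_id[S4Vectors::subjectHits(ov)]
  )
}
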