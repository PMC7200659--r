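#' Count DMPs per gene extended region and sample
#'
#' Tallies, for every gene's body ±1 kb extended region and every sample,
#' the number of DMPs the sample carries there. Include the control
#' samples' spontaneous DMPs so both groups have counts for the GLM.
#'
#' @param dmps DMP tibble with `sample_id, chrom, pos` (e.g.
#'   `bind_rows(fit$dmps, fit$spontaneous)` from [dmp_pipeline()]).
#' @param annotation Annotation tibble with extended gene regions.
#' @param sample_ids Samples to include as columns (default: those present
#'   in `dmps`; pass the full manifest ids so zero-count samples appear).
#' @param region `"extended"` (body ±1 kb, default) or `"body"`.
#' @return A `gene_count_matrix`: list with `counts` (genes x samples
#'   integer matrix), `region_kb` (named lengths in kb), `region`.
#' @export
count_dmps_per_region <- function(dmps, annotation, sample_ids = NULL,
                                  region = c("extended", "body")) {
  region <- match.arg(region)
  genes <- filter(annotation, .data$feature_class == "genic")
  if (is.null(sample_ids)) sample_ids <- sort(unique(dmps$sample_id))
  use_ext <- region == "extended"
  hits <- join_sites_to_regions(distinct(dmps, .data$chrom, .data$pos),
                                genes, use_extended = use_ext)
  tall <- dmps |>
    inner_join(hits, by = c("chrom", "pos"), relationship = "many-to-many") |>
    count(.data$feature_id, .data$sample_id, name = "n")
  mat <- matrix(0L, nrow = nrow(genes), ncol = length(sample_ids),
                dimnames = list(genes$feature_id, sample_ids))
  idx <- cbind(match(tall$feature_id, genes$feature_id),
               match(tall$sample_id, sample_ids))
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  mat[idx[keep, , drop = FALSE]] <- tall$n[keep]
  len <- if (use_ext) {
    genes$extended_end - genes$extended_start + 1L
  } else {
    genes$end - genes$start + 1L
  }
  structure(
    list(counts = mat, region_kb = setNames(len / 1000, genes$feature_id),
         region = region),
    class = "gene_count_matrix"
  )
}

#' @export
print.gene_count_matrix <- function(x, ...) {
  cat("<gene_count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", x$region, " regions)\n", sep = "")
  invisible(x)
}

#' Filter genes by DMP density
#'
#' A candidate differentially methylated gene must reach a minimum DMP
#' density (default 2.5 per kb, "at least": boundary included) in each
#' sample under the chosen scope. The default scope `each_treatment`
#' requires the density in every treatment-group sample (the group whose
#' DMGs are sought); `each_sample` applies the rule to all columns,
#' `any_sample` to at least one, `group_mean` to the treatment group mean.
#'
#' @param gcm A [count_dmps_per_region()] result.
#' @param min_density Minimum DMPs per kb (default 2.5).
#' @param scope One of `"each_treatment"`, `"each_sample"`,
#'   `"any_sample"`, `"group_mean"`.
#' @param groups Named character vector `sample_id -> group`; required for
#'   the treatment-aware scopes.
#' @return Character vector of retained gene ids.
#' @export
density_filter <- function(gcm, min_density = 2.5,
                           scope = c("each_treatment", "each_sample",
                                     "any_sample", "group_mean"),
                           groups = NULL) {
  scope <- match.arg(scope)
  dens <- sweep(gcm$counts, 1, gcm$region_kb[rownames(gcm$counts)], "/")
  cols <- colnames(dens)
  if (scope %in% c("each_treatment", "group_mean")) {
    if (is.null(groups)) {
      abort(paste0("scope '", scope, "' needs the sample groups"))
    }
    trt <- cols[groups[cols] == "treatment"]
    if (length(trt) == 0L) abort("no treatment samples in the matrix")
    dens <- dens[, trt, drop = FALSE]
  }
  ok <- switch(scope,
    each_treatment = ,
    each_sample = rowSums(dens >= min_density) == ncol(dens),
    any_sample = rowSums(dens >= min_density) >= 1,
    group_mean = rowMeans(dens) >= min_density
  )
  rownames(dens)[ok]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

# Fit one gene's count GLM and return (p, model_used). The group effect is
# a Wald test on the log-link coefficient; when one group's total count is
# zero the Wald statistic degenerates (complete separation drives the
# coefficient to -Inf), so the likelihood-ratio test is used instead.
fit_gene_glm <- function(y, g, mv_rate, model) {
  if (model == "auto") {
    m <- mean(y)
    v_within <- mean(tapply(y, g, stats::var), na.rm = TRUE)
    model <- if (!is.finite(v_within) || v_within == 0 ||
                   m / v_within >= mv_rate) "poisson" else "negbinomial"
  }
  separated <- any(tapply(y, g, sum) == 0)
  p_from <- function(fit, fit0) {
    if (separated) {
      stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                    lower.tail = FALSE)
    } else {
      summary(fit)$coefficients[2, 4]
    }
  }
  if (model %in% c("poisson", "quasipoisson")) {
    fam <- if (model == "poisson") poisson() else quasipoisson()
    fit <- glm(y ~ g, family = fam)
    fit0 <- glm(y ~ 1, family = fam)
    return(list(p = p_from(fit, fit0), model_used = model))
  }
  nb <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ g)),
    error = function(e) NULL
  )
  if (is.null(nb) || separated) {
    fit <- glm(y ~ g, family = quasipoisson())
    fit0 <- glm(y ~ 1, family = quasipoisson())
    return(list(p = p_from(fit, fit0), model_used = "quasipoisson"))
  }
  list(p = summary(nb)$coefficients[2, 4], model_used = "negbinomial")
}

#' GLM test of group DMP counts per gene (DMG calling)
#'
#' Per gene, tests the difference between group DMP counts with a
#' log-link count GLM and a Wald test on the group coefficient. The model
#' is chosen per gene by the mean/variance rate: Poisson when
#' `mean/variance >= mv_rate` (default 0.95), negative binomial otherwise
#' (quasi-Poisson available by flag or as fallback when the NB fit does
#' not converge). A gene is a DMG when `|log2fc| > 1` and BH-adjusted
#' `p < 0.05` (and it passed the density filter upstream). The log2 fold
#' change of group means uses a 0.5 continuity guard on both means when
#' either is zero.
#'
#' @param gcm A [count_dmps_per_region()] result.
#' @param groups Named character vector `sample_id -> group`
#'   (`control` / `treatment`).
#' @param genes Optional gene subset (e.g. from [density_filter()]);
#'   default all genes with a nonzero count.
#' @param mv_rate Minimum mean/variance rate for the Poisson model.
#' @param log2fc_min,padj_max DMG thresholds.
#' @param model `"auto"` (default), `"poisson"`, `"quasipoisson"`, or
#'   `"negbinomial"`.
#' @return Tibble `gene_id, mean_control, mean_treatment, log2fc,
#'   model_used, p, padj, is_dmg`, BH-adjusted across the tested genes.
#' @export
glm_count_test <- function(gcm, groups, genes = NULL, mv_rate = 0.95,
                           log2fc_min = 1, padj_max = 0.05,
                           model = c("auto", "poisson", "quasipoisson",
                                     "negbinomial")) {
  model <- match.arg(model)
  mat <- gcm$counts
  g <- factor(groups[colnames(mat)], levels = c("control", "treatment"))
  if (any(is.na(g))) abort("every sample column needs a group")
  if (min(table(g)) < 2L) abort("need >= 2 samples per group")
  if (is.null(genes)) genes <- rownames(mat)[rowSums(mat) > 0]
  genes <- genes[rowSums(mat[genes, , drop = FALSE]) > 0] # all-zero: excluded
  res <- purrr::map_dfr(genes, function(gene) {
    y <- mat[gene, ]
    fit <- fit_gene_glm(y, g, mv_rate, model)
    mc <- mean(y[g == "control"])
    mt <- mean(y[g == "treatment"])
    guard <- if (mc == 0 || mt == 0) 0.5 else 0
    tibble(
      gene_id = gene, mean_control = mc, mean_treatment = mt,
      log2fc = log2((mt + guard) / (mc + guard)),
      model_used = fit$model_used, p = fit$p
    )
  })
  if (nrow(res) == 0L) {
    return(mutate(res, padj = numeric(), is_dmg = logical()))
  }
  res |>
    mutate(
      padj = bh_adjust(.data$p),
      is_dmg = abs(.data$log2fc) > log2fc_min & .data$padj < padj_max
    )
}

#' Full DMG pipeline: counts, density filter, GLM
#'
#' @param dmps DMP tibble (treatment and spontaneous calls of all samples).
#' @param annotation Annotation tibble.
#' @param manifest Manifest with `sample_id, group`.
#' @param min_density,scope Passed to [density_filter()].
#' @param ... Passed to [glm_count_test()].
#' @return List: `results` (tibble), `gcm`, `dense_genes`.
#' @export
dmg_test <- function(dmps, annotation, manifest, min_density = 2.5,
                     scope = "each_treatment", ...) {
  groups <- setNames(manifest$group, manifest$sample_id)
  gcm <- count_dmps_per_region(dmps, annotation,
                               sample_ids = manifest$sample_id)
  dense <- density_filter(gcm, min_density = min_density, scope = scope,
                          groups = groups)
  results <- if (length(dense) == 0L) {
    tibble(gene_id = character(), mean_control = numeric(),
           mean_treatment = numeric(), log2fc = numeric(),
           model_used = character(), p = numeric(), padj = numeric(),
           is_dmg = logical())
  } else {
    glm_count_test(gcm, groups, genes = dense, ...)
  }
  list(results = results, gcm = gcm, dense_genes = dense)
}

#' Intersect per-generation DMG lists and count recurrence
#'
#' The heritable set is the intersection of all per-generation DMG lists;
#' the recurrence count records, for every gene in the union, how many
#' lists contain it (the basis of "detected in at least k generations"
#' summaries).
#'
#' @param dmg_lists List (>= 2) of character vectors of gene ids.
#' @return List: `heritable` (intersection), `recurrence` (tibble
#'   `gene_id, n_lists`), `at_least` (tibble `k, n_genes, frac_first_list`
#'   — fraction of the first list's genes in at least `k` lists).
#' @export
heritable_set <- function(dmg_lists) {
  if (length(dmg_lists) < 2L) abort("need >= 2 gene lists")
  heritable <- Reduce(intersect, dmg_lists)
  all_genes <- unique(unlist(dmg_lists))
  n_lists <- rowSums(vapply(dmg_lists, function(l) all_genes %in% l,
                            logical(length(all_genes))))
  rec <- tibble(gene_id = all_genes, n_lists = as.integer(n_lists))
  first <- dmg_lists[[1]]
  first_counts <- rec$n_lists[match(first, rec$gene_id)]
  at_least <- tibble(
    k = seq_along(dmg_lists),
    n_genes = vapply(seq_along(dmg_lists),
                     function(k) sum(rec$n_lists >= k), integer(1)),
    frac_first_list = vapply(seq_along(dmg_lists),
                             function(k) mean(first_counts >= k), numeric(1))
  )
  list(heritable = sort(heritable), recurrence = rec, at_least = at_least)
}

#' Closed-form recurrence probabilities under random gene lists
#'
#' For a gene in the first list, membership in each other list `j` is
#' independent Bernoulli with probability `n_j / universe_n` (uniform
#' sampling without replacement within a list), so the number of *other*
#' lists containing it is Poisson-binomial. Returns the exact probability
#' that a first-list gene appears in at least `k` of the lists
#' (membership count includes the first list).
#'
#' @param universe_n Size of the gene universe.
#' @param list_sizes Integer vector of list sizes (first list first).
#' @return Tibble `k, prob` for `k = 1..length(list_sizes)`.
#' @export
recurrence_closed_form <- function(universe_n, list_sizes) {
  stopifnot(all(list_sizes <= universe_n), length(list_sizes) >= 2)
  p <- list_sizes[-1] / universe_n
  f <- 1
  for (pi in p) {
    f <- c(f * (1 - pi), 0) + c(0, f * pi)
  }
  # f[x + 1] = P(X = x), X = number of other lists containing the gene
  k <- seq_along(list_sizes)
  tibble(k = k, prob = vapply(k, function(kk) sum(f[kk:length(f)]),
                              numeric(1)))
}

#' Monte-Carlo recurrence simulation for random gene lists
#'
#' Draws each gene list uniformly without replacement from the universe,
#' counts for every first-list gene how many of the lists contain it, and
#' averages over replicates the fraction present in at least `k` lists
#' (k = 2..K) and the number present in all lists. Optionally compares an
#' observed recurrence histogram (counts of first-list genes in exactly
#' 1..K lists) against the simulated expectation with a Pearson
#' chi-squared test.
#'
#' @param universe_n Gene universe size.
#' @param list_sizes Integer vector of list sizes (first list first).
#' @param reps Monte-Carlo replicates (>= 100 recommended).
#' @param seed Seed.
#' @param observed_histogram Optional integer vector of length K: observed
#'   counts of first-list genes in exactly 1..K lists.
#' @return A `recurrence_sim` list: `fraction_in_ge_k` (named k=2..K, as
#'   fractions), `count_in_all`, `expected_histogram` (probabilities of
#'   exactly-k bins), `chi2_stat`, `chi2_p` (when an observed histogram is
#'   supplied), `reps`, `closed_form` (from [recurrence_closed_form()]).
#' @export
recurrence_simulation <- function(universe_n, list_sizes, reps = 200,
                                  seed = 1, observed_histogram = NULL) {
  if (any(list_sizes > universe_n)) {
    abort("list size exceeds the gene universe")
  }
  K <- length(list_sizes)
  with_child_seed(seed, "recurrence", {
    ge_k <- matrix(0, nrow = reps, ncol = K)
    exact_k <- matrix(0, nrow = reps, ncol = K)
    for (r in seq_len(reps)) {
      member <- integer(universe_n)
      first <- sample.int(universe_n, list_sizes[1])
      member[first] <- 1L
      for (j in 2:K) {
        lj <- sample.int(universe_n, list_sizes[j])
        member[lj] <- member[lj] + 1L
      }
      counts <- member[first]
      tab <- tabulate(counts, nbins = K)
      exact_k[r, ] <- tab / length(first)
      ge_k[r, ] <- rev(cumsum(rev(tab))) / length(first)
    }
    frac_ge <- colMeans(ge_k)
    expected <- colMeans(exact_k)
    out <- list(
      fraction_in_ge_k = setNames(frac_ge[2:K], paste0("ge", 2:K)),
      count_in_all = frac_ge[K] * list_sizes[1],
      expected_histogram = setNames(expected, paste0("k", seq_len(K))),
      reps = reps,
      closed_form = recurrence_closed_form(universe_n, list_sizes)
    )
    if (!is.null(observed_histogram)) {
      stopifnot(length(observed_histogram) == K)
      chi <- suppressWarnings(
        stats::chisq.test(observed_histogram, p = expected, rescale.p = TRUE)
      )
      out$chi2_stat <- unname(chi$statistic)
      out$chi2_p <- chi$p.value
    }
    structure(out, class = "recurrence_sim")
  })
}

#' @export
print.recurrence_sim <- function(x, ...) {
  cat("<recurrence_sim> ", x$reps, " replicates; fraction of first-list ",
      "genes in >= k lists:\n", sep = "")
  print(round(100 * x$fraction_in_ge_k, 3))
  cat("expected count in all lists: ", round(x$count_in_all, 2), "\n",
      sep = "")
  invisible(x)
}

#' Two-by-two enrichment with Fisher's exact test
#'
#' @param hit_set,n_set Hits and size of the focal set.
#' @param hit_universe,n_universe Hits and size of the whole universe
#'   (including the set).
#' @return List: `table` (2x2), `prop_set`, `prop_universe`, `odds_ratio`,
#'   `p`.
#' @export
enrichment_2x2 <- function(hit_set, n_set, hit_universe, n_universe) {
  stopifnot(hit_set <= n_set, hit_universe <= n_universe,
            n_set <= n_universe, hit_set <= hit_universe)
  tab <- matrix(c(hit_set, n_set - hit_set,
                  hit_universe - hit_set,
                  (n_universe - n_set) - (hit_universe - hit_set)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_set", "rest"), c("hit", "no_hit")))
  ft <- stats::fisher.test(tab)
  list(table = tab, prop_set = hit_set / n_set,
       prop_universe = hit_universe / n_universe,
       odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Transposable-element proximity enrichment of a gene set
#'
#' A gene is TE-proximal if the gap between its body and the nearest TE is
#' at most `dist` bp (overlap counts as gap 0). Tests whether the focal
#' gene set is enriched in TE-proximal genes relative to the remaining
#' universe with Fisher's exact test.
#'
#' @param gene_set Character vector of gene ids (subset of the universe).
#' @param annotation Annotation tibble with genic and TE_related features.
#' @param universe Gene ids forming the universe (default: all genic
#'   features in the annotation).
#' @param dist Maximum gap in bp (default 1000).
#' @return List from [enrichment_2x2()] plus `proximal_genes`.
#' @export
te_proximity_enrichment <- function(gene_set, annotation, universe = NULL,
                                    dist = 1000) {
  genes <- filter(annotation, .data$feature_class == "genic")
  if (is.null(universe)) universe <- genes$feature_id
  if (length(gene_set) == 0L || length(universe) == 0L) {
    abort("empty gene set or universe")
  }
  stopifnot(all(gene_set %in% universe))
  genes <- filter(genes, .data$feature_id %in% universe)
  tes <- filter(annotation, .data$feature_class == "TE_related")
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  t_gr <- GenomicRanges::GRanges(tes$chrom,
                                 IRanges::IRanges(tes$start, tes$end))
  d <- GenomicRanges::distanceToNearest(g_gr, t_gr, ignore.strand = TRUE)
  gap <- rep(Inf, length(g_gr))
  gap[S4Vectors::queryHits(d)] <- S4Vectors::elementMetadata(d)$distance
  proximal <- genes$feature_id[gap <= dist]
  res <- enrichment_2x2(
    hit_set = sum(gene_set %in% proximal), n_set = length(gene_set),
    hit_universe = length(proximal), n_universe = length(universe)
  )
  res$proximal_genes <- proximal
  res
}
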