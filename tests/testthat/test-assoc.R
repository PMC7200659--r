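test_that("Ward clustering heights are permutation-invariant and duplicates merge first", {
  set.seed(12)
  m <- matrix(rnorm(8 * 20), nrow = 8,
              dimnames = list(paste0("s", 1:8), NULL))
  m[2, ] <- m[1, ] # duplicate rows
  cl <- hierarchical_cluster(m)
  expect_equal(min(cl$merge_heights), 0)
  first_pair <- cl$hclust$merge[1, ]
  expect_setequal(-first_pair, c(1, 2))
  expect_true(all(diff(cl$merge_heights) >= -1e-10))
  perm <- sample(8)
  cl2 <- hierarchical_cluster(m[perm, ])
  expect_equal(sort(cl2$merge_heights), sort(cl$merge_heights))
  expect_setequal(cl2$leaf_order, cl$leaf_order)
  expect_error(hierarchical_cluster(m[1:2, ]), ">= 3")
  expect_warning(hierarchical_cluster(matrix(0, 4, 3)), "all-zero")
  # newick export carries every leaf
  nwk <- as_newick(cl)
  expect_true(all(vapply(rownames(m), grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})

test_that("wild-type samples form their own clade on generation-1 data", {
  hits <- 0
  for (s in 1:10) {
    cfg <- synth_config(n_chrom = 1, chrom_len = 150000, n_genes = 30,
                        n_tes = 15, n_other = 3, target_gene_count = 12,
                        n_per_group = 4, seed = 100 + s)
    g <- build_toy_genome(cfg)
    exp1 <- suppressMessages(simulate_generations(
      g, modifyList(cfg, list(n_generations = 1))))
    gen1 <- exp1$generations[[1]]
    cen <- pool_reference(
      gen1$counts, gen1$design$sample_id[gen1$design$group == "control"])
    div <- divergence_table(gen1$counts, cen)
    pos <- dplyr::distinct(gen1$truth$induced_sites, chrom, pos)
    bm <- bin_matrix(div, positions = pos, statistic = "mean_hd_at_dmps")
    cl <- hierarchical_cluster(bm)
    clades <- cut_clades(cl, 2)
    wt <- gen1$design$sample_id[gen1$design$phenotype == "WT"]
    wt_clades <- clades[wt]
    other_clades <- clades[setdiff(names(clades), wt)]
    if (length(unique(wt_clades)) == 1 &&
          !any(other_clades == wt_clades[1])) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("PCA-LDA separates shifted classes and collapses under permutation", {
  set.seed(13)
  n_per <- 8
  m <- rbind(
    matrix(rnorm(n_per * 30, mean = 0), nrow = n_per),
    matrix(rnorm(n_per * 30, mean = 4), nrow = n_per)
  )
  rownames(m) <- paste0("s", 1:(2 * n_per))
  labels <- rep(c("wt", "memory"), each = n_per)
  fit <- pca_lda(m, labels)
  expect_equal(fit$loo_accuracy, 1)
  # permuted labels: near chance
  perm_acc <- replicate(3, {
    pca_lda(m, sample(labels))$loo_accuracy
  })
  expect_lt(mean(perm_acc), 0.8)
  # feature permutation leaves accuracy unchanged
  fit2 <- pca_lda(m[, sample(30)], labels)
  expect_equal(fit2$loo_accuracy, fit$loo_accuracy)
  expect_error(pca_lda(m, rep("a", 16)), "2 classes")
})

test_that("memory and nonmemory lines are discriminable from binned divergence", {
  s <- shared_sim()
  cfg1 <- modifyList(s$cfg, list(n_generations = 1))
  exp1 <- suppressMessages(simulate_generations(s$genome, cfg1))
  gen1 <- exp1$generations[[1]]
  cen <- pool_reference(
    gen1$counts, gen1$design$sample_id[gen1$design$group == "control"])
  div <- divergence_table(gen1$counts, cen)
  pos <- dplyr::distinct(gen1$truth$induced_sites, chrom, pos)
  bm <- bin_matrix(div, positions = pos, statistic = "mean_hd_at_dmps")
  keep <- gen1$design$phenotype %in% c("MM", "NM")
  ids <- gen1$design$sample_id[keep]
  fit <- pca_lda(as.matrix(bm)[ids, ],
                 gen1$design$phenotype[keep], var_explained = 0.9)
  expect_gte(fit$loo_accuracy, 0.9)
})

test_that("Spearman rho matches rank-then-Pearson and detects monotone signals", {
  set.seed(14)
  md <- tibble::tibble(gene_id = paste0("g", 1:200),
                       md = rexp(200) + 0.01)
  # perfectly monotone decreasing for the up stratum
  expr <- tibble::tibble(
    gene_id = md$gene_id,
    log2fc = c(1 / md$md[1:100], -abs(rnorm(100))),
    padj = runif(200)
  )
  res <- suppressWarnings(md_expression_assoc(md, expr))
  expect_equal(res$spearman_rho_up, -1)
  manual <- cor(rank(md$md[1:100]), rank(abs(expr$log2fc[1:100])))
  expect_equal(res$spearman_rho_up, manual, tolerance = 1e-12)
  expect_true(abs(res$spearman_rho_down) <= 1)
})

test_that("linear-by-linear statistic matches the trend formula and the null", {
  # 2x2 grid check against the classic Mantel-Haenszel trend statistic
  set.seed(15)
  u <- sample(1:2, 300, replace = TRUE)
  v <- ifelse(runif(300) < 0.3 + 0.3 * (u == 2), 2, 1)
  got <- memsig:::linear_by_linear(u, v)
  tab <- table(u, v)
  expect_equal(got$stat, mh_trend_2x2(unclass(tab)), tolerance = 1e-9)
  # independent data: small statistic, non-extreme p
  md <- tibble::tibble(gene_id = paste0("g", 1:500), md = rexp(500))
  expr <- tibble::tibble(gene_id = md$gene_id,
                         log2fc = rnorm(500), padj = runif(500))
  res <- md_expression_assoc(md, expr)
  expect_gt(res$lbl_p, 0.001)
})

test_that("interval join applies the gap rule and overlap counts", {
  ann <- make_annotation() # geneA body [2000, 4000]
  expect_equal(interval_join(tibble::tibble(chrom = "chr1", start = 500L,
                                            end = 999L), ann),
               "geneA") # gap 1000
  expect_equal(interval_join(tibble::tibble(chrom = "chr1", start = 500L,
                                            end = 998L), ann),
               character(0)) # gap 1001
  expect_equal(interval_join(tibble::tibble(chrom = "chr1", start = 2500L,
                                            end = 2600L), ann),
               "geneA") # cluster inside gene
})

test_that("set overlap reports intersection sizes and fractions", {
  ov <- set_overlap(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(ov$n, 2L)
  expect_equal(ov$frac_a, 2 / 3)
  expect_equal(ov$frac_b, 2 / 3)
  expect_equal(set_overlap(c("A"), c("B"))$n, 0L)
  expect_equal(set_overlap(c("A", "B"), c("A", "B", "C"))$n, 2L)
})

test_that("tidiers return the documented one-row and per-term shapes", {
  fit <- shared_fit()
  m <- fit$models$model[[1]]
  expect_equal(tidy(m)$term, c("shape", "scale"))
  expect_equal(glance(m)$hd_crit, m$hd_crit)
  expect_equal(nrow(tidy(fit$cutpoint)), 1L)
  sim <- recurrence_simulation(100, c(20, 20, 20), reps = 50, seed = 2)
  td <- tidy(sim)
  expect_equal(td$k, 2:3)
  expect_equal(glance(sim)$reps, 50)
})
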