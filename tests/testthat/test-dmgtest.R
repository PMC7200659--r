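test_that("DMP counting respects extended-region boundaries", {
  ann <- make_annotation() # geneA extended [1000, 5000]
  dmps <- tibble::tibble(
    sample_id = c("a", "a", "a", "b"),
    chrom = "chr1", pos = c(1500L, 4999L, 999L, 1500L)
  )
  gcm <- count_dmps_per_region(dmps, ann, sample_ids = c("a", "b"))
  expect_equal(gcm$counts["geneA", "a"], 2L) # 999 outside
  expect_equal(gcm$counts["geneA", "b"], 1L)
  expect_equal(gcm$counts["geneB", "a"], 0L)
  expect_equal(unname(gcm$region_kb["geneA"]), 4.001)
  # body-only counting is narrower: geneA body [2000,4000] holds none of
  # the positions
  gcm_body <- count_dmps_per_region(dmps, ann, sample_ids = c("a", "b"),
                                    region = "body")
  expect_equal(sum(gcm_body$counts["geneA", ]), 0L)
})

test_that("density filter applies the at-least rule per scope", {
  gcm <- structure(list(
    counts = matrix(c(12L, 9L, 11L, 13L,
                      12L, 11L, 10L, 13L), nrow = 2, byrow = TRUE,
                    dimnames = list(c("g1", "g2"),
                                    c("t1", "t2", "t3", "t4"))),
    region_kb = c(g1 = 4, g2 = 4), region = "extended"
  ), class = "gene_count_matrix")
  groups <- setNames(rep("treatment", 4), paste0("t", 1:4))
  # threshold 2.5/kb * 4 kb = 10: g2 passes everywhere (10 exactly counts),
  # g1 fails with a 9
  expect_equal(density_filter(gcm, scope = "each_sample"), "g2")
  expect_equal(density_filter(gcm, scope = "each_treatment",
                              groups = groups), "g2")
  expect_setequal(density_filter(gcm, scope = "any_sample"), c("g1", "g2"))
  expect_setequal(density_filter(gcm, scope = "group_mean",
                                 groups = groups), c("g1", "g2"))
  expect_error(density_filter(gcm, scope = "each_treatment"), "groups")
})

test_that("Poisson branch reproduces the hand-computed Wald example", {
  gcm <- structure(list(
    counts = matrix(c(2L, 2L, 2L, 8L, 8L, 8L), nrow = 1,
                    dimnames = list("g1", paste0("s", 1:6))),
    region_kb = c(g1 = 2), region = "extended"
  ), class = "gene_count_matrix")
  groups <- setNames(rep(c("control", "treatment"), each = 3),
                     paste0("s", 1:6))
  res <- glm_count_test(gcm, groups, model = "poisson")
  expect_equal(res$log2fc, 2)
  # z = ln 4 / sqrt(1/6 + 1/24) ~ 3.037
  expect_equal(res$p, 2 * pnorm(-log(4) / sqrt(1 / 6 + 1 / 24)),
               tolerance = 1e-4)
  expect_equal(res$p, 0.0024, tolerance = 0.05)
  expect_true(res$is_dmg)
  # cross-check against the exact conditional Poisson test
  expect_equal(res$p, exact_poisson_p(6, 3, 24, 3), tolerance = 0.005)
})

test_that("identical groups are never DMGs and all-zero genes are excluded", {
  gcm <- structure(list(
    counts = matrix(c(5L, 6L, 5L, 5L, 6L, 5L,
                      0L, 0L, 0L, 0L, 0L, 0L), nrow = 2, byrow = TRUE,
                    dimnames = list(c("g1", "g0"), paste0("s", 1:6))),
    region_kb = c(g1 = 2, g0 = 2), region = "extended"
  ), class = "gene_count_matrix")
  groups <- setNames(rep(c("control", "treatment"), each = 3),
                     paste0("s", 1:6))
  res <- glm_count_test(gcm, groups)
  expect_equal(res$gene_id, "g1")
  expect_equal(res$log2fc, 0)
  expect_gt(res$p, 0.9)
  expect_false(res$is_dmg)
})

test_that("overdispersed counts switch the model away from Poisson", {
  set.seed(7)
  y <- as.integer(c(rnbinom(5, mu = 10, size = 0.5),
                    rnbinom(5, mu = 40, size = 0.5)))
  gcm <- structure(list(
    counts = matrix(y, nrow = 1, dimnames = list("g1", paste0("s", 1:10))),
    region_kb = c(g1 = 2), region = "extended"
  ), class = "gene_count_matrix")
  groups <- setNames(rep(c("control", "treatment"), each = 5),
                     paste0("s", 1:10))
  res <- glm_count_test(gcm, groups)
  expect_true(res$model_used %in% c("negbinomial", "quasipoisson"))
})

test_that("Poisson GLM reaches the exact rate test's decisions", {
  # the exact conditional test is discrete, so mid-range p-values differ;
  # the two must agree on significance and on strongly significant genes
  set.seed(8)
  n_run <- 0
  agree <- 0
  for (i in 1:40) {
    yc <- rpois(4, lambda = sample(5:15, 1))
    yt <- rpois(4, lambda = sample(5:15, 1))
    if (sum(yc) < 20 || sum(yt) < 20) next
    gcm <- structure(list(
      counts = matrix(c(yc, yt), nrow = 1,
                      dimnames = list("g", paste0("s", 1:8))),
      region_kb = c(g = 2), region = "extended"
    ), class = "gene_count_matrix")
    groups <- setNames(rep(c("control", "treatment"), each = 4),
                       paste0("s", 1:8))
    res <- glm_count_test(gcm, groups, model = "poisson")
    p_exact <- exact_poisson_p(sum(yc), 4, sum(yt), 4)
    n_run <- n_run + 1
    agree <- agree + ((res$p < 0.05) == (p_exact < 0.05))
    if (p_exact < 0.01) {
      expect_lt(abs(res$p - p_exact), 0.01)
    }
  }
  expect_gt(n_run, 10)
  expect_gte(agree / n_run, 0.95)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(9)
  p <- runif(200)
  adj <- bh_adjust(p)
  expect_equal(adj, bh_stepup(p))
  expect_true(all(adj >= p))
})

test_that("heritable set logic intersects lists and counts recurrence", {
  lists <- list(c("A", "B", "C"), c("A", "B"), c("A", "C"))
  hs <- heritable_set(lists)
  expect_equal(hs$heritable, "A")
  rec <- setNames(hs$recurrence$n_lists, hs$recurrence$gene_id)
  expect_equal(unname(rec[c("A", "B", "C")]), c(3L, 2L, 2L))
  # sum over exact-count bins equals the union size
  expect_equal(sum(table(hs$recurrence$n_lists)),
               length(unique(unlist(lists))))
  expect_equal(hs$at_least$frac_first_list, c(1, 1, 1 / 3))
  expect_equal(heritable_set(list(c("x", "y"), c("z")))$heritable,
               character(0))
  expect_equal(heritable_set(list(c("a", "b"), c("a", "b")))$heritable,
               c("a", "b"))
})

test_that("closed-form recurrence matches subset enumeration and small cases", {
  # two lists of 5 from 10: P(first-list gene also in list 2) = 0.5
  cf2 <- recurrence_closed_form(10, c(5, 5))
  expect_equal(cf2$prob[cf2$k == 2], 0.5)
  # three lists: P(>= 2 of 3) = 1 - 0.5^2
  cf3 <- recurrence_closed_form(10, c(5, 5, 5))
  expect_equal(cf3$prob[cf3$k == 2], 0.75)
  # general case against independent subset enumeration
  sizes <- c(40, 25, 10, 30)
  cf <- recurrence_closed_form(100, sizes)
  p <- sizes[-1] / 100
  for (k in 2:4) {
    expect_equal(cf$prob[cf$k == k], pb_tail_enum(p, k - 1),
                 tolerance = 1e-12)
  }
})

test_that("recurrence simulation converges to the closed form", {
  sizes <- c(50, 40, 30, 35)
  sim <- recurrence_simulation(200, sizes, reps = 400, seed = 10)
  cf <- sim$closed_form
  for (k in 2:4) {
    p_true <- cf$prob[cf$k == k]
    # one replicate mean has variance <= p(1-p); 400 replicates
    se <- sqrt(p_true * (1 - p_true) / 400)
    expect_lt(abs(sim$fraction_in_ge_k[[paste0("ge", k)]] - p_true),
              3 * se + 1e-3)
  }
  # fractions non-increasing in k
  expect_true(all(diff(unname(sim$fraction_in_ge_k)) <= 1e-12))
  expect_error(recurrence_simulation(10, c(20, 5)), "exceeds")
  # chi-squared path runs when an observed histogram is supplied
  sim2 <- recurrence_simulation(200, sizes, reps = 100, seed = 1,
                                observed_histogram = c(10, 20, 15, 5))
  expect_true(is.finite(sim2$chi2_p))
})

test_that("TE proximity uses the 1 kb gap rule and Fisher enrichment", {
  ann <- tibble::tibble(
    chrom = "chr1",
    start = c(5000L, 20000L, 3500L, 18998L),
    end = c(6000L, 21000L, 4100L, 18999L),
    strand = "+",
    feature_id = c("gA", "gB", "te1", "te2"),
    subtype = c("gene", "gene", "transposable_element",
                "transposable_element"),
    feature_class = c("genic", "genic", "TE_related", "TE_related")
  ) |> memsig:::extend_genes()
  res <- te_proximity_enrichment(c("gA"), ann, dist = 1000)
  # gA gap to te1 = 899 -> proximal; gB gap to te2 = 1000 -> proximal
  expect_setequal(res$proximal_genes, c("gA", "gB"))
  # push te2 one bp farther: gap 1001 -> not proximal
  ann2 <- ann
  ann2$start[4] <- 18997L
  ann2$end[4] <- 18998L
  res2 <- te_proximity_enrichment(c("gA"), ann2, dist = 1000)
  expect_equal(res2$proximal_genes, "gA")
  expect_error(te_proximity_enrichment(character(), ann), "empty")
})

test_that("enrichment arithmetic reproduces proportions and Fisher p", {
  res <- enrichment_2x2(538, 954, 6936, 27420)
  expect_equal(round(100 * res$prop_set, 1), 56.4)
  expect_equal(round(100 * res$prop_universe, 1), 25.3)
  expect_lt(res$p, 1e-6)
  expect_gt(res$odds_ratio, 1)
})

test_that("end-to-end DMG pipeline recovers target genes on the shared fixture", {
  s <- shared_sim()
  fit <- shared_fit()
  dmg <- dmg_test(dplyr::bind_rows(fit$dmps, fit$spontaneous),
                  s$genome$annotation, s$sim$design)
  called <- dmg$results$gene_id[dmg$results$is_dmg]
  expect_gte(mean(s$sim$truth$target_genes %in% called), 0.8)
  if (length(called) > 0) {
    expect_lte(mean(!(called %in% s$sim$truth$target_genes)), 0.2)
  }
  expect_true(all(dmg$results$padj >= dmg$results$p))
})
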