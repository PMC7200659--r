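make_two_group_counts <- function(site_specs) {
  # site_specs: list of list(pos, ctrl = c(m, u) per rep, trt = ...)
  rows <- list()
  for (sp in site_specs) {
    for (i in seq_along(sp$ctrl)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = paste0("c", i), chrom = "chr1", pos = sp$pos,
        strand = "+", context = "CG",
        n_meth = sp$ctrl[[i]][1], n_unmeth = sp$ctrl[[i]][2]
      )
    }
    for (i in seq_along(sp$trt)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = paste0("t", i), chrom = "chr1", pos = sp$pos,
        strand = "+", context = "CG",
        n_meth = sp$trt[[i]][1], n_unmeth = sp$trt[[i]][2]
      )
    }
  }
  dplyr::bind_rows(rows)
}

two_group_manifest <- function(n = 3) {
  tibble::tibble(
    sample_id = c(paste0("c", 1:n), paste0("t", 1:n)),
    group = rep(c("control", "treatment"), each = n)
  )
}

test_that("Fisher caller matches hypergeometric enumeration and the conjunction rule", {
  counts <- make_two_group_counts(list(
    list(pos = 10L, ctrl = list(c(8L, 2L)), trt = list(c(2L, 8L))),
    list(pos = 20L, ctrl = list(c(5L, 5L)), trt = list(c(5L, 5L))),
    list(pos = 30L, ctrl = list(c(10L, 40L)), trt = list(c(20L, 30L)))
  ))
  mf <- two_group_manifest(1)
  res <- fisher_caller(counts, mf)
  r10 <- res[res$pos == 10, ]
  expect_equal(r10$p, fisher_enum_p(8, 2, 2, 8), tolerance = 1e-10)
  expect_equal(r10$p, 0.023, tolerance = 1e-3)
  expect_true(r10$called) # diff -0.6, p ~ 0.023
  expect_false(res$called[res$pos == 20]) # identical proportions
  # pos 30: diff 0.2 < 0.25 -> not called even though p may be small
  expect_false(res$called[res$pos == 30])
})

test_that("Fisher p equals exact enumeration for random tables with total <= 40", {
  set.seed(5)
  for (i in 1:40) {
    tot <- sample(8:40, 1)
    a <- sample(0:tot, 1)
    b <- sample(0:(tot - a), 1)
    cc <- sample(0:(tot - a - b), 1)
    d <- tot - a - b - cc
    if ((a + b) == 0 || (cc + d) == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, b, cc, d), 2,
                                       byrow = TRUE))$p.value
    expect_equal(p_pkg, fisher_enum_p(a, b, cc, d), tolerance = 1e-9)
  }
})

test_that("Wald caller evaluates the floored z statistic", {
  counts <- make_two_group_counts(list(
    # zero empirical variance: the binomial floor keeps z finite
    list(pos = 10L,
         ctrl = list(c(3L, 27L), c(3L, 27L), c(3L, 27L)),
         trt = list(c(27L, 3L), c(27L, 3L), c(27L, 3L))),
    list(pos = 20L,
         ctrl = list(c(5L, 25L), c(6L, 24L), c(4L, 26L)),
         trt = list(c(5L, 25L), c(6L, 24L), c(4L, 26L)))
  ))
  mf <- two_group_manifest(3)
  res <- wald_caller(counts, mf)
  r10 <- res[res$pos == 10, ]
  # direct formula: se^2 = (p(1-p)/90)/3 per group, diff 0.8
  se2 <- (0.1 * 0.9 / 90) / 3
  z_want <- 0.8 / sqrt(2 * se2)
  expect_equal(r10$z, z_want, tolerance = 1e-10)
  expect_true(is.finite(r10$z))
  expect_lt(r10$p, 1e-4)
  expect_true(r10$called)
  r20 <- res[res$pos == 20, ]
  expect_equal(r20$z, 0)
  expect_equal(r20$p, 1)
  expect_false(r20$called)
  expect_error(wald_caller(counts[counts$sample_id %in%
                                    c("c1", "t1", "t2"), ], mf),
               "replicates")
})

test_that("RMS statistic is zero at independence and transpose-invariant", {
  expect_equal(memsig:::rms_statistic(c(25, 25, 25, 25)), 0)
  # transposing the 2x2 permutes cells (a, c, b, d)
  cells <- c(8, 2, 2, 8)
  expect_equal(memsig:::rms_statistic(cells),
               memsig:::rms_statistic(cells[c(1, 3, 2, 4)]))
})

test_that("RMS Monte-Carlo p is within error of exhaustive enumeration", {
  counts <- make_two_group_counts(list(
    list(pos = 10L, ctrl = list(c(8L, 2L)), trt = list(c(2L, 8L)))
  ))
  mf <- two_group_manifest(1)
  n_mc <- 4000
  res <- rms_caller(counts, mf, n_mc = n_mc, seed = 99)
  p_exact <- rms_exact_p(c(8, 2, 2, 8), memsig:::rms_statistic)
  se <- sqrt(p_exact * (1 - p_exact) / n_mc)
  expect_lt(abs(res$p - p_exact), 2 * se + 2 / n_mc)
  # independence table is never called
  counts0 <- make_two_group_counts(list(
    list(pos = 10L, ctrl = list(c(25L, 25L)), trt = list(c(25L, 25L)))
  ))
  res0 <- rms_caller(counts0, mf, n_mc = 200, seed = 1)
  expect_false(res0$called)
})

test_that("signal-detection wrapper delegates to the pipeline deterministically", {
  s <- shared_sim()
  a <- suppressMessages(sd_caller(s$sim$counts, s$sim$design,
                                  diff_min = 0.25))
  b <- suppressMessages(dmp_pipeline(s$sim$counts, s$sim$design,
                                     tv_min = 0.25))
  expect_equal(a$dmps, b$dmps)
  # strict boundary: |tv| = 0.25 is excluded
  expect_true(all(abs(a$pdmp$tv) > 0.25))
})

test_that("classifier validation matches an independent confusion tally", {
  set.seed(6)
  n <- 400
  grp <- rep(c("control", "treatment"), each = n / 2)
  inst <- tibble::tibble(
    group = grp,
    hd = ifelse(grp == "treatment", rnorm(n, 8, 1), rnorm(n, 2, 1)),
    tv = ifelse(grp == "treatment", 0.5, 0.1) + rnorm(n, 0, 0.03),
    n_sample = rpois(n, 30) + 1L,
    context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE)
  )
  rep1 <- validate_dmps(inst, n_boot = 199, seed = 42)
  # separable case: perfect held-out classification
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$fdr, 0)
  expect_equal(rep1$n_test, n - rep1$n_train)
  # invariance to row order and to sample relabeling
  perm <- sample(n)
  rep2 <- validate_dmps(inst[perm, ], n_boot = 199, seed = 42)
  expect_equal(rep2$accuracy, rep1$accuracy)
  expect_equal(rep2$fdr, rep1$fdr)
  # permuted labels: near-chance accuracy
  inst_null <- inst
  inst_null$group <- sample(inst_null$group)
  rep3 <- validate_dmps(inst_null, n_boot = 199, seed = 42)
  expect_lt(rep3$accuracy, 0.65)
  expect_gt(rep3$accuracy, 0.35)
  # single-class training set errors
  expect_error(validate_dmps(dplyr::filter(inst, group == "control")),
               "single-class")
})

test_that("benchmark ranking is ordered by accuracy with stable ties", {
  mk <- function(method, acc) {
    structure(list(method = method, accuracy = acc, sensitivity = acc,
                   specificity = acc, fdr = 1 - acc, n_dmps = 10L,
                   n_train = 6L, n_test = 4L, n_boot = 9L,
                   ci = tibble::tibble(metric = "accuracy", lower = acc,
                                       upper = acc)),
              class = "classifier_report")
  }
  tab <- benchmark_compare(list(mk("a", 0.9), mk("b", 0.95), mk("c", 0.9)))
  expect_equal(tab$method, c("b", "a", "c"))
  expect_error(benchmark_compare(list()), "at least one")
})

test_that("all callers control the false-positive rate on null data", {
  cfg <- small_config(seed = 21, delta_chh_promoter = 0, delta_cg_body = 0,
                      spontaneous_rate = 0)
  g <- build_toy_genome(cfg)
  sim <- suppressMessages(simulate_counts(g, cfg))
  mf <- sim$design
  fis <- fisher_caller(sim$counts, mf)
  wal <- wald_caller(sim$counts, mf)
  rms <- rms_caller(sim$counts, mf, n_mc = 200, seed = 1)
  # pooled/replicate callers: per-site FPR at nominal alpha = 0.05
  expect_lte(mean(fis$called), 0.1)
  expect_lte(mean(wal$called), 0.1)
  expect_lte(mean(rms$called), 0.1)
  sd_fit <- suppressMessages(sd_caller(sim$counts, mf, diff_min = 0.25))
  n_tested <- sum(sd_fit$divergence$group == "treatment")
  expect_lte(nrow(sd_fit$dmps) / n_tested, 0.1)
})
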