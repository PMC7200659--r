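# Pool counts per site within each group and attach levels.
pool_by_group <- function(counts, manifest) {
  counts |>
    inner_join(select(manifest, "sample_id", "group"), by = "sample_id") |>
    group_by(.data$chrom, .data$pos, .data$strand, .data$context,
             .data$group) |>
    summarise(n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
              .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "group",
      values_from = c("n_meth", "n_unmeth"),
      values_fill = 0L
    )
}

#' Fisher exact DMP caller (pooled counts)
#'
#' Pools counts within each group per site and calls a DMP where the
#' two-sided Fisher exact test on the pooled 2x2 table is significant and
#' the pooled level difference exceeds `diff_min` in absolute value. This
#' is the classic pooled-replicate strategy of count-based DMR tools.
#'
#' @param counts Multi-sample count tibble.
#' @param manifest Manifest with `group` in `{control, treatment}`.
#' @param diff_min Minimum absolute pooled level difference (strict).
#' @param p_max p-value threshold (strict).
#' @return Per-site tibble with pooled levels, `diff`, `p` and `called`;
#'   sites failing the difference filter carry `p = NA` (not tested).
#'   Zero-coverage sites in either group are skipped.
#' @export
fisher_caller <- function(counts, manifest, diff_min = 0.25, p_max = 0.05) {
  pooled <- pool_by_group(counts, manifest) |>
    filter(.data$n_meth_control + .data$n_unmeth_control > 0,
           .data$n_meth_treatment + .data$n_unmeth_treatment > 0) |>
    mutate(
      level_control = .data$n_meth_control /
        (.data$n_meth_control + .data$n_unmeth_control),
      level_treatment = .data$n_meth_treatment /
        (.data$n_meth_treatment + .data$n_unmeth_treatment),
      diff = .data$level_treatment - .data$level_control
    )
  test_idx <- which(abs(pooled$diff) > diff_min)
  p <- rep(NA_real_, nrow(pooled))
  p[test_idx] <- vapply(test_idx, function(i) {
    m <- matrix(c(pooled$n_meth_control[i], pooled$n_unmeth_control[i],
                  pooled$n_meth_treatment[i], pooled$n_unmeth_treatment[i]),
                nrow = 2, byrow = TRUE)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  mutate(pooled, p = p,
         called = !is.na(p) & p < p_max & abs(.data$diff) > diff_min)
}

#' Wald-test DMP caller (replicate levels)
#'
#' Per site, compares the mean methylation level across replicates between
#' groups with a Wald z statistic. The group variance is the larger of the
#' across-replicate empirical variance of levels and a binomial floor
#' \eqn{\bar p (1-\bar p) / \sum n} (which also guarantees a finite
#' statistic when replicates agree exactly), divided by the number of
#' replicates. This is a moment-based stand-in for the dispersion-shrinkage
#' smoothing of replicate-aware DMR tools.
#'
#' @inheritParams fisher_caller
#' @return Per-site tibble with group means, `diff`, `z`, `p`, `called`.
#'   Sites with fewer than 2 replicates in either group are dropped.
#' @export
wald_caller <- function(counts, manifest, diff_min = 0.25, p_max = 0.05) {
  per_rep <- counts |>
    inner_join(select(manifest, "sample_id", "group"), by = "sample_id") |>
    mutate(level = .data$n_meth / (.data$n_meth + .data$n_unmeth),
           cov = .data$n_meth + .data$n_unmeth)
  stats <- per_rep |>
    group_by(.data$chrom, .data$pos, .data$strand, .data$context,
             .data$group) |>
    summarise(
      n_reps = n(), mean_level = mean(.data$level),
      var_emp = if (n() > 1) stats::var(.data$level) else NA_real_,
      total_cov = sum(.data$cov), .groups = "drop"
    ) |>
    filter(.data$n_reps >= 2) |>
    mutate(
      var_floor = .data$mean_level * (1 - .data$mean_level) /
        .data$total_cov,
      se2 = pmax(.data$var_emp, .data$var_floor) / .data$n_reps
    ) |>
    tidyr::pivot_wider(
      id_cols = c("chrom", "pos", "strand", "context"),
      names_from = "group",
      values_from = c("n_reps", "mean_level", "se2")
    )
  if (!all(c("mean_level_control", "mean_level_treatment") %in%
             names(stats))) {
    abort("wald_caller needs >= 2 replicates per group")
  }
  stats |>
    filter(!is.na(.data$mean_level_control),
           !is.na(.data$mean_level_treatment)) |>
    mutate(
      diff = .data$mean_level_treatment - .data$mean_level_control,
      z = .data$diff / sqrt(.data$se2_treatment + .data$se2_control),
      z = if_else(is.finite(.data$z), .data$z, 0),
      p = 2 * pnorm(-abs(.data$z)),
      called = .data$p < p_max & abs(.data$diff) > diff_min
    )
}

# RMS statistic on a length-4 vector (mCc, uCc, mCt, uCt) or 4 x k matrix
# of counts: root-mean-square distance of joint proportions from the
# independence table implied by the margins.
rms_statistic <- function(cells) {
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 4)
  tot <- colSums(cells)
  pi_obs <- sweep(cells, 2, tot, "/")
  row1 <- pi_obs[1, ] + pi_obs[2, ] # control margin
  col1 <- pi_obs[1, ] + pi_obs[3, ] # methylated margin
  pi_ind <- rbind(row1 * col1, row1 * (1 - col1),
                  (1 - row1) * col1, (1 - row1) * (1 - col1))
  sqrt(colSums((pi_obs - pi_ind)^2) / 4)
}

#' Root-mean-square DMP caller (pooled counts, Monte-Carlo null)
#'
#' Per site, measures the root-mean-square distance between the observed
#' joint proportions of the pooled 2x2 table and the independence table
#' implied by its margins; the null distribution is simulated by drawing
#' multinomial tables under independence with the observed margins and
#' total. The Monte-Carlo p-value uses the add-one rule
#' `(1 + #[sim >= obs]) / (1 + n_mc)` so it is never zero.
#'
#' @inheritParams fisher_caller
#' @param n_mc Number of Monte-Carlo null tables per tested site.
#' @param seed Seed for the null draws.
#' @return Per-site tibble with `diff`, `stat`, `p`, `called`; sites
#'   failing the difference filter carry `p = NA` (not tested).
#' @export
rms_caller <- function(counts, manifest, diff_min = 0.25, p_max = 0.05,
                       n_mc = 1000, seed = 1) {
  pooled <- pool_by_group(counts, manifest) |>
    filter(.data$n_meth_control + .data$n_unmeth_control > 0,
           .data$n_meth_treatment + .data$n_unmeth_treatment > 0) |>
    mutate(
      level_control = .data$n_meth_control /
        (.data$n_meth_control + .data$n_unmeth_control),
      level_treatment = .data$n_meth_treatment /
        (.data$n_meth_treatment + .data$n_unmeth_treatment),
      diff = .data$level_treatment - .data$level_control
    )
  cells_all <- rbind(pooled$n_meth_control, pooled$n_unmeth_control,
                     pooled$n_meth_treatment, pooled$n_unmeth_treatment)
  stat <- rms_statistic(cells_all)
  test_idx <- which(abs(pooled$diff) > diff_min)
  p <- rep(NA_real_, nrow(pooled))
  with_child_seed(seed, "rms_caller", {
    for (i in test_idx) {
      cells <- cells_all[, i]
      tot <- sum(cells)
      prow <- (cells[1] + cells[2]) / tot
      pcol <- (cells[1] + cells[3]) / tot
      p4 <- c(prow * pcol, prow * (1 - pcol),
              (1 - prow) * pcol, (1 - prow) * (1 - pcol))
      sim <- rmultinom(n_mc, tot, p4)
      p[i] <- (1 + sum(rms_statistic(sim) >= stat[i])) / (1 + n_mc)
    }
  })
  mutate(pooled, stat = stat, p = p,
         called = !is.na(p) & p < p_max & abs(.data$diff) > diff_min)
}

#' Signal-detection DMP caller (benchmark wrapper)
#'
#' Delegates to the full signal-detection pipeline ([dmp_pipeline()]) with
#' the benchmark's level-difference threshold, so all four callers face the
#' same difference cutoff.
#'
#' @inheritParams fisher_caller
#' @param ... Passed to [dmp_pipeline()].
#' @return The [dmp_pipeline()] result list.
#' @export
sd_caller <- function(counts, manifest, diff_min = 0.25, ...) {
  dmp_pipeline(counts, manifest, tv_min = diff_min, ...)
}

#' Build classifier instances for a called site set
#'
#' Expands a set of called positions to one instance per (site, sample)
#' with that sample's divergence features and group label — the common
#' currency on which [validate_dmps()] scores every caller.
#'
#' @param div Divergence tibble with `group` (e.g. from [dmp_pipeline()]).
#' @param positions Tibble of called positions (`chrom, pos`).
#' @return Instance tibble (subset of `div`).
#' @export
dmp_instances <- function(div, positions) {
  semi_join(div, distinct(positions, .data$chrom, .data$pos),
            by = c("chrom", "pos"))
}

classifier_features <- function(instances) {
  x <- cbind(
    hd = instances$hd,
    abs_tv = abs(instances$tv),
    log2_cov = log2(pmax(instances$n_sample, 1))
  )
  if ("context" %in% names(instances)) {
    x <- cbind(x,
               ctx_chg = as.numeric(instances$context == "CHG"),
               ctx_chh = as.numeric(instances$context == "CHH"))
  }
  x
}

confusion_metrics <- function(truth, pred) {
  tp <- sum(truth == "treatment" & pred == "treatment")
  fp <- sum(truth == "control" & pred == "treatment")
  tn <- sum(truth == "control" & pred == "control")
  fn <- sum(truth == "treatment" & pred == "control")
  c(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    fdr = if (tp + fp > 0) fp / (tp + fp) else 0
  )
}

#' Validate a DMP set by held-out classification
#'
#' Splits the (site, sample) instances 60/40 (stratified by group), trains
#' a ridge-regularized logistic model on standardized features (HD,
#' absolute level difference, log2 coverage, context indicators) on the
#' training portion, classifies the held-out portion, and cross-checks the
#' predicted group against each instance's true carrier-sample group.
#' Bootstrap resampling of the test set yields 95% percentile intervals
#' for accuracy, sensitivity, specificity and FDR.
#'
#' @param instances Tibble with `group` plus the feature columns of
#'   [dmp_instances()].
#' @param split Training fraction (default 0.6).
#' @param n_boot Bootstrap resamples (default 999).
#' @param seed Seed for the split and the bootstrap.
#' @param method Label recorded in the report.
#' @param lambda Ridge penalty (default 0.01).
#' @return A `classifier_report` with point metrics, `n_dmps`, and a `ci`
#'   tibble of 95% bootstrap intervals.
#' @export
validate_dmps <- function(instances, split = 0.6, n_boot = 999, seed = 1,
                          method = "signal_detection", lambda = 0.01) {
  stopifnot(nrow(instances) >= 5)
  y <- factor(instances$group, levels = c("control", "treatment"))
  idx_train <- with_child_seed(seed, "validate_split", {
    unlist(lapply(split(seq_along(y), y), function(ii) {
      sample(ii, floor(length(ii) * split))
    }), use.names = FALSE)
  })
  if (length(unique(y[idx_train])) < 2L) {
    abort("single-class training set: cannot fit the classifier")
  }
  x <- classifier_features(instances)
  keep_col <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (sum(keep_col) < 2L) keep_col[which(!keep_col)[1:(2 - sum(keep_col))]] <- TRUE
  x <- x[, keep_col, drop = FALSE]
  # decreasing lambda path gives glmnet warm starts; near-separable data
  # does not converge when the target penalty is fit cold
  path <- sort(unique(c(10, 3, 1, 0.3, 0.1, 0.03, lambda)),
               decreasing = TRUE)
  fit <- suppressWarnings(
    glmnet::glmnet(x[idx_train, , drop = FALSE], y[idx_train],
                   family = "binomial", alpha = 0, lambda = path,
                   standardize = TRUE, maxit = 1e6)
  )
  s_use <- max(lambda, min(fit$lambda))
  idx_test <- setdiff(seq_along(y), idx_train)
  prob <- as.numeric(predict(fit, x[idx_test, , drop = FALSE],
                             type = "response", s = s_use))
  pred <- if_else(prob >= 0.5, "treatment", "control")
  truth <- as.character(y[idx_test])
  point <- confusion_metrics(truth, pred)
  boot <- with_child_seed(seed, "validate_boot", {
    t(vapply(seq_len(n_boot), function(b) {
      ii <- sample.int(length(truth), replace = TRUE)
      confusion_metrics(truth[ii], pred[ii])
    }, numeric(4)))
  })
  ci <- tibble(
    metric = names(point),
    lower = apply(boot, 2, stats::quantile, 0.025, na.rm = TRUE),
    upper = apply(boot, 2, stats::quantile, 0.975, na.rm = TRUE)
  )
  structure(
    list(method = method,
         accuracy = unname(point["accuracy"]),
         sensitivity = unname(point["sensitivity"]),
         specificity = unname(point["specificity"]),
         fdr = unname(point["fdr"]),
         n_dmps = nrow(instances), n_train = length(idx_train),
         n_test = length(truth), n_boot = n_boot, ci = ci),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report> ", x$method, ": accuracy = ",
      signif(x$accuracy, 3), ", sensitivity = ", signif(x$sensitivity, 3),
      ", specificity = ", signif(x$specificity, 3), ", FDR = ",
      signif(x$fdr, 3), " (n = ", x$n_dmps, ")\n", sep = "")
  invisible(x)
}

#' Rank caller validation reports
#'
#' Orders classifier reports by accuracy (descending); ties keep the
#' original order. All metrics, DMP counts and bootstrap intervals are
#' carried along.
#'
#' @param reports List of `classifier_report` objects.
#' @return Ranking tibble, one row per method.
#' @export
benchmark_compare <- function(reports) {
  if (length(reports) == 0L) {
    abort("benchmark_compare requires at least one report")
  }
  tab <- purrr::map_dfr(reports, function(r) {
    ci <- tidyr::pivot_wider(r$ci, names_from = "metric",
                             values_from = c("lower", "upper"))
    bind_cols(
      tibble(method = r$method, n_dmps = r$n_dmps, accuracy = r$accuracy,
             sensitivity = r$sensitivity, specificity = r$specificity,
             fdr = r$fdr),
      ci
    )
  })
  tab[order(-tab$accuracy), ]
}

#' Run the four-caller DMP benchmark on one dataset
#'
#' Runs the Fisher, Wald, root-mean-square and signal-detection callers on
#' the same counts with a shared level-difference threshold, expands each
#' caller's positions to per-sample instances, validates each with the
#' held-out classifier, and ranks the reports.
#'
#' @inheritParams fisher_caller
#' @param n_mc Monte-Carlo draws for the RMS null.
#' @param n_boot Bootstrap resamples for validation intervals.
#' @param seed Seed for the RMS null, splits and bootstraps.
#' @param alpha Signal-detection critical-value level.
#' @return List: `reports` (per method), `ranking` (from
#'   [benchmark_compare()]), and the signal-detection `pipeline`.
#' @export
run_benchmark <- function(counts, manifest, diff_min = 0.25, p_max = 0.05,
                          n_mc = 1000, n_boot = 999, seed = 1,
                          alpha = 0.05) {
  sd_fit <- sd_caller(counts, manifest, diff_min = diff_min, alpha = alpha)
  div <- sd_fit$divergence
  callers <- list(
    fisher = filter(fisher_caller(counts, manifest, diff_min, p_max),
                    .data$called),
    wald = filter(wald_caller(counts, manifest, diff_min, p_max),
                  .data$called),
    rms = filter(rms_caller(counts, manifest, diff_min, p_max,
                            n_mc = n_mc, seed = seed), .data$called)
  )
  reports <- purrr::imap(callers, function(set, nm) {
    inst <- dmp_instances(div, set)
    validate_dmps(inst, n_boot = n_boot, seed = seed, method = nm)
  })
  sd_inst <- bind_rows(sd_fit$dmps, sd_fit$spontaneous)
  reports$signal_detection <- validate_dmps(
    select(sd_inst, dplyr::any_of(names(div))),
    n_boot = n_boot, seed = seed, method = "signal_detection"
  )
  list(reports = reports, ranking = benchmark_compare(reports),
       pipeline = sd_fit)
}
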