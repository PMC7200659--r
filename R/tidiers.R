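#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.hd_model <- function(x, ...) {
  tibble(term = c("shape", "scale"), estimate = c(x$shape, x$scale))
}

#' @export
glance.hd_model <- function(x, ...) {
  tibble(distribution = x$distribution, n_fit = x$n_fit, alpha = x$alpha,
         hd_crit = x$hd_crit, aic = x$aic, ks_stat = x$ks_stat,
         loglik = x$loglik)
}

#' @export
tidy.cutpoint_result <- function(x, ...) {
  tibble(cutoff_hd = x$cutoff_hd, youden_j = x$youden_j,
         sensitivity = x$sensitivity, specificity = x$specificity,
         n_control = x$n_control, n_treatment = x$n_treatment)
}

#' @export
glance.cutpoint_result <- tidy.cutpoint_result

#' @export
tidy.classifier_report <- function(x, ...) {
  point <- c(accuracy = x$accuracy, sensitivity = x$sensitivity,
             specificity = x$specificity, fdr = x$fdr)
  x$ci |>
    mutate(estimate = unname(point[.data$metric]), .after = "metric") |>
    mutate(method = x$method, .before = 1)
}

#' @export
glance.classifier_report <- function(x, ...) {
  tibble(method = x$method, accuracy = x$accuracy,
         sensitivity = x$sensitivity, specificity = x$specificity,
         fdr = x$fdr, n_dmps = x$n_dmps, n_train = x$n_train,
         n_test = x$n_test, n_boot = x$n_boot)
}

#' @export
tidy.recurrence_sim <- function(x, ...) {
  K <- length(x$expected_histogram)
  tibble(
    k = 2:K,
    fraction_ge_k = unname(x$fraction_in_ge_k),
    closed_form = x$closed_form$prob[2:K]
  )
}

#' @export
glance.recurrence_sim <- function(x, ...) {
  tibble(reps = x$reps, count_in_all = x$count_in_all,
         chi2_stat = x$chi2_stat %||% NA_real_,
         chi2_p = x$chi2_p %||% NA_real_)
}

#' @export
tidy.association_result <- function(x, ...) {
  tibble(
    stratum = c("up", "down"),
    spearman_rho = c(x$spearman_rho_up, x$spearman_rho_down),
    n = c(x$n_up, x$n_down)
  )
}

#' @export
glance.association_result <- function(x, ...) {
  tibble(lbl_stat = x$lbl_stat, lbl_p = x$lbl_p, n_genes = x$n_genes,
         spearman_rho_up = x$spearman_rho_up,
         spearman_rho_down = x$spearman_rho_down)
}

#' @export
tidy.pca_lda_result <- function(x, ...) {
  as_tibble(x$projections, rownames = "sample_id") |>
    mutate(label = as.character(x$labels),
           loo_pred = x$loo_pred)
}

#' @export
glance.pca_lda_result <- function(x, ...) {
  tibble(ncomp = x$ncomp, loo_accuracy = x$loo_accuracy,
         n_samples = length(x$labels), n_classes = nlevels(x$labels))
}

#' @export
tidy.cluster_result <- function(x, ...) {
  tibble(merge = seq_along(x$merge_heights), height = x$merge_heights)
}

#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_leaves = length(x$leaf_order),
         max_height = max(x$merge_heights))
}
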