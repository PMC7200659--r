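# Two-parameter gamma MLE via Newton iteration on the shape, using the
# sufficient statistics mean(x) and mean(log x): the score equation is
# log(k) - digamma(k) = log(mean) - meanlog, and scale = mean / k.
# O(1) after one pass over the data; agrees with generic numeric MLE.
gamma_mle <- function(x, max_iter = 50, tol = 1e-10) {
  m <- mean(x)
  s <- log(m) - mean(log(x))
  if (!is.finite(s) || s <= 0) return(NULL)
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in seq_len(max_iter)) {
    step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < tol * k) {
      k <- k_new
      break
    }
    k <- k_new
  }
  theta <- m / k
  n <- length(x)
  ll <- sum((k - 1) * log(x)) - sum(x) / theta - n * k * log(theta) -
    n * lgamma(k)
  list(estimate = c(shape = k, rate = 1 / theta), aic = 4 - 2 * ll,
       loglik = ll)
}

#' Fit a parametric null model to Hellinger divergence values
#'
#' Fits a two-parameter gamma distribution (default) to the strictly
#' positive HD values of one sample by maximum likelihood and records the
#' critical value `hd_crit`, the `1 - alpha` quantile of the fitted
#' distribution. Sites with HD exactly zero are excluded from the fit (the
#' point mass breaks continuous MLE). A two-parameter Weibull is available
#' as an alternative, and `model = "auto"` picks the better fit by AIC.
#'
#' @param hd Numeric vector of HD values (zeros dropped internally).
#' @param alpha Significance level for the critical value (default 0.05).
#' @param model `"gamma2p"` (default), `"weibull2p"`, or `"auto"`.
#' @param min_n Minimum number of positive values required (default 100).
#' @return An `hd_model` object with fields `distribution, shape, scale,
#'   n_fit, alpha, hd_crit, aic, ks_stat, loglik`.
#' @export
fit_hd_model <- function(hd, alpha = 0.05,
                         model = c("gamma2p", "weibull2p", "auto"),
                         min_n = 100) {
  model <- match.arg(model)
  x <- hd[hd > 0 & is.finite(hd)]
  if (length(x) < min_n) {
    abort(paste0("fit_hd_model needs >= ", min_n,
                 " strictly positive HD values; got ", length(x)))
  }
  if (stats::var(x) == 0) {
    abort("fit non-convergence: HD values are constant; consider a different null model")
  }
  fits <- list()
  if (model %in% c("gamma2p", "auto")) fits$gamma <- gamma_mle(x)
  if (model %in% c("weibull2p", "auto")) {
    wb <- tryCatch(
      suppressWarnings(fitdistrplus::fitdist(x, "weibull", method = "mle")),
      error = function(e) NULL
    )
    if (!is.null(wb)) {
      fits$weibull <- list(estimate = wb$estimate, aic = wb$aic,
                           loglik = wb$loglik)
    }
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0L) {
    abort("fit non-convergence: neither gamma nor Weibull MLE converged; consider a nonparametric quantile")
  }
  best_name <- names(fits)[which.min(vapply(fits, function(f) f$aic,
                                            numeric(1)))]
  fit <- fits[[best_name]]
  if (best_name == "gamma") {
    shape <- unname(fit$estimate["shape"])
    scale <- 1 / unname(fit$estimate["rate"])
    crit <- qgamma(1 - alpha, shape = shape, scale = scale)
    cdf <- function(q) stats::pgamma(q, shape = shape, scale = scale)
  } else {
    shape <- unname(fit$estimate["shape"])
    scale <- unname(fit$estimate["scale"])
    crit <- qweibull(1 - alpha, shape = shape, scale = scale)
    cdf <- function(q) stats::pweibull(q, shape = shape, scale = scale)
  }
  xs <- sort(x)
  ks_stat <- max(abs(seq_along(xs) / length(xs) - cdf(xs)),
                 abs((seq_along(xs) - 1) / length(xs) - cdf(xs)))
  structure(
    list(distribution = if (best_name == "gamma") "gamma2p" else "weibull2p",
         shape = shape, scale = scale, n_fit = length(x), alpha = alpha,
         hd_crit = crit, aic = fit$aic, ks_stat = ks_stat,
         loglik = fit$loglik),
    class = "hd_model"
  )
}

#' @export
print.hd_model <- function(x, ...) {
  cat("<hd_model> ", x$distribution, ": shape = ", signif(x$shape, 4),
      ", scale = ", signif(x$scale, 4), "; HD crit(alpha = ", x$alpha,
      ") = ", signif(x$hd_crit, 4), " [n = ", x$n_fit, "]\n", sep = "")
  invisible(x)
}

#' Fit per-sample (or pooled) HD null models
#'
#' Critical values are estimated for each individual sample by default; a
#' pooled fit over all samples is available for small designs.
#'
#' @param div Divergence tibble from [divergence_table()].
#' @param alpha,model Passed to [fit_hd_model()].
#' @param pooled If `TRUE`, fit once on all samples' HD values and reuse
#'   the critical value for every sample.
#' @return Tibble `sample_id, model (list), hd_crit`.
#' @export
fit_hd_models <- function(div, alpha = 0.05, model = "gamma2p",
                          pooled = FALSE) {
  if (pooled) {
    m <- fit_hd_model(div$hd, alpha = alpha, model = model)
    return(tibble(sample_id = unique(div$sample_id),
                  model = list(m), hd_crit = m$hd_crit))
  }
  div |>
    group_by(.data$sample_id) |>
    summarise(model = list(fit_hd_model(.data$hd, alpha = alpha,
                                        model = model)),
              .groups = "drop") |>
    mutate(hd_crit = vapply(.data$model, function(m) m$hd_crit, numeric(1)))
}

#' Select potential DMPs
#'
#' A potential DMP (pDMP) is a site whose methylation level difference
#' against the reference centroid exceeds `tv_min` in absolute value
#' (strictly: "higher than 20%") and whose Hellinger divergence reaches
#' the sample's fitted critical value.
#'
#' @param div Divergence tibble.
#' @param models Output of [fit_hd_models()] (per-sample critical values).
#' @param tv_min Minimum absolute level difference (default 0.2, strict).
#' @return The pDMP subset of `div`, with the sample's `hd_crit` attached.
#' @export
select_pdmp <- function(div, models, tv_min = 0.2) {
  div |>
    inner_join(select(models, "sample_id", "hd_crit"), by = "sample_id") |>
    filter(abs(.data$tv) > tv_min, .data$hd >= .data$hd_crit)
}

#' Estimate the optimal HD cutoff by Youden index
#'
#' Scans every observed pDMP HD value as a candidate threshold, classifies
#' a pDMP as "treatment" iff its HD is at or above the threshold, and
#' returns the cutoff maximizing the Youden index
#' `J = sensitivity + specificity - 1` for discriminating
#' treatment-carried from control-carried pDMPs. Ties are broken by the
#' smallest cutoff.
#'
#' @param pdmp pDMP tibble carrying a `group` column (`control` /
#'   `treatment`) for each site's carrier sample (attach from the manifest
#'   if absent).
#' @return A `cutpoint_result` with `cutoff_hd, youden_j, sensitivity,
#'   specificity, n_control, n_treatment`.
#' @export
estimate_cutpoint <- function(pdmp) {
  if (!"group" %in% names(pdmp)) {
    abort("pdmp must carry a 'group' column (control/treatment)")
  }
  hd_t <- pdmp$hd[pdmp$group == "treatment"]
  hd_c <- pdmp$hd[pdmp$group == "control"]
  if (length(hd_t) == 0L || length(hd_c) == 0L) {
    abort("estimate_cutpoint requires pDMPs in both the control and treatment comparisons")
  }
  cand <- sort(unique(pdmp$hd))
  # vectorised sweep: sens(c) = P(hd_t >= c), spec(c) = P(hd_c < c)
  nt <- length(hd_t)
  nc <- length(hd_c)
  sens <- 1 - (findInterval(cand - 1e-12, sort(hd_t)) / nt)
  spec <- findInterval(cand - 1e-12, sort(hd_c)) / nc
  j <- sens + spec - 1
  best <- which.max(j) # which.max returns the first (smallest cutoff) tie
  structure(
    list(cutoff_hd = cand[best], youden_j = j[best],
         sensitivity = sens[best], specificity = spec[best],
         n_control = nc, n_treatment = nt),
    class = "cutpoint_result"
  )
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("<cutpoint_result> HD cutoff = ", signif(x$cutoff_hd, 4),
      " (J = ", signif(x$youden_j, 3), "; sens = ",
      signif(x$sensitivity, 3), ", spec = ", signif(x$specificity, 3),
      ")\n", sep = "")
  invisible(x)
}

#' Direction of a methylation change
#'
#' Hypermethylated if the level difference against the reference centroid
#' is positive, hypomethylated if negative. A zero difference cannot occur
#' in a DMP (the level-difference filter is strict) and is rejected.
#'
#' @param tv Signed level differences.
#' @return Character vector `"hyper"` / `"hypo"`.
#' @export
classify_direction <- function(tv) {
  if (any(tv == 0)) {
    abort("tv = 0 cannot be classified (unreachable for sites passing the level-difference filter)")
  }
  if_else(tv > 0, "hyper", "hypo")
}

#' Call final DMPs at the Youden cutoff
#'
#' Final DMPs are the treatment-carried pDMPs with HD at or above the
#' cutoff (boundary included). Control-carried pDMPs passing the same rule
#' are retained in the output flagged `dmp_type = "spontaneous"`: they are
#' the background DMPs expected within wild-type samples from spontaneous
#' variation. Direction (`hyper`/`hypo`) is assigned from the sign of the
#' level difference.
#'
#' @param pdmp pDMP tibble with `group`.
#' @param cutpoint A `cutpoint_result` (or a bare numeric cutoff).
#' @return Tibble of passing sites with `direction` and `dmp_type`
#'   (`"treatment"` or `"spontaneous"`).
#' @export
call_dmps <- function(pdmp, cutpoint) {
  cutoff <- if (inherits(cutpoint, "cutpoint_result")) {
    cutpoint$cutoff_hd
  } else {
    cutpoint
  }
  out <- filter(pdmp, .data$hd >= cutoff)
  if (nrow(out) == 0L) {
    return(mutate(out, direction = character(), dmp_type = character()))
  }
  mutate(
    out,
    direction = classify_direction(.data$tv),
    dmp_type = if_else(.data$group == "treatment", "treatment", "spontaneous")
  )
}

#' Count cytosine positions per genomic feature class
#'
#' Classifies every distinct position of a site table into `TE_related`,
#' `genic` (body plus 1 kb flanks), `other`, or `intergenic` using the
#' priority `TE_related > genic > other`, and tallies totals per class and
#' context — the denominators of relative DMP frequencies.
#'
#' @param sites Tibble with `chrom, pos` (and optionally `context`).
#' @param annotation Annotation tibble with extended gene regions.
#' @return Tibble `feature_class, context?, n_cytosines`.
#' @export
count_cytosines_by_class <- function(sites, annotation) {
  cls <- classify_positions(distinct(sites, .data$chrom, .data$pos,
                                     .keep_all = TRUE), annotation)
  if ("context" %in% names(cls)) {
    count(cls, .data$feature_class, .data$context, name = "n_cytosines")
  } else {
    count(cls, .data$feature_class, name = "n_cytosines")
  }
}

# Assign one feature class per position with priority
# TE_related > genic (extended) > other > intergenic.
classify_positions <- function(sites, annotation) {
  pick <- function(class, use_ext) {
    regs <- filter(annotation, .data$feature_class == class)
    join_sites_to_regions(sites, regs, use_extended = use_ext) |>
      distinct(.data$chrom, .data$pos) |>
      mutate(feature_class = class)
  }
  hits <- bind_rows(
    pick("TE_related", FALSE),
    pick("genic", TRUE),
    pick("other", FALSE)
  ) |>
    mutate(priority = match(.data$feature_class,
                            c("TE_related", "genic", "other"))) |>
    arrange(.data$priority) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    select(-"priority")
  sites |>
    left_join(hits, by = c("chrom", "pos")) |>
    mutate(feature_class = dplyr::coalesce(.data$feature_class, "intergenic"))
}

#' Assign DMPs to genomic feature classes and tabulate relative frequency
#'
#' Each DMP is assigned a single class (priority `TE_related > genic >
#' other > intergenic`; a TE inside a gene's 1 kb flank wins). The relative
#' DMP frequency per class is the number of DMPs divided by the total
#' number of genomic cytosine positions in that class, reported per sample
#' and context.
#'
#' @param dmps DMP tibble from [call_dmps()].
#' @param annotation Annotation tibble.
#' @param total_sites Tibble of all assayed positions (`chrom, pos,
#'   context`) supplying the per-class denominators.
#' @return List: `dmps` (with `feature_class`), `frequency` (tibble
#'   `sample_id, context, feature_class, n_dmps, n_cytosines, frequency`).
#' @export
assign_features <- function(dmps, annotation, total_sites) {
  dmps_cls <- classify_positions(dmps, annotation)
  denom <- count_cytosines_by_class(total_sites, annotation)
  freq <- dmps_cls |>
    count(.data$sample_id, .data$context, .data$feature_class,
          name = "n_dmps") |>
    left_join(denom, by = c("feature_class", "context")) |>
    mutate(frequency = .data$n_dmps / .data$n_cytosines)
  list(dmps = dmps_cls, frequency = freq)
}

#' Run the full signal-detection DMP pipeline
#'
#' Pools the reference group into a centroid, computes per-site divergence
#' for every sample, fits per-sample HD null models, selects pDMPs, picks
#' the Youden cutoff between control- and treatment-carried pDMPs, and
#' calls final DMPs.
#'
#' @param counts Multi-sample count tibble.
#' @param manifest Sample manifest (`sample_id, group`).
#' @param ref_group Group pooled as reference centroid (default
#'   `"control"`).
#' @param alpha Critical-value level (default 0.05).
#' @param tv_min Minimum absolute level difference (default 0.2).
#' @param model Null model passed to [fit_hd_model()].
#' @param pooled_fit Fit one pooled HD model instead of per-sample models.
#' @return List with `divergence`, `models`, `pdmp`, `cutpoint`, `dmps`
#'   (treatment DMPs), `spontaneous` (control DMPs) and `centroid`.
#' @export
dmp_pipeline <- function(counts, manifest, ref_group = "control",
                         alpha = 0.05, tv_min = 0.2, model = "gamma2p",
                         pooled_fit = FALSE) {
  manifest <- validate_manifest(manifest)
  ref_ids <- manifest$sample_id[manifest$group == ref_group]
  centroid <- pool_reference(counts, ref_ids)
  div <- divergence_table(counts, centroid) |>
    left_join(select(manifest, "sample_id", "group"), by = "sample_id") |>
    mutate(group = if_else(.data$group == ref_group, "control", "treatment"))
  models <- fit_hd_models(div, alpha = alpha, model = model,
                          pooled = pooled_fit)
  pdmp <- select_pdmp(div, models, tv_min = tv_min)
  cutpoint <- estimate_cutpoint(pdmp)
  called <- call_dmps(pdmp, cutpoint)
  list(
    divergence = div, models = models, pdmp = pdmp, cutpoint = cutpoint,
    dmps = filter(called, .data$dmp_type == "treatment"),
    spontaneous = filter(called, .data$dmp_type == "spontaneous"),
    centroid = centroid
  )
}
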