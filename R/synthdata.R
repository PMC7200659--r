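#' Configuration for the synthetic bisulfite experiment
#'
#' Bundles every knob of the generator, which emulates the design of a
#' transgenerational methylation-memory study: a wild-type control group, a
#' heritable "memory" group carrying induced methylation repatterning
#' (CHH hypermethylation in promoters, CG hypomethylation in gene bodies of
#' a chosen target-gene set), and a first-generation "nonmemory" sibling
#' group sharing only a subset of the induced sites. Counts follow a
#' beta-binomial (biological inter-individual variation) over
#' negative-binomial coverage, with rare spontaneous level shifts in single
#' individuals providing background DMPs.
#'
#' @param n_chrom,chrom_len Number and length (bp) of toy chromosomes.
#' @param n_genes,n_tes,n_other Feature counts across the genome.
#' @param te_near_gene_frac Fraction of genes given a TE within 1 kb.
#' @param gene_body_len,te_len Feature lengths in bp.
#' @param promoter_len Promoter length (1 kb upstream of the TSS).
#' @param sites Per-feature cytosine site counts (list: `promoter_chh`,
#'   `promoter_cg`, `body_cg`, `body_chg`, `body_chh`, `te_per_context`) and
#'   the intergenic site rate per bp (`intergenic_rate`).
#' @param baseline Baseline methylation mixture: gene-body CG is bimodal
#'   (`cg_levels` with `cg_weights`), CHG/CHH unimodal, TE sites elevated in
#'   all contexts (`te`).
#' @param coverage_mean,coverage_dispersion Negative-binomial read coverage
#'   (mean and size).
#' @param rho Beta-binomial intra-class correlation (biological dispersion).
#' @param spontaneous_rate Per-site, per-individual probability of a
#'   spontaneous methylation shift (uniform magnitude 0.2-0.5, random sign).
#' @param target_gene_count Number of genes receiving induced effects.
#' @param delta_chh_promoter Induced CHH level increase in target promoters.
#' @param delta_cg_body Induced CG level decrease (negative) at methylated
#'   gene-body CG sites of targets.
#' @param affected_site_frac Fraction of eligible sites per target gene
#'   actually induced.
#' @param nonmemory_shared_frac Fraction of induced sites shared by the
#'   first-generation nonmemory group.
#' @param retention_rate Per-generation probability that an induced site is
#'   retained in the memory line.
#' @param n_generations Number of generations simulated.
#' @param n_per_group Samples per group.
#' @param expr_coupling Expression log2 fold change per unit of net induced
#'   methylation shift (negative: methylation gain represses).
#' @param expr_noise_sd Gaussian noise SD on log2 fold changes.
#' @param seed Global seed; every stochastic stage derives a child stream.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_chrom = 2, chrom_len = 600000,
                         n_genes = 200, n_tes = 100, n_other = 10,
                         te_near_gene_frac = 0.3,
                         gene_body_len = 2000, te_len = 400,
                         promoter_len = 1000,
                         sites = list(promoter_chh = 20, promoter_cg = 4,
                                      body_cg = 15, body_chg = 5,
                                      body_chh = 10, te_per_context = 6,
                                      intergenic_rate = 0.045),
                         baseline = list(cg_levels = c(0.08, 0.85),
                                         cg_weights = c(0.7, 0.3),
                                         chg = 0.10, chh = 0.05,
                                         te = c(CG = 0.7, CHG = 0.4, CHH = 0.2)),
                         coverage_mean = 30, coverage_dispersion = 8,
                         rho = 0.01,
                         spontaneous_rate = 0.001,
                         target_gene_count = 100,
                         delta_chh_promoter = 0.4,
                         delta_cg_body = -0.3,
                         affected_site_frac = 0.8,
                         nonmemory_shared_frac = 0.6,
                         retention_rate = 0.8,
                         n_generations = 6,
                         n_per_group = 5,
                         expr_coupling = -2,
                         expr_noise_sd = 0.25,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$te_near_gene_frac >= 0, cfg$te_near_gene_frac <= 1,
    cfg$affected_site_frac >= 0, cfg$affected_site_frac <= 1,
    cfg$nonmemory_shared_frac >= 0, cfg$nonmemory_shared_frac <= 1,
    cfg$retention_rate >= 0, cfg$retention_rate <= 1,
    cfg$rho > 0, cfg$rho < 1,
    cfg$delta_chh_promoter >= 0, cfg$delta_cg_body <= 0,
    cfg$target_gene_count <= cfg$n_genes,
    cfg$n_generations >= 1
  )
  structure(cfg, class = "synth_config")
}

#' Build a toy annotated genome with a cytosine site map
#'
#' Lays out genes (with 1 kb promoters), transposable elements (a
#' configured fraction within 1 kb of a gene), and small "other" features
#' on the toy chromosomes, then scatters cytosine sites with contexts and
#' baseline methylation levels drawn from the configured context mixtures.
#' The layout is deterministic given the config seed.
#'
#' @param config A [synth_config()].
#' @return A `synth_genome` list: `annotation` (feature tibble compatible
#'   with [read_annotation()] output), `sites` (per-cytosine tibble with
#'   `site_id, chrom, pos, strand, context, region, gene_id, p0`), and
#'   `chrom_lengths`.
#' @export
build_toy_genome <- function(config) {
  cfg <- config
  genes_per_chrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  slot <- cfg$gene_body_len + 2 * cfg$promoter_len + cfg$te_len + 600
  if (genes_per_chrom * slot > cfg$chrom_len) {
    abort(paste0("infeasible packing: ", genes_per_chrom,
                 " genes need ", genes_per_chrom * slot,
                 " bp but chrom_len is ", cfg$chrom_len,
                 "; increase chrom_len or reduce n_genes"))
  }
  with_child_seed(cfg$seed, "genome", {
    chroms <- paste0("chr", seq_len(cfg$n_chrom))
    # genes on regular slots
    feats <- list()
    gene_idx <- 0L
    for (ci in seq_len(cfg$n_chrom)) {
      n_here <- min(genes_per_chrom, cfg$n_genes - gene_idx)
      if (n_here <= 0) break
      slot_len <- floor(cfg$chrom_len / genes_per_chrom)
      for (k in seq_len(n_here)) {
        gene_idx <- gene_idx + 1L
        offset <- (k - 1L) * slot_len
        start <- offset + cfg$promoter_len + 200L +
          sample.int(200L, 1L)
        feats[[length(feats) + 1L]] <- tibble(
          chrom = chroms[ci], start = start,
          end = start + cfg$gene_body_len - 1L,
          strand = "+",
          feature_id = sprintf("gene_%04d", gene_idx),
          subtype = "gene", feature_class = "genic"
        )
      }
    }
    ann <- bind_rows(feats)
    # TEs: first n_near genes get one within 1 kb downstream of the body
    n_near <- round(cfg$n_genes * cfg$te_near_gene_frac)
    if (n_near > cfg$n_tes) {
      abort("n_tes too small for te_near_gene_frac")
    }
    near_genes <- if (n_near > 0) {
      ann$feature_id[sample.int(nrow(ann), n_near)]
    } else {
      character()
    }
    tes <- list()
    te_idx <- 0L
    for (g in near_genes) {
      te_idx <- te_idx + 1L
      row <- ann[ann$feature_id == g, ]
      gap <- sample(50:800, 1L)
      tes[[te_idx]] <- tibble(
        chrom = row$chrom, start = row$end + gap,
        end = row$end + gap + cfg$te_len - 1L, strand = "+",
        feature_id = sprintf("te_%04d", te_idx),
        subtype = "transposable_element", feature_class = "TE_related"
      )
    }
    # remaining TEs placed in the tail space of random chromosomes, far
    # from the gene slots
    n_far <- cfg$n_tes - n_near
    n_slots <- max(genes_per_chrom, 1L)
    slot_len <- floor(cfg$chrom_len / n_slots)
    for (k in seq_len(n_far)) {
      te_idx <- te_idx + 1L
      ci <- sample.int(cfg$n_chrom, 1L)
      s <- (sample.int(n_slots, 1L) - 1L) * slot_len +
        slot_len - cfg$te_len - 50L
      # keep if beyond the gene+1kb footprint of that slot, else shift right
      tes[[te_idx]] <- tibble(
        chrom = chroms[ci], start = as.integer(s),
        end = as.integer(s + cfg$te_len - 1L), strand = "+",
        feature_id = sprintf("te_%04d", te_idx),
        subtype = "transposable_element", feature_class = "TE_related"
      )
    }
    te_tab <- if (te_idx > 0) bind_rows(tes) else NULL
    others <- if (cfg$n_other > 0) {
      tibble(
        chrom = sample(chroms, cfg$n_other, replace = TRUE),
        start = sample.int(cfg$chrom_len - 200L, cfg$n_other),
        strand = "+",
        feature_id = sprintf("other_%03d", seq_len(cfg$n_other)),
        subtype = "ncRNA", feature_class = "other"
      ) |> mutate(end = .data$start + 120L, .after = "start")
    } else {
      NULL
    }
    ann <- bind_rows(ann, te_tab, others) |>
      arrange(.data$chrom, .data$start)
    chrom_lengths <- setNames(rep(cfg$chrom_len, cfg$n_chrom), chroms)
    ann <- extend_genes(ann, chrom_lengths = chrom_lengths,
                        flank = cfg$promoter_len)
    sites <- scatter_sites(ann, cfg, chrom_lengths)
    structure(
      list(annotation = ann, sites = sites, chrom_lengths = chrom_lengths,
           config = cfg),
      class = "synth_genome"
    )
  })
}

# Place cytosine sites with contexts and baseline levels p0. Runs inside
# the "genome" child stream.
scatter_sites <- function(ann, cfg, chrom_lengths) {
  s <- cfg$sites
  b <- cfg$baseline
  pick <- function(region_start, region_end, n) {
    n <- min(n, region_end - region_start + 1L)
    sort(sample(seq.int(region_start, region_end), n))
  }
  out <- list()
  genes <- filter(ann, .data$feature_class == "genic")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    prom_start <- max(g$start - cfg$promoter_len, 1L)
    prom_end <- g$start - 1L
    chh_prom <- pick(prom_start, prom_end, s$promoter_chh)
    cg_prom <- pick(prom_start, prom_end, s$promoter_cg)
    cg_body <- pick(g$start, g$end, s$body_cg)
    chg_body <- pick(g$start, g$end, s$body_chg)
    chh_body <- pick(g$start, g$end, s$body_chh)
    out[[length(out) + 1L]] <- tibble(
      chrom = g$chrom,
      pos = c(chh_prom, cg_prom, cg_body, chg_body, chh_body),
      context = rep(c("CHH", "CG", "CG", "CHG", "CHH"),
                    c(length(chh_prom), length(cg_prom), length(cg_body),
                      length(chg_body), length(chh_body))),
      region = rep(c("promoter", "promoter", "body", "body", "body"),
                   c(length(chh_prom), length(cg_prom), length(cg_body),
                     length(chg_body), length(chh_body))),
      gene_id = g$feature_id
    )
  }
  tes <- filter(ann, .data$feature_class == "TE_related")
  for (i in seq_len(nrow(tes))) {
    t <- tes[i, ]
    n_ctx <- s$te_per_context
    ps <- pick(t$start, t$end, 3L * n_ctx)
    out[[length(out) + 1L]] <- tibble(
      chrom = t$chrom, pos = ps,
      context = rep(c("CG", "CHG", "CHH"), length.out = length(ps)),
      region = "te", gene_id = NA_character_
    )
  }
  # intergenic background
  for (ci in names(chrom_lengths)) {
    n_bg <- round(chrom_lengths[[ci]] * s$intergenic_rate)
    if (n_bg > 0) {
      out[[length(out) + 1L]] <- tibble(
        chrom = ci,
        pos = sort(sample.int(chrom_lengths[[ci]], n_bg)),
        context = sample(c("CG", "CHG", "CHH"), n_bg, replace = TRUE,
                         prob = c(0.3, 0.3, 0.4)),
        region = "intergenic", gene_id = NA_character_
      )
    }
  }
  sites <- bind_rows(out) |>
    mutate(strand = sample(c("+", "-"), n(), replace = TRUE)) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$pos)
  # baseline levels by context and region
  n <- nrow(sites)
  p0 <- numeric(n)
  is_te <- sites$region == "te"
  for (ctx in c("CG", "CHG", "CHH")) {
    idx <- which(sites$context == ctx & !is_te)
    p0[idx] <- switch(ctx,
      CG = sample(b$cg_levels, length(idx), replace = TRUE,
                  prob = b$cg_weights),
      CHG = b$chg,
      CHH = b$chh
    )
    idx_te <- which(sites$context == ctx & is_te)
    p0[idx_te] <- b$te[[ctx]]
  }
  sites$p0 <- pmin(pmax(p0, 0.01), 0.99)
  sites$site_id <- seq_len(nrow(sites))
  select(sites, "site_id", "chrom", "pos", "strand", "context",
         "region", "gene_id", "p0")
}

# Choose target genes and the induced site set with realized (clipped)
# level shifts. Deterministic given seed.
draw_truth_sites <- function(genome, cfg) {
  with_child_seed(cfg$seed, "targets", {
    genes <- unique(stats::na.omit(genome$sites$gene_id))
    targets <- sort(sample(genes, cfg$target_gene_count))
    elig_chh <- filter(genome$sites, .data$gene_id %in% targets,
                       .data$region == "promoter", .data$context == "CHH")
    elig_cg <- filter(genome$sites, .data$gene_id %in% targets,
                      .data$region == "body", .data$context == "CG",
                      .data$p0 >= 0.5)
    take <- function(df) {
      df |>
        group_by(.data$gene_id) |>
        slice(sort(sample.int(n(), ceiling(n() * cfg$affected_site_frac)))) |>
        ungroup()
    }
    ind <- bind_rows(
      if (cfg$delta_chh_promoter > 0) {
        mutate(take(elig_chh), delta_nominal = cfg$delta_chh_promoter)
      },
      if (cfg$delta_cg_body < 0) {
        mutate(take(elig_cg), delta_nominal = cfg$delta_cg_body)
      }
    )
    if (is.null(ind) || nrow(ind) == 0L) {
      ind <- genome$sites[0, ] |> mutate(delta_nominal = numeric())
    }
    ind |>
      mutate(
        delta = pmin(pmax(.data$p0 + .data$delta_nominal, 0.01), 0.99) - .data$p0,
        direction = if_else(.data$delta_nominal > 0, "hyper", "hypo")
      ) |>
      arrange(.data$site_id) |>
      list(induced_sites = _, target_genes = targets)
  })
}

# Simulate one sample's counts given per-site mean levels.
# Vectorised over sites; runs inside a caller-managed RNG stream.
sim_one_sample <- function(p_site, cfg) {
  n <- length(p_site)
  cov <- rnbinom(n, mu = cfg$coverage_mean, size = cfg$coverage_dispersion)
  # spontaneous single-individual shifts
  p <- p_site
  flip <- which(runif(n) < cfg$spontaneous_rate)
  if (length(flip) > 0) {
    shift <- runif(length(flip), 0.2, 0.5) * sample(c(-1, 1), length(flip),
                                                    replace = TRUE)
    p[flip] <- pmin(pmax(p[flip] + shift, 0.01), 0.99)
  }
  a <- p * (1 - cfg$rho) / cfg$rho
  bb <- (1 - p) * (1 - cfg$rho) / cfg$rho
  p_ind <- rbeta(n, a, bb)
  n_meth <- rbinom(n, cov, p_ind)
  list(cov = cov, n_meth = n_meth)
}

#' Simulate replicate bisulfite count tables with known truth
#'
#' Draws per-sample counts at every genome site: coverage is
#' negative-binomial, each individual's methylation level is beta-binomial
#' around the site baseline (or shifted baseline at induced sites of
#' treatment samples), and rare spontaneous level shifts hit single
#' individuals in any group. Zero-coverage draws are dropped (site missing
#' in that sample).
#'
#' @param genome A [build_toy_genome()] result.
#' @param config The [synth_config()] used (or a modified copy).
#' @param design Sample manifest tibble (`sample_id, group`), groups
#'   `control` / `treatment`; defaults to `n_per_group` of each.
#' @param seed Seed for this stage (default: config seed).
#' @param induced_site_ids Optional subset of truth site ids to induce in
#'   the treatment group (used for generation-specific retention); default
#'   all induced sites.
#' @return A list: `counts` (long tibble of all samples), `truth`
#'   (`synth_truth`: `induced_sites`, `target_genes`, `all_genes`),
#'   `design`.
#' @export
simulate_counts <- function(genome, config, design = NULL,
                            seed = config$seed, induced_site_ids = NULL) {
  cfg <- config
  if (is.null(design)) {
    design <- default_design(cfg$n_per_group)
  }
  design <- validate_manifest(design)
  truth0 <- draw_truth_sites(genome, cfg)
  induced <- truth0$induced_sites
  if (!is.null(induced_site_ids)) {
    induced <- filter(induced, .data$site_id %in% induced_site_ids)
  }
  sites <- genome$sites
  delta_vec <- numeric(nrow(sites))
  delta_vec[induced$site_id] <- induced$delta
  counts <- purrr::map(seq_len(nrow(design)), function(i) {
    sid <- design$sample_id[i]
    trt <- design$group[i] == "treatment"
    p_mean <- if (trt) sites$p0 + delta_vec else sites$p0
    sim <- with_child_seed(seed, paste0("counts/", sid),
                           sim_one_sample(p_mean, cfg))
    keep <- sim$cov >= 1L
    tibble(
      sample_id = sid,
      chrom = sites$chrom[keep], pos = sites$pos[keep],
      strand = sites$strand[keep], context = sites$context[keep],
      n_meth = sim$n_meth[keep],
      n_unmeth = sim$cov[keep] - sim$n_meth[keep]
    )
  }) |> bind_rows()
  truth <- structure(
    list(induced_sites = induced,
         target_genes = truth0$target_genes,
         all_genes = sort(unique(stats::na.omit(sites$gene_id)))),
    class = "synth_truth"
  )
  list(counts = counts, truth = truth, design = design)
}

default_design <- function(n_per_group,
                           groups = c("control", "treatment"),
                           phenotypes = c(control = "WT", treatment = "MM"),
                           generation = 1L) {
  bind_rows(lapply(groups, function(g) {
    tibble(
      sample_id = sprintf("%s_g%d_%02d", phenotypes[[g]], generation,
                          seq_len(n_per_group)),
      group = g, generation = generation, phenotype = phenotypes[[g]]
    )
  }))
}

#' Simulate a multi-generation methylation-memory experiment
#'
#' Generation 1 contains wild-type (control), memory and nonmemory groups;
#' the nonmemory group carries only a configured fraction of the induced
#' sites. Generations 2..G contain wild-type and memory groups, each
#' induced site being independently retained with probability
#' `retention_rate` per generation transition, so the per-generation truth
#' sets are nested (monotone set inclusion).
#'
#' @param genome A [build_toy_genome()] result.
#' @param config The [synth_config()].
#' @param seed Seed (default: config seed).
#' @return A list with `generations` (list per generation of `counts`,
#'   `design`, `truth`) and `truth` (overall: full induced set, per-
#'   generation retained site ids, nonmemory shared site ids, target
#'   genes).
#' @export
simulate_generations <- function(genome, config, seed = config$seed) {
  cfg <- config
  truth0 <- draw_truth_sites(genome, cfg)
  all_ids <- truth0$induced_sites$site_id
  retained <- vector("list", cfg$n_generations)
  retained[[1]] <- all_ids
  if (cfg$n_generations > 1) {
    with_child_seed(seed, "retention", {
      for (g in 2:cfg$n_generations) {
        prev <- retained[[g - 1]]
        keep <- runif(length(prev)) < cfg$retention_rate
        retained[[g]] <- prev[keep]
      }
    })
  }
  nm_shared <- with_child_seed(seed, "nonmemory", {
    n_shared <- round(length(all_ids) * cfg$nonmemory_shared_frac)
    sort(sample(all_ids, n_shared))
  })
  generations <- vector("list", cfg$n_generations)
  for (g in seq_len(cfg$n_generations)) {
    design <- default_design(cfg$n_per_group, generation = g)
    sim <- simulate_counts(genome, cfg, design,
                           seed = child_seed(seed, paste0("gen", g)),
                           induced_site_ids = retained[[g]])
    if (g == 1L) {
      nm_design <- tibble(
        sample_id = sprintf("NM_g1_%02d", seq_len(cfg$n_per_group)),
        group = "treatment", generation = 1L, phenotype = "NM"
      )
      nm <- simulate_counts(genome, cfg, nm_design,
                            seed = child_seed(seed, "gen1nm"),
                            induced_site_ids = nm_shared)
      sim$counts <- bind_rows(sim$counts, nm$counts)
      sim$design <- bind_rows(sim$design, nm_design)
    }
    generations[[g]] <- sim
  }
  structure(
    list(
      generations = generations,
      truth = list(
        induced_sites = truth0$induced_sites,
        retained_site_ids = retained,
        nonmemory_shared_ids = nm_shared,
        target_genes = truth0$target_genes
      )
    ),
    class = "synth_experiment"
  )
}

#' Simulate a matched differential-expression table
#'
#' Target genes receive a log2 fold change proportional (negatively, by
#' default) to their net induced methylation shift plus Gaussian noise;
#' non-target genes receive noise only. Adjusted p-values come from the
#' Gaussian null and BH correction.
#'
#' @param truth `synth_truth` from [simulate_counts()].
#' @param config The [synth_config()].
#' @param seed Seed (default: config seed).
#' @return An expression tibble `gene_id, log2fc, padj`.
#' @export
simulate_expression <- function(truth, config, seed = config$seed) {
  cfg <- config
  genes <- truth$all_genes
  gene_delta <- truth$induced_sites |>
    distinct(.data$gene_id, .data$delta_nominal) |>
    group_by(.data$gene_id) |>
    summarise(net = sum(.data$delta_nominal), .groups = "drop")
  net <- setNames(rep(0, length(genes)), genes)
  net[gene_delta$gene_id] <- gene_delta$net
  with_child_seed(seed, "expression", {
    l2fc <- cfg$expr_coupling * net + rnorm(length(genes),
                                            sd = cfg$expr_noise_sd)
    p <- 2 * pnorm(-abs(l2fc) / cfg$expr_noise_sd)
    tibble(gene_id = genes, log2fc = unname(l2fc),
           padj = p.adjust(p, method = "BH"))
  })
}

#' Write a synthetic experiment to disk in standard formats
#'
#' Per-sample Bismark cytosine reports, a GFF3 annotation, the manifest and
#' the truth tables as TSV.
#'
#' @param sim Output of [simulate_counts()].
#' @param genome The [build_toy_genome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in unique(sim$counts$sample_id)) {
    write_bismark_cov(filter(sim$counts, .data$sample_id == sid),
                      file.path(dir, paste0(sid, ".cov")))
  }
  ann <- genome$annotation
  gr <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$start, ann$end), strand = ann$strand,
    type = ann$subtype, ID = ann$feature_id
  )
  rtracklayer::export(gr, file.path(dir, "annotation.gff3"), format = "gff3")
  readr::write_tsv(sim$design, file.path(dir, "manifest.tsv"))
  readr::write_tsv(sim$truth$induced_sites,
                   file.path(dir, "truth_sites.tsv"))
  readr::write_tsv(tibble(gene_id = sim$truth$target_genes),
                   file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}
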