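#' Read a Bismark-style per-cytosine coverage file
#'
#' Reads either the 6-column Bismark coverage dialect
#' (`chrom, start, end, methylation%, count_methylated, count_unmethylated`)
#' or the 7-column cytosine-report dialect
#' (`chrom, pos, strand, count_methylated, count_unmethylated, context,
#' trinucleotide`). The dialect is auto-detected from the column count. The
#' methylation percentage column of the coverage dialect is ignored; levels
#' are always recomputed from counts. Positions are 1-based.
#'
#' Coverage-dialect files carry no strand or context: strand is set to `"."`
#' and context to `NA`; join a context track with [attach_context()] before
#' context-aware analysis.
#'
#' @param path Path to a tab-separated coverage or cytosine-report file.
#' @param sample_id Sample identifier attached to every record. Defaults to
#'   the file name without extension.
#' @return A tibble with columns `sample_id, chrom, pos, strand, context,
#'   n_meth, n_unmeth`, sorted by position within chromosome.
#' @export
read_bismark_cov <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(cov|txt|tsv)(\\.gz)?$", "", basename(path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    rlang::warn(paste0("empty coverage file: ", path))
    return(tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      strand = character(), context = character(),
      n_meth = integer(), n_unmeth = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (!all(ncols == ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    abort(paste0("malformed line ", bad, " in ", path,
                 ": expected ", ncols[1], " fields, found ", ncols[bad]))
  }
  mat <- do.call(rbind, fields)
  parse_count <- function(x, col_label) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(paste0("parse error at line ", bad, " in ", path,
                   ": non-numeric ", col_label, " '", x[bad], "'"))
    }
    if (any(v < 0)) {
      bad <- which(v < 0)[1]
      abort(paste0("validation error at line ", bad, " in ", path,
                   ": negative ", col_label))
    }
    as.integer(v)
  }
  if (ncols[1] == 6L) {
    out <- tibble(
      sample_id = sample_id,
      chrom = mat[, 1],
      pos = parse_count(mat[, 2], "position"),
      strand = ".",
      context = NA_character_,
      n_meth = parse_count(mat[, 5], "methylated count"),
      n_unmeth = parse_count(mat[, 6], "unmethylated count")
    )
  } else if (ncols[1] == 7L) {
    ctx <- mat[, 6]
    if (!all(ctx %in% c("CG", "CpG", "CHG", "CHH"))) {
      bad <- which(!ctx %in% c("CG", "CpG", "CHG", "CHH"))[1]
      abort(paste0("parse error at line ", bad, " in ", path,
                   ": unknown context '", ctx[bad], "'"))
    }
    out <- tibble(
      sample_id = sample_id,
      chrom = mat[, 1],
      pos = parse_count(mat[, 2], "position"),
      strand = mat[, 3],
      context = if_else(ctx == "CpG", "CG", ctx),
      n_meth = parse_count(mat[, 4], "methylated count"),
      n_unmeth = parse_count(mat[, 5], "unmethylated count")
    )
  } else {
    abort(paste0("unrecognised dialect in ", path, ": ", ncols[1],
                 " columns (expected 6 for coverage, 7 for cytosine report)"))
  }
  arrange(out, .data$chrom, .data$pos)
}

#' Write a per-cytosine count table as a Bismark cytosine report
#'
#' Writes the 7-column cytosine-report dialect, the lossless counterpart of
#' [read_bismark_cov()] (the 6-column coverage dialect drops strand and
#' context). Round-tripping through write/read preserves the record set.
#'
#' @param counts A per-cytosine count tibble (one sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(counts, path) {
  stopifnot(length(unique(counts$sample_id)) <= 1L)
  out <- counts |>
    arrange(.data$chrom, .data$pos) |>
    mutate(trinuc = .data$context) |>
    select("chrom", "pos", "strand", "n_meth", "n_unmeth", "context", "trinuc")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Attach sequence context to a coverage-dialect count table
#'
#' Plain Bismark coverage files carry no cytosine context. This joins a
#' context track (`chrom, pos, strand, context`) such as the one emitted by
#' the synthetic genome, dropping records without a context match.
#'
#' @param counts Count tibble with `context` possibly `NA`.
#' @param context_track Tibble with `chrom, pos, strand, context`.
#' @return The count tibble with `context` filled in; records with no
#'   matching context are dropped with a warning.
#' @export
attach_context <- function(counts, context_track) {
  track <- distinct(context_track, .data$chrom, .data$pos, .data$strand,
                    ctx_new = .data$context)
  out <- counts |>
    select(-"context") |>
    left_join(track, by = c("chrom", "pos", "strand")) |>
    rename(context = "ctx_new")
  n_drop <- sum(is.na(out$context))
  if (n_drop > 0) {
    rlang::warn(paste0(n_drop, " records had no context in the track and were dropped"))
    out <- filter(out, !is.na(.data$context))
  }
  out
}

#' Bisulfite conversion rate from chloroplast counts
#'
#' The chloroplast genome is unmethylated, so its apparent methylation
#' measures conversion failure: the conversion rate is the unmethylated
#' fraction of all chloroplast cytosine reads. Samples must exceed 99%
#' conversion to pass QC.
#'
#' @param counts Count tibble, possibly multi-sample.
#' @param chloroplast_chrom Chromosome name of the chloroplast genome.
#' @param min_rate QC threshold; pass requires `rate > min_rate`.
#' @return A tibble with one row per sample: `sample_id, rate, qc_pass`.
#' @export
conversion_rate <- function(counts, chloroplast_chrom, min_rate = 0.99) {
  cp <- filter(counts, .data$chrom == chloroplast_chrom)
  if (nrow(cp) == 0L) {
    abort(paste0("cannot compute conversion rate: no records on '",
                 chloroplast_chrom, "'"))
  }
  cp |>
    group_by(.data$sample_id) |>
    summarise(
      rate = sum(.data$n_unmeth) / sum(.data$n_meth + .data$n_unmeth),
      .groups = "drop"
    ) |>
    mutate(qc_pass = .data$rate > min_rate)
}

#' Filter cytosine records by read coverage
#'
#' Removes records whose coverage exceeds `max_cov` (PCR-bias control;
#' "greater than" is strict, so coverage exactly `max_cov` is retained) or
#' falls below `min_cov`.
#'
#' @param counts Count tibble.
#' @param max_cov Maximum retained coverage (default 500).
#' @param min_cov Minimum retained coverage (default 4).
#' @return The filtered tibble; numbers removed at each end are logged.
#' @export
filter_coverage <- function(counts, max_cov = 500, min_cov = 4) {
  if (max_cov < min_cov) {
    abort("configuration error: max_cov < min_cov")
  }
  cov <- counts$n_meth + counts$n_unmeth
  n_hi <- sum(cov > max_cov)
  n_lo <- sum(cov < min_cov)
  msg_log("filter_coverage: removed ", n_hi, " records with coverage > ",
          max_cov, " and ", n_lo, " with coverage < ", min_cov)
  counts[cov <= max_cov & cov >= min_cov, , drop = FALSE]
}

#' Read a genome annotation with feature classes and extended gene regions
#'
#' Imports GFF3 or BED (detected from the extension) and maps feature types
#' to the three classes used throughout: `genic`, `TE_related` (TEs, TE
#' genes, TE fragments, pseudogenes) and `other` (tRNA, rRNA, snRNA, miRNA,
#' ncRNA). Genes additionally carry an extended region of the body plus 1 kb
#' upstream and 1 kb downstream, clipped at chromosome bounds.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @param class_map Named character vector mapping source feature types to
#'   classes, e.g. `c(gene = "genic", transposable_element = "TE_related")`.
#'   Types absent from the map are logged and dropped.
#' @param chrom_lengths Optional named integer vector of chromosome lengths
#'   used to clip extended regions; without it regions are clipped at 1 only.
#' @param flank Extension in bp on each side of a gene (default 1000).
#' @return A tibble `chrom, start, end, strand, feature_id, feature_class,
#'   subtype, extended_start, extended_end` (extension is `NA` for
#'   non-genic features).
#' @export
read_annotation <- function(path, class_map = default_class_map(),
                            chrom_lengths = NULL, flank = 1000) {
  gr <- rtracklayer::import(path)
  df <- as_tibble(as.data.frame(gr))
  type <- if ("type" %in% names(df)) as.character(df$type) else rep("region", nrow(df))
  id <- if ("ID" %in% names(df) && !all(is.na(df$ID))) {
    as.character(df$ID)
  } else if ("Name" %in% names(df) && !all(is.na(df$Name))) {
    as.character(df$Name)
  } else if ("name" %in% names(df)) {
    as.character(df$name)
  } else {
    paste0("feat_", seq_len(nrow(df)))
  }
  ann <- tibble(
    chrom = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = as.character(df$strand),
    feature_id = id,
    subtype = type
  )
  if (any(ann$start > ann$end)) {
    bad <- ann$feature_id[which(ann$start > ann$end)[1]]
    abort(paste0("malformed annotation: start > end for feature '", bad, "'"))
  }
  unmapped <- setdiff(unique(ann$subtype), names(class_map))
  if (length(unmapped) > 0) {
    msg_log("read_annotation: dropping unmapped feature types: ",
            paste(unmapped, collapse = ", "))
  }
  ann <- ann |>
    filter(.data$subtype %in% names(class_map)) |>
    mutate(feature_class = unname(class_map[.data$subtype]))
  extend_genes(ann, chrom_lengths = chrom_lengths, flank = flank)
}

#' Default GFF3 feature-type to class mapping
#'
#' Covers the common Ensembl Plants / TAIR types.
#' @return Named character vector usable as `class_map`.
#' @export
default_class_map <- function() {
  c(
    gene = "genic", protein_coding_gene = "genic", mRNA = "genic",
    transposable_element = "TE_related",
    transposable_element_gene = "TE_related",
    transposon_fragment = "TE_related",
    pseudogene = "TE_related",
    tRNA = "other", rRNA = "other", snRNA = "other", snoRNA = "other",
    miRNA = "other", ncRNA = "other", lnc_RNA = "other",
    tRNA_gene = "other", rRNA_gene = "other", ncRNA_gene = "other"
  )
}

# Add [start - flank, end + flank] extended regions to genic features,
# clipped at 1 and (if known) the chromosome length.
extend_genes <- function(ann, chrom_lengths = NULL, flank = 1000) {
  ann <- mutate(
    ann,
    extended_start = if_else(.data$feature_class == "genic",
                             pmax(.data$start - flank, 1L), NA_integer_),
    extended_end = if_else(.data$feature_class == "genic",
                           .data$end + flank, NA_integer_)
  )
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[ann$chrom]
    ann$extended_end <- if_else(
      !is.na(ann$extended_end) & !is.na(len),
      pmin(ann$extended_end, as.integer(len)), ann$extended_end
    )
  }
  ann
}

#' Read a sample manifest
#'
#' @param path Headered CSV or TSV with columns `sample_id, group,
#'   generation, phenotype`.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  validate_manifest(reader(path, show_col_types = FALSE))
}

validate_manifest <- function(manifest) {
  need <- c("sample_id", "group")
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("manifest lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(manifest$sample_id)) {
    abort("manifest sample_ids must be unique")
  }
  as_tibble(manifest)
}

#' Read a differential-expression results table
#'
#' Expression results (e.g. from an RNA-seq DE analysis) are consumed, not
#' computed: only `gene_id`, `log2fc` and `padj` are used downstream.
#'
#' @param path Headered CSV or TSV with columns `gene_id, log2fc, padj`.
#' @return A tibble with those three columns.
#' @export
read_expression <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  tab <- reader(path, show_col_types = FALSE)
  need <- c("gene_id", "log2fc", "padj")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(paste0("expression table lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(tab$padj < 0 | tab$padj > 1, na.rm = TRUE)) {
    abort("padj values must lie in [0, 1]")
  }
  select(as_tibble(tab), "gene_id", "log2fc", "padj")
}
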