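#' Load genome gene coordinates
#'
#' Reads gene loci from GFF3 (rows of type `gene`, 1-based inclusive,
#' converted on ingestion) or BED (0-based half-open, passed through).
#' Internally all coordinates are 0-based half-open.
#'
#' @param path file path.
#' @param format `"GFF3"` or `"BED"`.
#' @return data.frame of class `gene_loci` with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`; attribute `chrom_lengths` holds named
#'   chromosome lengths (from `##sequence-region` pragmas when present,
#'   otherwise the maximum gene end per chromosome).
#' @export
load_genome <- function(path, format = c("GFF3", "BED")) {
  format <- match.arg(format)
  if (format == "GFF3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids)) stop("GFF3 gene rows must carry ID attributes")
    genes <- data.frame(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    pragma <- grep("^##sequence-region", readLines(path, warn = FALSE),
                   value = TRUE)
    chrom_lengths <- NULL
    if (length(pragma)) {
      f <- strsplit(trimws(pragma), "\\s+")
      chrom_lengths <- stats::setNames(
        vapply(f, function(x) as.numeric(x[[4L]]), 0), # end (1-based) = length
        vapply(f, `[[`, "", 2L))
    }
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    genes <- data.frame(
      gene_id = as.character(gr$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    chrom_lengths <- NULL
  }
  genes$strand[!genes$strand %in% c("+", "-")] <- "unknown"
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) stop("duplicate gene_ids: ", paste(unique(dup), collapse = ", "))
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(genes$end, genes$chrom, max)
  structure(genes, chrom_lengths = chrom_lengths,
            class = c("gene_loci", "data.frame"))
}

genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    gene_id = genes$gene_id)
}

#' Genes overlapping a genomic region
#'
#' Any-overlap rule: a gene is included if it overlaps the half-open region
#' `[start, end)` by at least one base pair.
#'
#' @param genes a `gene_loci` data.frame.
#' @param region list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return character vector of gene ids.
#' @export
genes_in_region <- function(genes, region) {
  if (!region$chrom %in% genes$chrom) {
    warning("chromosome ", region$chrom, " absent from genome")
    return(character(0))
  }
  hit <- genes$chrom == region$chrom &
    genes$start < region$end & genes$end > region$start
  genes$gene_id[hit]
}

#' Read a QTL region table
#'
#' TSV with header `trait_id, trait_type, chrom, start, end`. `trait_type`
#' must be one of `macroscopic`, `metabolite`, `expression`.
#'
#' @param path file path.
#' @param coordinate_convention `"bed"` (0-based half-open, default) or
#'   `"one_based"` (1-based inclusive, converted on ingestion).
#' @return data.frame with columns `region_id`, `trait_id`, `trait_type`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @export
read_qtl_table <- function(path, coordinate_convention = c("bed", "one_based")) {
  coordinate_convention <- match.arg(coordinate_convention)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trait_id", "trait_type", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("QTL table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$trait_type),
                 c("macroscopic", "metabolite", "expression"))
  if (length(bad)) stop("unknown trait_type: ", paste(bad, collapse = ", "))
  if (coordinate_convention == "one_based") {
    df$start <- df$start - 1L
  }
  if (any(df$start >= df$end)) stop("QTL region with start >= end")
  df$region_id <- sprintf("%s_r%d", df$trait_id,
                          stats::ave(seq_len(nrow(df)), df$trait_id,
                                     FUN = seq_along))
  df[, c("region_id", "trait_id", "trait_type", "chrom", "start", "end")]
}

#' Build a QTL dataset: map every region to its gene set
#'
#' Computes, for each region, the set of overlapping genes (any-overlap rule)
#' in one vectorized interval query. Overlapping regions of one trait are kept
#' distinct (occurrence counting uses regions as given) and logged.
#'
#' @param regions data.frame from [read_qtl_table()].
#' @param genes a `gene_loci` data.frame.
#' @return object of class `qtl_dataset`: list with `regions` (the input
#'   data.frame), `region_genes` (named list region_id -> gene ids) and
#'   `traits` (data.frame `trait_id`, `trait_type`).
#' @export
build_qtl_dataset <- function(regions, genes) {
  gr_genes <- genes_granges(genes)
  gr_regions <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_regions, gr_genes))
  region_genes <- rep(list(character(0)), nrow(regions))
  names(region_genes) <- regions$region_id
  if (length(hits)) {
    sp <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    region_genes[as.integer(names(sp))] <- sp
  }
  traits <- unique(regions[, c("trait_id", "trait_type")])
  rownames(traits) <- NULL
  structure(list(regions = regions, region_genes = region_genes,
                 traits = traits),
            class = "qtl_dataset")
}

#' Trait gene sets (deduplicated union over the trait's regions)
#' @param dataset a `qtl_dataset`.
#' @return named list trait_id -> character vector of gene ids.
#' @export
trait_gene_sets <- function(dataset) {
  sp <- split(dataset$region_genes, dataset$regions$trait_id)
  lapply(sp, function(x) unique(unlist(x, use.names = FALSE)))
}

#' Pipeline configuration with the published default thresholds
#'
#' Defaults: regions capped at 450 genes; traits need at least 2
#' (macroscopic, metabolite) or 3 (expression) regions; a term must occur in
#' at least half of a trait's regions; terms annotated to more than 1% of all
#' genes are excluded; enrichment FDR 0.1; trait-link FDR 0.05; 1,000
#' permutations.
#'
#' @param region_gene_cap maximum genes per QTL region.
#' @param min_regions named integer vector per trait type.
#' @param occurrence_fraction minimum fraction of a trait's regions a term
#'   must occur in.
#' @param generality_max_fraction maximum fraction of genome genes a term may
#'   annotate.
#' @param enrichment_fdr BH level for trait-term links.
#' @param linkage_fdr BH level for max-similarity trait links.
#' @param n_permutations permutation replicates.
#' @param rng_seed master seed.
#' @param global_correction apply BH across all traits jointly instead of
#'   within each trait.
#' @param symmetric_bma use the symmetrized best-match average (default);
#'   `FALSE` gives the one-directional variant.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(region_gene_cap = 450L,
                            min_regions = c(macroscopic = 2L, metabolite = 2L,
                                            expression = 3L),
                            occurrence_fraction = 0.5,
                            generality_max_fraction = 0.01,
                            enrichment_fdr = 0.1,
                            linkage_fdr = 0.05,
                            n_permutations = 1000L,
                            rng_seed = 1L,
                            global_correction = FALSE,
                            symmetric_bma = TRUE) {
  stopifnot(region_gene_cap >= 1L,
            all(min_regions >= 1L),
            occurrence_fraction > 0, occurrence_fraction <= 1,
            generality_max_fraction > 0, generality_max_fraction <= 1,
            enrichment_fdr > 0, enrichment_fdr <= 1,
            linkage_fdr > 0, linkage_fdr <= 1,
            n_permutations >= 1L)
  structure(list(region_gene_cap = as.integer(region_gene_cap),
                 min_regions = min_regions,
                 occurrence_fraction = occurrence_fraction,
                 generality_max_fraction = generality_max_fraction,
                 enrichment_fdr = enrichment_fdr,
                 linkage_fdr = linkage_fdr,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed),
                 global_correction = global_correction,
                 symmetric_bma = symmetric_bma),
            class = "pipeline_config")
}

#' Apply the region-size and trait-inclusion filters
#'
#' First drops regions whose gene count exceeds `region_gene_cap`, then drops
#' traits left with fewer than `min_regions[trait_type]` regions. Every drop
#' is recorded in the exclusion log.
#'
#' @param dataset a `qtl_dataset`.
#' @param config a `pipeline_config`.
#' @return filtered `qtl_dataset` with attribute `exclusion_log`, a
#'   data.frame (`kind`, `id`, `trait_id`, `reason`).
#' @export
apply_filters <- function(dataset, config = pipeline_config()) {
  log <- data.frame(kind = character(0), id = character(0),
                    trait_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  sizes <- lengths(dataset$region_genes)
  too_big <- sizes > config$region_gene_cap
  if (any(too_big)) {
    log <- rbind(log, data.frame(
      kind = "region", id = dataset$regions$region_id[too_big],
      trait_id = dataset$regions$trait_id[too_big],
      reason = sprintf("region has %d genes > cap %d",
                       sizes[too_big], config$region_gene_cap)))
  }
  regions <- dataset$regions[!too_big, , drop = FALSE]
  region_genes <- dataset$region_genes[!too_big]

  counts <- table(regions$trait_id)
  ttypes <- stats::setNames(dataset$traits$trait_type, dataset$traits$trait_id)
  need <- config$min_regions[ttypes[names(counts)]]
  drop_traits <- names(counts)[as.integer(counts) < as.integer(need)]
  # traits that lost every region also must go
  gone <- setdiff(dataset$traits$trait_id, regions$trait_id)
  drop_traits <- union(drop_traits, gone)
  if (length(drop_traits)) {
    n_left <- as.integer(table(factor(regions$trait_id, levels = drop_traits)))
    log <- rbind(log, data.frame(
      kind = "trait", id = drop_traits, trait_id = drop_traits,
      reason = sprintf("trait has %d regions < required %d", n_left,
                       as.integer(config$min_regions[ttypes[drop_traits]]))))
    keep <- !regions$trait_id %in% drop_traits
    regions <- regions[keep, , drop = FALSE]
    region_genes <- region_genes[regions$region_id]
  }
  traits <- dataset$traits[dataset$traits$trait_id %in% regions$trait_id, ,
                           drop = FALSE]
  rownames(regions) <- NULL; rownames(traits) <- NULL
  structure(list(regions = regions, region_genes = region_genes,
                 traits = traits),
            class = "qtl_dataset", exclusion_log = log)
}

#' Per-type descriptive statistics of a QTL dataset
#'
#' One row per trait type: trait count, mean (sample sd) regions per trait,
#' genes per trait (deduplicated) and genes per region.
#'
#' @param dataset a filtered `qtl_dataset`.
#' @return data.frame with columns `trait_type`, `n_traits`,
#'   `regions_per_trait`, `genes_per_trait`, `genes_per_region` (each a
#'   `"mean (sd)"` string) plus numeric columns for downstream use.
#' @export
dataset_summary <- function(dataset) {
  types <- c("macroscopic", "metabolite", "expression")
  fmt <- function(x) {
    if (length(x) == 0L) return("0 (0)")
    s <- if (length(x) > 1L) stats::sd(x) else 0
    sprintf("%.1f (%.1f)", mean(x), s)
  }
  tg <- trait_gene_sets(dataset)
  rows <- lapply(types, function(ty) {
    tr <- dataset$traits$trait_id[dataset$traits$trait_type == ty]
    reg_counts <- as.integer(table(factor(dataset$regions$trait_id,
                                          levels = tr)))
    gene_counts <- lengths(tg[tr])
    reg_ids <- dataset$regions$region_id[dataset$regions$trait_id %in% tr]
    per_region <- lengths(dataset$region_genes[reg_ids])
    data.frame(trait_type = ty, n_traits = length(tr),
               regions_per_trait = fmt(reg_counts),
               genes_per_trait = fmt(gene_counts),
               genes_per_region = fmt(per_region),
               mean_regions = if (length(reg_counts)) mean(reg_counts) else 0,
               mean_genes_per_trait =
                 if (length(gene_counts)) mean(gene_counts) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
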