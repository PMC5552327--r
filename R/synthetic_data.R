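#' Specification of a synthetic benchmark dataset
#'
#' Describes the world the generator emulates: a DAG-structured ontology per
#' namespace with power-law term usage, genes tiled along chromosomes, and
#' traits of three types whose QTL regions recurrently contain genes carrying
#' planted "signal" terms. Defaults mirror the published dataset shape at
#' desk scale: a handful of regions per trait, tens of genes per region, and
#' signal terms specific enough to pass the 1% generality filter.
#'
#' @param n_terms terms per namespace (excluding nothing; root included).
#' @param dag_depth maximum depth of the ontology DAG.
#' @param diamond_fraction fraction of non-root terms given a second parent.
#' @param n_genes genes in the genome.
#' @param n_chromosomes chromosomes; genes are tiled evenly across them.
#' @param gene_length,gene_spacing base pairs per gene and between genes.
#' @param annotation_rate mean direct terms per gene per namespace (Poisson).
#' @param powerlaw_alpha exponent of the power-law term-usage weights.
#' @param n_traits named vector: traits per type.
#' @param regions_range inclusive range of regions per (unplanted) trait.
#' @param region_length_range inclusive bp range of region lengths.
#' @param n_planted_traits traits carrying a planted signal (assigned to
#'   types round-robin), grouped in `group_size`-sized groups that share
#'   signal terms.
#' @param group_size planted traits per group.
#' @param signal_terms_per_group signal (leaf) terms per group per namespace.
#' @param carriers_per_term genes annotated with each group's signal terms;
#'   defaults to 1% of the genome so signal terms sit exactly at the
#'   generality boundary (kept by the `<=` rule).
#' @param planted_regions regions per planted trait.
#' @param planting_prob probability that a planted trait's region is centered
#'   on a carrier gene (0 gives a pure null dataset).
#' @param generality_max_fraction the generality cap the downstream pipeline
#'   will use; the generator warns when planted terms would exceed it.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_terms = 200L, dag_depth = 5L,
                           diamond_fraction = 0.1,
                           n_genes = 500L, n_chromosomes = 5L,
                           gene_length = 3000L, gene_spacing = 2000L,
                           annotation_rate = 3, powerlaw_alpha = 1.2,
                           n_traits = c(macroscopic = 10L, metabolite = 10L,
                                        expression = 10L),
                           regions_range = c(3L, 6L),
                           region_length_range = c(10000L, 20000L),
                           n_planted_traits = 10L, group_size = 2L,
                           signal_terms_per_group = 4L,
                           carriers_per_term = NULL,
                           planted_regions = 4L,
                           planting_prob = 1,
                           generality_max_fraction = 0.01) {
  if (is.null(carriers_per_term))
    carriers_per_term <- max(3L, floor(generality_max_fraction * n_genes))
  if (n_planted_traits > 0L &&
      carriers_per_term > generality_max_fraction * n_genes)
    warning("planted signal terms annotate more than ",
            sprintf("%.1f%%", 100 * generality_max_fraction),
            " of genes; the pipeline's generality filter will reject them")
  stopifnot(n_terms >= 10L, dag_depth >= 1L, n_genes >= 10L,
            n_chromosomes >= 1L, annotation_rate > 0,
            all(n_traits >= 0L), n_planted_traits <= sum(n_traits),
            planting_prob >= 0, planting_prob <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a random ontology namespace
#'
#' Rooted DAG: each term gets one uniformly chosen parent among shallower
#' existing terms, then a fraction of terms receive a second parent (always
#' an earlier term, which keeps the graph acyclic). Draws from the current
#' RNG stream.
#'
#' @param n_terms number of terms including the root.
#' @param namespace `"BP"` or `"MF"` (controls ids and the OBO namespace
#'   tag).
#' @param dag_depth maximum depth.
#' @param diamond_fraction fraction of non-root terms with two parents.
#' @return data.frame `term_id`, `name`, `depth`, `parent1`, `parent2`
#'   (`NA` when absent), `is_leaf`.
#' @export
generate_ontology <- function(n_terms, namespace = c("BP", "MF"),
                              dag_depth = 5L, diamond_fraction = 0.1) {
  namespace <- match.arg(namespace)
  pref <- if (namespace == "BP") "GO:1%06d" else "GO:2%06d"
  ids <- sprintf(pref, seq_len(n_terms))
  depth <- integer(n_terms); depth[1L] <- 0L
  parent1 <- rep(NA_character_, n_terms)
  parent2 <- rep(NA_character_, n_terms)
  for (i in seq_len(n_terms)[-1L]) {
    elig <- which(depth[seq_len(i - 1L)] < dag_depth)
    p <- if (length(elig) == 1L) elig else sample(elig, 1L)
    parent1[i] <- ids[p]
    depth[i] <- depth[p] + 1L
  }
  extra <- which(seq_len(n_terms) > 2L &
                 stats::runif(n_terms) < diamond_fraction)
  for (i in extra) {
    cand <- setdiff(seq_len(i - 1L), match(parent1[i], ids))
    if (length(cand) == 0L) next
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    parent2[i] <- ids[p]
  }
  has_child <- ids %in% c(parent1, parent2)
  data.frame(term_id = ids,
             name = sprintf("synthetic %s term %d",
                            tolower(namespace), seq_len(n_terms)),
             depth = depth, parent1 = parent1, parent2 = parent2,
             is_leaf = !has_child, stringsAsFactors = FALSE)
}

ontology_to_obo <- function(ontologies) {
  ns_long <- c(BP = "biological_process", MF = "molecular_function")
  out <- c("format-version: 1.2", "ontology: synthetic")
  for (nsv in names(ontologies)) {
    df <- ontologies[[nsv]]
    for (i in seq_len(nrow(df))) {
      out <- c(out, "", "[Term]",
               paste0("id: ", df$term_id[i]),
               paste0("name: ", df$name[i]),
               paste0("namespace: ", ns_long[[nsv]]))
      if (!is.na(df$parent1[i]))
        out <- c(out, paste0("is_a: ", df$parent1[i]))
      if (!is.na(df$parent2[i]))
        out <- c(out, paste0("is_a: ", df$parent2[i]))
    }
  }
  out
}

#' Generate genome coordinates and background annotations
#'
#' Genes are tiled without overlap across chromosomes (constant length and
#' spacing). Direct annotations per gene and namespace are Poisson in number
#' and drawn without replacement with power-law weights over the background
#' term pool (signal terms are reserved and excluded from the background so
#' their genome frequency is exactly the planted carrier count). Draws from
#' the current RNG stream.
#'
#' @param spec a `synthetic_spec`.
#' @param ontologies named list (`BP`, `MF`) of ontology data.frames.
#' @param reserved_terms character vector of term ids excluded from
#'   background sampling.
#' @return list with `genes` (a `gene_loci` data.frame), `chrom_lengths`,
#'   and `direct` (named list per namespace: gene -> direct term ids).
#' @export
generate_genome_and_annotations <- function(spec, ontologies,
                                            reserved_terms = character(0)) {
  per_chrom <- ceiling(spec$n_genes / spec$n_chromosomes)
  chrom <- rep(sprintf("chr%d", seq_len(spec$n_chromosomes)),
               each = per_chrom)[seq_len(spec$n_genes)]
  idx <- stats::ave(seq_len(spec$n_genes), chrom, FUN = seq_along)
  pitch <- spec$gene_length + spec$gene_spacing
  start <- (idx - 1L) * pitch
  genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(spec$n_genes)),
                      chrom = chrom, start = start,
                      end = start + spec$gene_length,
                      strand = rep(c("+", "-"),
                                   length.out = spec$n_genes),
                      stringsAsFactors = FALSE)
  chrom_lengths <- tapply(genes$end + spec$gene_spacing, genes$chrom, max)
  chrom_lengths <- chrom_lengths[unique(chrom)]
  genes <- structure(genes, chrom_lengths = chrom_lengths,
                     class = c("gene_loci", "data.frame"))
  direct <- list()
  for (nsv in names(ontologies)) {
    df <- ontologies[[nsv]]
    pool <- setdiff(df$term_id[df$depth > 0L], reserved_terms)
    w <- seq_along(pool)^(-spec$powerlaw_alpha)
    w <- sample(w)  # random assignment of weights to terms
    n_per_gene <- pmin(stats::rpois(spec$n_genes, spec$annotation_rate),
                       length(pool))
    ann <- lapply(seq_len(spec$n_genes), function(g) {
      if (n_per_gene[g] == 0L) return(character(0))
      sample(pool, n_per_gene[g], prob = w)
    })
    names(ann) <- genes$gene_id
    direct[[nsv]] <- ann
  }
  list(genes = genes, chrom_lengths = chrom_lengths, direct = direct)
}

pick_signal_terms <- function(ontology, n, min_depth = 2L) {
  # mid-depth leaves pass the generality filter yet carry informative IC;
  # prefer leaves whose parent has several children so background
  # annotation reliably pushes the parent above the generality cap
  df <- ontology
  sibling_count <- table(df$parent1)
  cand <- df$term_id[df$is_leaf & df$depth >= min_depth]
  if (length(cand) < n)
    cand <- df$term_id[df$is_leaf]
  nsib <- as.integer(sibling_count[df$parent1[match(cand, df$term_id)]])
  nsib[is.na(nsib)] <- 0L
  cand <- cand[order(-nsib, cand)]
  pref <- cand[seq_len(min(length(cand), max(n * 2L, n)))]
  sample(pref, n)
}

#' Generate a full synthetic dataset with planted functional signals
#'
#' Builds the ontology (BP and MF), genome, background annotations, planted
#' carrier genes and the QTL region tables, plus a ground-truth table of
#' every planted trait-term pair and group membership. With
#' `planting_prob = 0` the dataset is a pure null. Fully deterministic given
#' `seed`.
#'
#' @param spec a `synthetic_spec`.
#' @param seed integer seed.
#' @param dir optional directory; when given, writes `ontology.obo`,
#'   `genome.gff3`, `annotations_BP.tsv`, `annotations_MF.tsv`, `qtl.tsv`
#'   and `ground_truth.tsv`.
#' @return list with `graph` (`OntologyGraph`), `genes`, `corpora`
#'   (propagated `AnnotationCorpus` per namespace), `qtl_regions`
#'   (data.frame), `dataset` (`qtl_dataset`), `ground_truth` (data.frame
#'   `trait_id`, `group`, `namespace`, `term_id`), `files` (paths or NULL).
#' @export
generate_synthetic_dataset <- function(spec = synthetic_spec(), seed = 1L,
                                       dir = NULL) {
  ontologies <- with_substream(seed, "ontology", list(
    BP = generate_ontology(spec$n_terms, "BP", spec$dag_depth,
                           spec$diamond_fraction),
    MF = generate_ontology(spec$n_terms, "MF", spec$dag_depth,
                           spec$diamond_fraction)))

  n_groups <- if (spec$n_planted_traits > 0L)
    ceiling(spec$n_planted_traits / spec$group_size) else 0L
  signal <- with_substream(seed, "signals", {
    lapply(stats::setNames(nm = names(ontologies)), function(nsv) {
      if (n_groups == 0L) return(rep(list(character(0)), 0L))
      terms <- pick_signal_terms(ontologies[[nsv]],
                                 n_groups * spec$signal_terms_per_group)
      split(terms, rep(seq_len(n_groups), each = spec$signal_terms_per_group))
    })
  })
  reserved <- unique(unlist(signal, use.names = FALSE))

  gen <- with_substream(seed, "genome_annotations",
                        generate_genome_and_annotations(spec, ontologies,
                                                        reserved))
  genes <- gen$genes

  # carrier genes: per group, carriers_per_term genes annotated with all of
  # the group's signal terms (both namespaces); carriers are kept at least
  # one maximal region length apart so distinct causal loci never fall into
  # one region
  carriers <- with_substream(seed, "carriers", {
    if (n_groups == 0L) list() else {
      min_sep <- spec$region_length_range[2L]
      ord <- sample(seq_len(nrow(genes)))
      picked <- integer(0)
      for (i in ord) {
        ok <- !any(genes$chrom[picked] == genes$chrom[i] &
                     abs(genes$start[picked] - genes$start[i]) < min_sep)
        if (ok) picked <- c(picked, i)
        if (length(picked) >= n_groups * spec$carriers_per_term) break
      }
      if (length(picked) < n_groups * spec$carriers_per_term)
        stop("genome too small to place separated carrier genes")
      pool <- genes$gene_id[picked]
      lapply(seq_len(n_groups), function(g)
        pool[((g - 1L) * spec$carriers_per_term + 1L):
               (g * spec$carriers_per_term)])
    }
  })
  for (nsv in names(signal)) {
    for (g in seq_along(carriers)) {
      for (cg in carriers[[g]]) {
        gen$direct[[nsv]][[cg]] <- unique(c(gen$direct[[nsv]][[cg]],
                                            signal[[nsv]][[g]]))
      }
    }
  }

  # trait table: planted traits assigned to types round-robin
  types <- rep(names(spec$n_traits), spec$n_traits)
  trait_ids <- sprintf("%s_%02d", substr(types, 1L, 3L),
                       stats::ave(seq_along(types), types, FUN = seq_along))
  planted_idx <- integer(0)
  if (spec$n_planted_traits > 0L) {
    by_type <- split(seq_along(types), types)
    ord <- unlist(lapply(seq_len(max(lengths(by_type))), function(i)
      vapply(by_type, function(v) if (i <= length(v)) v[[i]] else NA_integer_,
             1L)), use.names = FALSE)
    ord <- ord[!is.na(ord)]
    planted_idx <- ord[seq_len(spec$n_planted_traits)]
  }
  group_of <- stats::setNames(rep(NA_integer_, length(types)), trait_ids)
  if (length(planted_idx))
    group_of[planted_idx] <- rep(seq_len(n_groups),
                                 each = spec$group_size)[
                                   seq_along(planted_idx)]

  regions <- with_substream(seed, "qtl_regions", {
    rows <- list()
    for (i in seq_along(trait_ids)) {
      g <- group_of[[i]]
      rr <- seq(spec$regions_range[1L], spec$regions_range[2L])
      k <- if (!is.na(g)) spec$planted_regions else
        if (length(rr) == 1L) rr else sample(rr, 1L)
      carr <- if (!is.na(g)) sample(rep(carriers[[g]], length.out = k)) else NULL
      for (r in seq_len(k)) {
        len <- round(stats::runif(1L, spec$region_length_range[1L],
                                  spec$region_length_range[2L]))
        planted_here <- !is.na(g) && stats::runif(1L) < spec$planting_prob
        if (planted_here) {
          gi <- match(carr[[r]], genes$gene_id)
          ch <- genes$chrom[gi]
          center <- (genes$start[gi] + genes$end[gi]) / 2
          start <- round(center - len / 2)
        } else {
          ch <- sample(names(gen$chrom_lengths), 1L)
          start <- floor(stats::runif(1L, 0,
                                      max(1, gen$chrom_lengths[[ch]] - len)))
        }
        start <- max(0, min(start, gen$chrom_lengths[[ch]] - len))
        rows[[length(rows) + 1L]] <- data.frame(
          trait_id = trait_ids[[i]], trait_type = types[[i]], chrom = ch,
          start = start, end = start + len, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  regions$region_id <- sprintf("%s_r%d", regions$trait_id,
                               stats::ave(seq_len(nrow(regions)),
                                          regions$trait_id, FUN = seq_along))
  regions <- regions[, c("region_id", "trait_id", "trait_type", "chrom",
                         "start", "end")]

  gt_rows <- list()
  for (nsv in names(signal)) {
    for (i in which(!is.na(group_of))) {
      g <- group_of[[i]]
      for (t in signal[[nsv]][[g]]) {
        gt_rows[[length(gt_rows) + 1L]] <- data.frame(
          trait_id = trait_ids[[i]], group = g, namespace = nsv,
          term_id = t, stringsAsFactors = FALSE)
      }
    }
  }
  ground_truth <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    data.frame(trait_id = character(0), group = integer(0),
               namespace = character(0), term_id = character(0))

  obo_lines <- ontology_to_obo(ontologies)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(obo = file.path(dir, "ontology.obo"),
                  gff3 = file.path(dir, "genome.gff3"),
                  ann_bp = file.path(dir, "annotations_BP.tsv"),
                  ann_mf = file.path(dir, "annotations_MF.tsv"),
                  qtl = file.path(dir, "qtl.tsv"),
                  truth = file.path(dir, "ground_truth.tsv"))
    writeLines(obo_lines, files$obo)
    write_gff3(genes, gen$chrom_lengths, files$gff3)
    write_annotation_tsv(gen$direct$BP, files$ann_bp)
    write_annotation_tsv(gen$direct$MF, files$ann_mf)
    utils::write.table(regions[, c("trait_id", "trait_type", "chrom",
                                   "start", "end")],
                       files$qtl, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ground_truth, files$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  tmp <- tempfile(fileext = ".obo")
  writeLines(obo_lines, tmp)
  graph <- parse_obo(tmp)
  unlink(tmp)
  corpora <- lapply(stats::setNames(nm = names(gen$direct)), function(nsv)
    propagate_annotations(graph, gen$direct[[nsv]],
                          n_genes_total = spec$n_genes))
  dataset <- build_qtl_dataset(regions, genes)
  list(graph = graph, genes = genes, corpora = corpora,
       qtl_regions = regions, dataset = dataset,
       ground_truth = ground_truth, files = files, spec = spec, seed = seed)
}

write_gff3 <- function(genes, chrom_lengths, path) {
  head <- c("##gff-version 3",
            sprintf("##sequence-region %s 1 %d", names(chrom_lengths),
                    as.integer(chrom_lengths)))
  body <- sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  genes$chrom, genes$start + 1L, genes$end,
                  ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                  genes$gene_id)
  writeLines(c(head, body), path)
}

write_annotation_tsv <- function(direct, path) {
  direct <- direct[lengths(direct) > 0L]
  genes <- rep(names(direct), lengths(direct))
  terms <- unlist(direct, use.names = FALSE)
  writeLines(c("gene_id\tterm_id", sprintf("%s\t%s", genes, terms)), path)
}
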