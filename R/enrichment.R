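#' Number of a trait's regions in which a term occurs
#'
#' A term occurs in a region when at least one gene of the region carries the
#' term in its propagated annotation set (true-path rule: a gene annotated to
#' a child counts as occurrence of every ancestor).
#'
#' @param dataset a `qtl_dataset`.
#' @param trait_id trait identifier.
#' @param term_id term identifier.
#' @param corpus a propagated `AnnotationCorpus`.
#' @return integer count of regions.
#' @export
occurrence_count <- function(dataset, trait_id, term_id, corpus) {
  reg_ids <- dataset$regions$region_id[dataset$regions$trait_id == trait_id]
  sum(vapply(dataset$region_genes[reg_ids], function(gg) {
    any(vapply(corpus$propagated[gg], function(tt) term_id %in% tt, TRUE))
  }, TRUE))
}

#' Minimum occurrence count implied by the occurrence fraction
#'
#' Smallest integer `c` with `c / n_regions >= occurrence_fraction`, i.e.
#' `ceiling(fraction * n_regions)`. With the default fraction 0.5 a trait
#' with 5 regions needs the term in at least 3 of them.
#'
#' @param n_regions number of regions of the trait.
#' @param occurrence_fraction minimum fraction (default 0.5).
#' @return integer threshold.
#' @export
occurrence_threshold <- function(n_regions, occurrence_fraction = 0.5) {
  stopifnot(n_regions >= 1L)
  as.integer(ceiling(occurrence_fraction * n_regions - 1e-9))
}

#' One-sided Fisher (hypergeometric upper-tail) p-value
#'
#' Probability of observing `k` or more term-carrying genes in a sample of
#' `n` trait genes, given `K` carriers among `N` annotated genome genes.
#'
#' @param k genes in the trait set carrying the term.
#' @param K genes in the genome carrying the term.
#' @param n trait gene-set size.
#' @param N annotated genome size.
#' @return p-value in `(0, 1]`; vectorized over its arguments.
#' @export
fisher_pvalue <- function(k, K, n, N) {
  if (any(k > K) || any(k > n) || any(n > N) || any(K > N) || any(k < 0))
    stop("inconsistent contingency bounds")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Textbook step-up: sort ascending, multiply by `m / rank`, enforce
#' monotonicity with a running minimum from the largest p down, cap at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same order as input.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Generality filter: is a term specific enough to keep?
#'
#' Keeps a term iff it annotates at most `generality_max_fraction` of all
#' genes (default 1%); strictly more than the threshold excludes it. Removes
#' uninformative high-level terms before enrichment.
#'
#' @param corpus an `AnnotationCorpus`.
#' @param term_id term id (vectorized).
#' @param generality_max_fraction maximum annotated fraction.
#' @return logical, `TRUE` to keep.
#' @export
generality_filter <- function(corpus, term_id, generality_max_fraction = 0.01) {
  count <- corpus$term_gene_count[term_id]
  count[is.na(count)] <- 0L
  unname(count / corpus$n_genes_total <= generality_max_fraction + 1e-12)
}

#' Link traits to overrepresented terms
#'
#' For each trait: the candidate universe is the set of propagated terms of
#' its genes passing the generality filter; a one-sided Fisher test against
#' the annotated genome background gives `p_raw`; BH within the trait's
#' candidate set (or globally with `config$global_correction`) gives `p_adj`;
#' links are retained when `p_adj <= enrichment_fdr` AND the term occurs in
#' at least `occurrence_threshold` of the trait's regions. Output is ordered
#' by (trait_id, p_adj, term_id).
#'
#' @param dataset a filtered `qtl_dataset`.
#' @param corpus a propagated `AnnotationCorpus` (one namespace).
#' @param graph the `OntologyGraph`.
#' @param config a `pipeline_config`.
#' @return data.frame of trait-term links with columns `trait_id`,
#'   `trait_type`, `namespace`, `term_id`, `term_name`, `p_raw`, `p_adj`,
#'   `occ_regions`, `n_regions`, `k_trait`, `K_genome`, `n_trait`,
#'   `N_genome`.
#' @export
link_traits_to_terms <- function(dataset, corpus, graph,
                                 config = pipeline_config()) {
  N <- corpus$n_annotated_genes
  ttypes <- stats::setNames(dataset$traits$trait_type, dataset$traits$trait_id)
  tg <- trait_gene_sets(dataset)
  keep_general <- names(corpus$term_gene_count)[
    generality_filter(corpus, names(corpus$term_gene_count),
                      config$generality_max_fraction)]

  acc <- list()
  for (tid in dataset$traits$trait_id) {
    genes <- intersect(tg[[tid]], names(corpus$propagated))
    if (length(genes) == 0L) next
    counts <- table(unlist(corpus$propagated[genes], use.names = FALSE))
    cand <- intersect(names(counts), keep_general)
    if (length(cand) == 0L) next
    k <- as.integer(counts[cand])
    K <- as.integer(corpus$term_gene_count[cand])
    n <- length(genes)
    p <- fisher_pvalue(k, K, n, N)

    reg_ids <- dataset$regions$region_id[dataset$regions$trait_id == tid]
    region_terms <- lapply(dataset$region_genes[reg_ids], function(gg)
      unique(unlist(corpus$propagated[intersect(gg, names(corpus$propagated))],
                    use.names = FALSE)))
    occm <- vapply(region_terms, function(tt) cand %in% tt,
                   logical(length(cand)))
    occ <- rowSums(matrix(occm, nrow = length(cand)))
    acc[[tid]] <- list(trait_id = rep(tid, length(cand)),
                       term_id = cand, p_raw = p,
                       occ_regions = as.integer(occ),
                       n_regions = rep(length(reg_ids), length(cand)),
                       k_trait = k, K_genome = K,
                       n_trait = rep(n, length(cand)))
  }
  if (length(acc) == 0L) return(empty_links(corpus$namespace))
  pull <- function(f) unlist(lapply(acc, `[[`, f), use.names = FALSE)
  res <- data.frame(trait_id = pull("trait_id"),
                    term_id = pull("term_id"), p_raw = pull("p_raw"),
                    p_adj = NA_real_, occ_regions = pull("occ_regions"),
                    n_regions = pull("n_regions"), k_trait = pull("k_trait"),
                    K_genome = pull("K_genome"), n_trait = pull("n_trait"),
                    stringsAsFactors = FALSE)
  res$trait_type <- unname(ttypes[res$trait_id])
  res$namespace <- corpus$namespace
  res$N_genome <- N

  if (isTRUE(config$global_correction)) {
    res$p_adj <- bh_adjust(res$p_raw)
  } else {
    for (tid in unique(res$trait_id)) {
      i <- res$trait_id == tid
      res$p_adj[i] <- bh_adjust(res$p_raw[i])
    }
  }
  thr <- occurrence_threshold(res$n_regions, config$occurrence_fraction)
  res <- res[res$p_adj <= config$enrichment_fdr + 1e-12 &
               res$occ_regions >= thr, , drop = FALSE]
  res <- res[order(res$trait_id, res$p_adj, res$term_id), , drop = FALSE]
  res$term_name <- graph$terms[res$term_id, "name"]
  rownames(res) <- NULL
  res[, c("trait_id", "trait_type", "namespace", "term_id", "term_name",
          "p_raw", "p_adj", "occ_regions", "n_regions", "k_trait",
          "K_genome", "n_trait", "N_genome")]
}

empty_links <- function(namespace = NA_character_) {
  data.frame(trait_id = character(0), trait_type = character(0),
             namespace = character(0), term_id = character(0),
             term_name = character(0), p_raw = numeric(0),
             p_adj = numeric(0), occ_regions = integer(0),
             n_regions = integer(0), k_trait = integer(0),
             K_genome = integer(0), n_trait = integer(0),
             N_genome = integer(0), stringsAsFactors = FALSE)
}
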