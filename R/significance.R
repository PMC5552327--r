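#' Sample random genome regions matching a template
#'
#' Draws, for each template region, a region of the identical base-pair
#' length placed uniformly over all valid (chromosome, start) positions
#' genome-wide (placement is not restricted to the template's chromosome and
#' sampled regions may overlap each other).
#'
#' @param genome a `gene_loci` data.frame with a `chrom_lengths` attribute.
#' @param template_regions data.frame with `region_id`, `trait_id`,
#'   `trait_type`, `chrom`, `start`, `end` (0-based half-open).
#' @return data.frame with the same columns and region lengths, random
#'   placements; draws from the current RNG stream.
#' @export
sample_random_regions <- function(genome, template_regions) {
  lens <- attr(genome, "chrom_lengths")
  if (is.null(lens)) stop("genome is missing chromosome lengths")
  chroms <- names(lens)
  out <- template_regions
  reg_len <- template_regions$end - template_regions$start
  u_ch <- stats::runif(nrow(out))
  u_pos <- stats::runif(nrow(out))
  for (i in seq_len(nrow(out))) {
    L <- reg_len[[i]]
    valid <- lens[lens >= L]
    if (length(valid) == 0L)
      stop("region of length ", L, " does not fit any chromosome")
    # uniform over all valid start positions genome-wide:
    # chromosome chosen with probability proportional to (len - L + 1)
    wts <- cumsum(valid - L + 1)
    ci <- sum(wts < u_ch[[i]] * wts[[length(wts)]]) + 1L
    ch <- names(valid)[[ci]]
    start <- min(floor(u_pos[[i]] * (valid[[ci]] - L + 1)), valid[[ci]] - L)
    out$chrom[[i]] <- ch
    out$start[[i]] <- start
    out$end[[i]] <- start + L
  }
  out
}

#' Counts of trait pairs at or above similarity thresholds
#'
#' Shared entry point for the observed data and every region-permutation
#' replicate: runs enrichment (per namespace), builds similarity matrices and
#' counts trait pairs with similarity >= each threshold, per namespace and
#' pooled. Namespaces with fewer than 2 linked traits contribute zero pairs.
#'
#' @param dataset a `qtl_dataset` (regions already mapped to genes,
#'   unfiltered; filters from `config` are applied here so permutation
#'   replicates traverse the identical code path).
#' @param corpora named list of `AnnotationCorpus` objects, e.g.
#'   `list(BP = ..., MF = ...)`.
#' @param graph the `OntologyGraph`.
#' @param config a `pipeline_config`.
#' @param thresholds numeric vector of similarity levels in `(0, 1]`.
#' @return named list: one integer vector of counts per namespace plus
#'   `"pooled"`, each named by threshold.
#' @export
similarity_pair_counts <- function(dataset, corpora, graph, config,
                                   thresholds = c(1, 0.95, 0.9)) {
  filtered <- apply_filters(dataset, config)
  sims <- list()
  for (nsv in names(corpora)) {
    links <- link_traits_to_terms(filtered, corpora[[nsv]], graph, config)
    sims[[nsv]] <- if (length(unique(links$trait_id)) >= 2L) {
      m <- similarity_matrix(links, corpora[[nsv]], graph,
                             symmetric = config$symmetric_bma)
      m$values[upper.tri(m$values)]
    } else numeric(0)
  }
  counts <- lapply(sims, function(v)
    stats::setNames(vapply(thresholds, function(th) sum(v >= th - 1e-12), 0L),
                    as.character(thresholds)))
  counts$pooled <- stats::setNames(
    vapply(thresholds, function(th)
      sum(unlist(sims, use.names = FALSE) >= th - 1e-12), 0L),
    as.character(thresholds))
  counts
}

#' Region-randomization permutation test (scheme i)
#'
#' The observed statistic is the number of trait pairs with semantic
#' similarity at or above a threshold. The null is built by rerunning the
#' entire pipeline (overrepresentation with identical filters, then
#' similarity) on random genome regions that match each trait's region count
#' and lengths. `p = (1 + #\{null >= observed\}) / (n_reps + 1)`.
#'
#' @param dataset the observed `qtl_dataset` (unfiltered).
#' @param genome the `gene_loci` genome (for random placement and overlap).
#' @param corpora named list of `AnnotationCorpus` objects.
#' @param graph the `OntologyGraph`.
#' @param config a `pipeline_config`.
#' @param thresholds similarity levels to test (default the published set
#'   1, 0.95, 0.9).
#' @param n_reps permutation replicates (default from config).
#' @param seed master seed (default from config); each replicate uses a
#'   named substream so runs are reproducible and restartable.
#' @return data.frame with one row per (namespace-or-pooled, threshold):
#'   `scope`, `threshold`, `observed`, `null_mean`, `null_sd`, `p_value`,
#'   `n_reps`, `seed`; attribute `null_stats` holds the full null matrices.
#' @export
region_permutation_test <- function(dataset, genome, corpora, graph,
                                    config = pipeline_config(),
                                    thresholds = c(1, 0.95, 0.9),
                                    n_reps = config$n_permutations,
                                    seed = config$rng_seed) {
  stopifnot(all(thresholds > 0 & thresholds <= 1))
  observed <- similarity_pair_counts(dataset, corpora, graph, config,
                                     thresholds)
  scopes <- names(observed)
  null_stats <- lapply(observed, function(x)
    matrix(NA_integer_, n_reps, length(thresholds),
           dimnames = list(NULL, as.character(thresholds))))
  for (r in seq_len(n_reps)) {
    counts <- with_substream(seed, paste0("region_perm_rep_", r), {
      ok <- FALSE; attempt <- 0L; cts <- NULL
      while (!ok && attempt < 5L) {
        attempt <- attempt + 1L
        rand_regions <- sample_random_regions(genome, dataset$regions)
        cts <- tryCatch({
          rd <- build_qtl_dataset(rand_regions, genome)
          similarity_pair_counts(rd, corpora, graph, config, thresholds)
        }, error = function(e) NULL)
        ok <- !is.null(cts)
      }
      if (is.null(cts)) stop("permutation replicate failed after 5 attempts")
      cts
    })
    for (sc in scopes) null_stats[[sc]][r, ] <- counts[[sc]]
  }
  rows <- list()
  for (sc in scopes) {
    for (th in as.character(thresholds)) {
      nulls <- null_stats[[sc]][, th]
      obs <- observed[[sc]][[th]]
      rows[[length(rows) + 1L]] <- data.frame(
        scope = sc, threshold = as.numeric(th), observed = obs,
        null_mean = mean(nulls), null_sd = stats::sd(nulls),
        p_value = (1 + sum(nulls >= obs)) / (n_reps + 1),
        n_reps = n_reps, seed = seed, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), null_stats = null_stats)
}

#' Shuffle trait-term links (scheme ii null)
#'
#' Randomly reassigns terms to traits keeping the number of traits, the
#' global term multiset and the per-trait link counts fixed. A trait-term
#' link is a set membership, so duplicate terms within one trait after
#' shuffling are resolved by repair swaps; if no duplicate-free assignment is
#' found (pathological small inputs) duplicates are allowed with a warning.
#'
#' @param links trait-term link data.frame (columns `trait_id`, `term_id`
#'   used; other columns carried along).
#' @return links with the `term_id` column permuted; draws from the current
#'   RNG stream.
#' @export
shuffle_trait_term_links <- function(links) {
  if (nrow(links) == 0L) stop("cannot shuffle an empty link set")
  terms <- sample(links$term_id)
  trait <- links$trait_id
  for (pass in 1:200) {
    dup <- which(stats::ave(seq_along(terms), trait, terms,
                            FUN = seq_along) > 1L)
    if (length(dup) == 0L) break
    for (i in dup) {
      js <- sample(length(terms))
      swapped <- FALSE
      for (j in js) {
        if (trait[j] == trait[i]) next
        # swap i<->j must not create duplicates on either side
        if (!terms[i] %in% terms[trait == trait[j]] &&
            !terms[j] %in% terms[trait == trait[i] & seq_along(terms) != i]) {
          tmp <- terms[i]; terms[i] <- terms[j]; terms[j] <- tmp
          swapped <- TRUE
          break
        }
      }
      if (!swapped) next
    }
  }
  if (length(unique(paste(trait, terms))) < length(terms))
    warning("could not remove duplicate trait-term pairs; allowing duplicates")
  out <- links
  out$term_id <- terms
  out
}

#' Significance of maximum-similarity links (scheme ii)
#'
#' For each observed max-similarity link, the null distribution of the
#' source trait's maximum similarity within the target category is built
#' from `n_reps` shuffles of the trait-term links;
#' `p = (1 + #\{null >= observed\}) / (n_reps + 1)`, followed by BH across
#' all links at `config$linkage_fdr`. A trait absent from a replicate
#' contributes maximum similarity 0 for that replicate.
#'
#' @param links observed trait-term links (one namespace).
#' @param corpus,graph annotation corpus and ontology.
#' @param config a `pipeline_config`.
#' @param n_reps replicates (default from config).
#' @param seed master seed (default from config).
#' @return data.frame of max-similarity links with `p_value`, `p_adj` and
#'   `significant` columns.
#' @export
maxsim_link_significance <- function(links, corpus, graph,
                                     config = pipeline_config(),
                                     n_reps = config$n_permutations,
                                     seed = config$rng_seed) {
  ts <- termsim_matrix(corpus, graph, unique(links$term_id))
  obs_matrix <- similarity_matrix(links, corpus, graph,
                                  symmetric = config$symmetric_bma,
                                  termsim = ts)
  obs_links <- max_similarity_links(obs_matrix)
  if (nrow(obs_links) == 0L) return(obs_links)
  key <- paste(obs_links$source, obs_links$target_type)
  exceed <- stats::setNames(integer(length(key)), key)
  for (r in seq_len(n_reps)) {
    null_max <- with_substream(seed, paste0("link_shuffle_rep_", r), {
      sh <- shuffle_trait_term_links(links)
      m <- similarity_matrix(sh, corpus, graph,
                             symmetric = config$symmetric_bma,
                             termsim = ts)
      ml <- max_similarity_links(m)
      stats::setNames(ml$similarity, paste(ml$source, ml$target_type))
    })
    got <- null_max[key]
    got[is.na(got)] <- 0  # trait lost from the replicate
    exceed <- exceed + (got >= obs_links$similarity - 1e-12)
  }
  obs_links$p_value <- (1 + unname(exceed)) / (n_reps + 1)
  obs_links$p_adj <- bh_adjust(obs_links$p_value)
  obs_links$significant <- obs_links$p_adj <= config$linkage_fdr + 1e-12
  obs_links
}
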