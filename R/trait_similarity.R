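#' Best-match average similarity between two term sets
#'
#' Symmetric form (default): for each term of X take its best match in Y,
#' average; likewise Y against X; average the two directional means. The
#' one-directional variant (X against Y only) is available with
#' `symmetric = FALSE`.
#'
#' @param terms_x,terms_y character vectors of term ids (non-empty).
#' @param termsim symmetric term-similarity matrix with both sets among its
#'   dimnames (see [termsim_matrix()]).
#' @param symmetric use the symmetrized form (default `TRUE`).
#' @return similarity in `[0, 1]`.
#' @export
best_match_average <- function(terms_x, terms_y, termsim, symmetric = TRUE) {
  if (length(terms_x) == 0L || length(terms_y) == 0L)
    stop("best_match_average is undefined for empty term sets")
  s <- termsim[terms_x, terms_y, drop = FALSE]
  xy <- mean(apply(s, 1L, max))
  if (!symmetric) return(xy)
  yx <- mean(apply(s, 2L, max))
  (xy + yx) / 2
}

#' Trait-trait similarity matrix from trait-term links
#'
#' Builds, per namespace, the best-match-average similarity between the
#' overrepresented term sets of every pair of traits with at least one link.
#' Term-pair similarities are computed once ([termsim_matrix()]) and reused
#' across trait pairs.
#'
#' @param links trait-term link data.frame from [link_traits_to_terms()],
#'   restricted to one namespace.
#' @param corpus the matching `AnnotationCorpus`.
#' @param graph the `OntologyGraph`.
#' @param symmetric use symmetric BMA (default).
#' @param termsim_fun term-level similarity plug-in, default [lin_similarity].
#' @param termsim optional precomputed term-similarity matrix covering all
#'   linked terms (e.g. from [termsim_matrix()]); computed when `NULL`.
#'   Shuffling-based permutation replicates reuse one cache because the
#'   global term multiset is invariant under the shuffle.
#' @return object of class `trait_sim_matrix`: list with `namespace`,
#'   `trait_ids`, `values` (symmetric matrix), `sim_max` (maximum
#'   off-diagonal value), `trait_types` (named), `term_sets` (named list)
#'   and `set_identical` (logical matrix; TRUE when two traits carry exactly
#'   the same term set).
#' @export
similarity_matrix <- function(links, corpus, graph, symmetric = TRUE,
                              termsim_fun = lin_similarity, termsim = NULL) {
  nsv <- unique(links$namespace)
  if (length(nsv) > 1L) stop("links span multiple namespaces")
  term_sets <- lapply(split(links$term_id, links$trait_id), unique)
  trait_ids <- sort(names(term_sets))
  if (length(trait_ids) < 2L)
    stop("need at least 2 traits with links to build a similarity matrix")
  term_sets <- term_sets[trait_ids]
  all_terms <- unique(unlist(term_sets, use.names = FALSE))
  ts <- if (is.null(termsim)) {
    termsim_matrix(corpus, graph, all_terms, termsim_fun = termsim_fun)
  } else {
    stopifnot(all(all_terms %in% rownames(termsim)))
    termsim
  }

  n <- length(trait_ids)
  values <- matrix(0, n, n, dimnames = list(trait_ids, trait_ids))
  ident <- matrix(FALSE, n, n, dimnames = list(trait_ids, trait_ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- best_match_average(term_sets[[i]], term_sets[[j]], ts,
                              symmetric = symmetric)
      values[i, j] <- values[j, i] <- v
      eq <- setequal(term_sets[[i]], term_sets[[j]])
      ident[i, j] <- ident[j, i] <- eq
    }
  }
  off <- values; diag(off) <- NA
  sim_max <- if (n > 1L) max(off, na.rm = TRUE) else NA_real_
  trait_types <- stats::setNames(links$trait_type, links$trait_id)
  trait_types <- trait_types[!duplicated(names(trait_types))][trait_ids]
  structure(list(namespace = if (length(nsv)) nsv else NA_character_,
                 trait_ids = trait_ids, values = values, sim_max = sim_max,
                 trait_types = trait_types, term_sets = term_sets,
                 set_identical = ident),
            class = "trait_sim_matrix")
}

#' Maximum-similarity trait links
#'
#' For every trait, and separately for every trait category present
#' (macroscopic, metabolite, expression), the partner trait with maximum
#' similarity (the trait itself excluded; ties broken by lexicographically
#' smaller trait id).
#'
#' @param matrix a `trait_sim_matrix`.
#' @return data.frame with `source`, `target`, `target_type`, `similarity`,
#'   `namespace`.
#' @export
max_similarity_links <- function(matrix) {
  v <- matrix$values
  types <- matrix$trait_types
  out <- list()
  for (src in matrix$trait_ids) {
    for (ty in sort(unique(types))) {
      cand <- matrix$trait_ids[types == ty & matrix$trait_ids != src]
      if (length(cand) == 0L) next
      sims <- v[src, cand]
      best <- max(sims)
      target <- min(cand[sims == best])  # lexicographic tie-break
      out[[length(out) + 1L]] <- data.frame(
        source = src, target = target, target_type = ty,
        similarity = unname(best), namespace = matrix$namespace,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(source = character(0), target = character(0),
                      target_type = character(0), similarity = numeric(0),
                      namespace = character(0), stringsAsFactors = FALSE)
  res
}

#' Fraction of BP links per trait (f_BP)
#'
#' `f_BP = n_bp / (n_bp + n_mf)`; 1 means only BP links, 0 only MF links,
#' 0.5 the same number of each.
#'
#' @param n_bp,n_mf link counts (vectorized).
#' @return fraction in `[0, 1]`; `NA` where both counts are zero.
#' @export
f_bp <- function(n_bp, n_mf) {
  tot <- n_bp + n_mf
  ifelse(tot >= 1L, n_bp / tot, NA_real_)
}

#' Per-trait f_BP table from BP and MF link sets
#'
#' @param links_bp,links_mf link data.frames for the two namespaces.
#' @return data.frame `trait_id`, `trait_type`, `n_bp`, `n_mf`, `f_bp`;
#'   traits with zero links in both namespaces are excluded.
#' @export
f_bp_table <- function(links_bp, links_mf) {
  tb <- table(links_bp$trait_id)
  tm <- table(links_mf$trait_id)
  ids <- sort(union(names(tb), names(tm)))
  if (length(ids) == 0L)
    return(data.frame(trait_id = character(0), trait_type = character(0),
                      n_bp = integer(0), n_mf = integer(0),
                      f_bp = numeric(0), stringsAsFactors = FALSE))
  n_bp <- as.integer(tb[ids]); n_bp[is.na(n_bp)] <- 0L
  n_mf <- as.integer(tm[ids]); n_mf[is.na(n_mf)] <- 0L
  types <- c(stats::setNames(links_bp$trait_type, links_bp$trait_id),
             stats::setNames(links_mf$trait_type, links_mf$trait_id))
  types <- types[!duplicated(names(types))]
  data.frame(trait_id = ids, trait_type = unname(types[ids]),
             n_bp = n_bp, n_mf = n_mf, f_bp = f_bp(n_bp, n_mf),
             stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided D statistic with the asymptotic p-value, used to compare f_BP
#' distributions across trait types.
#'
#' @param sample_a,sample_b numeric samples, each of size >= 2.
#' @return list with `D` and `p_value`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2L, length(sample_b) >= 2L)
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                        alternative = "two.sided",
                                        exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}
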