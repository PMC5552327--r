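#' Linear similarity-to-distance transform
#'
#' `d(a, b) = sim_max - sim(a, b)` with `sim_max` the maximum off-diagonal
#' similarity, so the most similar observed pair sits at distance 0. The
#' diagonal is forced to 0.
#'
#' @param matrix a `trait_sim_matrix`.
#' @return symmetric numeric distance matrix with a `sim_max` attribute.
#' @export
similarity_to_distance <- function(matrix) {
  d <- matrix$sim_max - matrix$values
  diag(d) <- 0
  attr(d, "sim_max") <- matrix$sim_max
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Naive O(n^3) agglomeration with deterministic tie-breaking: among merge
#' candidates at the minimal linkage distance, the pair whose smallest member
#' label is lexicographically smallest wins (then the second member). Heights
#' are the merge distances themselves, which for complete linkage are
#' non-decreasing.
#'
#' @param dist symmetric distance matrix with dimnames, `n >= 2`, no `NaN`.
#' @return object of class `trait_dendrogram`: list with `merge` (hclust
#'   convention: negative = leaf index, positive = earlier merge), `height`,
#'   `labels`, `members` (list of leaf label sets per merge).
#' @export
complete_linkage <- function(dist) {
  if (any(is.nan(dist))) stop("NaN in distance matrix")
  labels <- rownames(dist)
  n <- nrow(dist)
  stopifnot(n >= 2L, identical(labels, colnames(dist)))
  # active clusters: list of leaf index vectors; id: hclust code
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- vector("list", n - 1L)
  linkage <- function(a, b) max(dist[labels[a], labels[b]])
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- linkage(clusters[[i]], clusters[[j]])
        key <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 &&
             (is.null(best_key) ||
              key[1] < best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])))) {
          best_d <- d; best <- c(i, j); best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- best_d
    members[[step]] <- sort(labels[c(clusters[[i]], clusters[[j]])])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- step
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  structure(list(merge = merge, height = height, labels = labels,
                 members = members),
            class = "trait_dendrogram")
}

#' Convert a dendrogram to hclust
#' @param x a `trait_dendrogram`.
#' @param ... unused.
#' @return a `stats::hclust` object.
#' @export
as.hclust.trait_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = dendro_leaf_order(x), labels = x$labels,
                 method = "complete"),
            class = "hclust")
}

dendro_leaf_order <- function(x) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(x$merge[node, 1L]), rec(x$merge[node, 2L]))
  }
  rec(nrow(x$merge))
}

#' Newick export of a dendrogram
#'
#' Branch lengths are differences of merge heights: a leaf branch spans from
#' height 0 to its parent's merge height, an internal branch from the child
#' merge to the parent merge.
#'
#' @param dendrogram a `trait_dendrogram`.
#' @return single Newick string, terminated with `;`.
#' @export
to_newick <- function(dendrogram) {
  m <- dendrogram$merge
  h <- dendrogram$height
  fmt <- function(x) sub("\\.$", "", sub("0+$", "", sprintf("%.9f", x)))
  min_leaf <- function(node) {
    if (node < 0L) return(dendrogram$labels[-node])
    min(vapply(m[node, ], min_leaf, ""))
  }
  kids_of <- function(node) {          # children ordered by smallest leaf
    kk <- m[node, ]
    kk[order(vapply(kk, min_leaf, ""))]
  }
  rec <- function(node, parent_height) {
    if (node < 0L) {
      return(sprintf("%s:%s", dendrogram$labels[-node], fmt(parent_height)))
    }
    kids <- vapply(kids_of(node), rec, "", parent_height = h[node])
    sprintf("(%s):%s", paste(kids, collapse = ","),
            fmt(parent_height - h[node]))
  }
  root <- nrow(m)
  kids <- vapply(kids_of(root), rec, "", parent_height = h[root])
  paste0("(", paste(kids, collapse = ","), ");")
}

#' Export a trait network in SIF format
#'
#' One line per undirected link, `traitA sim traitB`, with A-B/B-A pairs
#' deduplicated; node attributes (trait type) and edge attributes
#' (similarity, p_adj) as TSVs, plus counts of links per category pair.
#'
#' @param links data.frame of (significant) max-similarity links, columns
#'   `source`, `target`, `target_type`, `similarity` and, when present,
#'   `p_adj`; a `source_type` column may supply source categories, otherwise
#'   `trait_types` is consulted.
#' @param trait_types named character vector trait_id -> type.
#' @param prefix output path prefix; writes `<prefix>.sif`,
#'   `<prefix>_nodes.tsv`, `<prefix>_edges.tsv`.
#' @return invisibly, a list with `sif` lines, `nodes`, `edges` and
#'   `category_counts` data.frames.
#' @export
export_network <- function(links, trait_types, prefix = NULL) {
  if (nrow(links) == 0L) {
    warning("empty link set; writing empty network files")
    edges <- data.frame(a = character(0), b = character(0),
                        similarity = numeric(0), p_adj = numeric(0))
    sif <- character(0)
    nodes <- data.frame(trait_id = character(0), trait_type = character(0))
    cat_counts <- data.frame(category_pair = character(0), n = integer(0))
  } else {
    a <- pmin(links$source, links$target)
    b <- pmax(links$source, links$target)
    keep <- !duplicated(paste(a, b))
    edges <- data.frame(a = a[keep], b = b[keep],
                        similarity = links$similarity[keep],
                        p_adj = if ("p_adj" %in% names(links))
                          links$p_adj[keep] else NA_real_,
                        stringsAsFactors = FALSE)
    sif <- sprintf("%s sim %s", edges$a, edges$b)
    node_ids <- sort(unique(c(edges$a, edges$b)))
    nodes <- data.frame(trait_id = node_ids,
                        trait_type = unname(trait_types[node_ids]),
                        stringsAsFactors = FALSE)
    pair <- apply(cbind(trait_types[edges$a], trait_types[edges$b]), 1L,
                  function(x) paste(sort(x), collapse = "-"))
    tb <- table(pair)
    cat_counts <- data.frame(category_pair = names(tb), n = as.integer(tb),
                             stringsAsFactors = FALSE)
  }
  if (!is.null(prefix)) {
    writeLines(sif, paste0(prefix, ".sif"))
    utils::write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(sif = sif, nodes = nodes, edges = edges,
                 category_counts = cat_counts))
}
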