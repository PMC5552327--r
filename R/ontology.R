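NAMESPACE_MAP <- c(biological_process = "BP", molecular_function = "MF",
                   cellular_component = "CC", BP = "BP", MF = "MF", CC = "CC")

#' Parse an OBO 1.2/1.4 ontology file
#'
#' Reads `[Term]` stanzas into an ontology graph. `is_a` lines and, by
#' default, `relationship: part_of` lines become parent edges (the common
#' practice for annotation propagation). Obsolete terms are retained but
#' flagged and excluded from ancestor queries. Parent edges crossing
#' namespaces are rejected, and the graph must be acyclic.
#'
#' @param path path to an OBO file.
#' @param part_of_as_parent treat `part_of` relationships as parent edges
#'   (default `TRUE`).
#' @return an object of class `OntologyGraph`: a list with
#'   \describe{
#'     \item{terms}{data.frame with `term_id`, `name`, `namespace`
#'       (`"BP"`, `"MF"` or `"CC"`) and `obsolete`.}
#'     \item{parents}{named list mapping `term_id` to character vector of
#'       parent term ids.}
#'     \item{roots}{named character vector, one root term id per namespace.}
#'   }
#' @export
parse_obo <- function(path, part_of_as_parent = TRUE) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas found in ", path)
  other_starts <- grep("^\\[", lines)
  bounds <- c(other_starts, length(lines) + 1L)

  ids <- character(0); names_ <- character(0); ns <- character(0)
  obs <- logical(0); parents <- list()
  for (s in stanza_starts) {
    stop_at <- min(bounds[bounds > s]) - 1L
    block <- lines[(s + 1L):stop_at]
    field <- function(tag) sub(paste0("^", tag, ":\\s*"), "",
                               grep(paste0("^", tag, ":"), block, value = TRUE))
    id <- field("id")
    if (length(id) != 1L) stop("stanza without a single id near line ", s)
    nsv <- field("namespace")
    if (length(nsv) != 1L)
      stop("term ", id, ": missing namespace tag")
    nsv <- NAMESPACE_MAP[nsv]
    if (is.na(nsv)) stop("term ", id, ": unknown namespace")
    isa <- sub("\\s*!.*$", "", field("is_a"))
    if (part_of_as_parent) {
      rel <- field("relationship")
      po <- grep("^part_of\\s", rel, value = TRUE)
      isa <- c(isa, sub("\\s*!.*$", "", sub("^part_of\\s+", "", po)))
    }
    obsolete <- any(grepl("^true", field("is_obsolete")))
    nm <- field("name"); if (length(nm) == 0L) nm <- id
    ids <- c(ids, id); names_ <- c(names_, nm[1L]); ns <- c(ns, unname(nsv))
    obs <- c(obs, obsolete); parents[[id]] <- unique(trimws(isa))
  }
  if (anyDuplicated(ids)) stop("duplicate term ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  terms <- data.frame(term_id = ids, name = names_, namespace = ns,
                      obsolete = obs, stringsAsFactors = FALSE)
  rownames(terms) <- ids

  for (id in ids) {
    for (p in parents[[id]]) {
      if (!p %in% ids) stop("term ", id, ": unknown parent ", p)
      if (terms[p, "namespace"] != terms[id, "namespace"])
        stop("term ", id, ": parent ", p, " is in another namespace")
    }
  }
  graph <- structure(list(terms = terms, parents = parents, roots = NULL,
                          anc_cache = new.env(parent = emptyenv())),
                     class = "OntologyGraph")
  graph$roots <- find_roots(graph)
  check_acyclic(graph)
  graph
}

find_roots <- function(graph) {
  terms <- graph$terms[!graph$terms$obsolete, ]
  roots <- character(0)
  for (nsv in unique(terms$namespace)) {
    tt <- terms$term_id[terms$namespace == nsv]
    r <- tt[vapply(graph$parents[tt], length, 1L) == 0L]
    if (length(r) != 1L)
      stop("namespace ", nsv, " must have exactly one root, found ",
           length(r))
    roots[nsv] <- r
  }
  roots
}

check_acyclic <- function(graph) {
  # Kahn topological sort over child -> parent edges
  ids <- graph$terms$term_id
  indeg <- vapply(graph$parents[ids], length, 1L)
  names(indeg) <- ids
  children <- split(
    rep(ids, lengths(graph$parents[ids])),
    unlist(graph$parents[ids], use.names = FALSE)
  )
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[v]] %||% character(0)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    cyc <- names(indeg)[indeg > 0L]
    stop("ontology contains a cycle involving: ",
         paste(utils::head(cyc, 5L), collapse = " -> "))
  }
  invisible(TRUE)
}

#' Ancestors of a term (including the term itself)
#'
#' Transitive closure over parent edges. Including the query term itself means
#' the most informative common ancestor (MICA) of a pair handles the
#' identical-term and ancestor-descendant cases uniformly.
#'
#' @param graph an `OntologyGraph`.
#' @param term_id a term id present in the graph.
#' @return character vector of ancestor term ids (self included).
#' @export
ancestors <- function(graph, term_id) {
  if (!term_id %in% graph$terms$term_id) stop("unknown term: ", term_id)
  if (isTRUE(graph$terms[term_id, "obsolete"]))
    stop("term ", term_id, " is obsolete")
  anc_of(graph, term_id)
}

# memoised ancestor closure (no obsolete check; internal)
anc_of <- function(graph, term_id) {
  cache <- graph$anc_cache
  hit <- cache[[term_id]]
  if (!is.null(hit)) return(hit)
  res <- term_id
  for (p in graph$parents[[term_id]]) res <- c(res, anc_of(graph, p))
  res <- unique(res)
  cache[[term_id]] <- res
  res
}

#' Read gene-to-term annotations
#'
#' Accepts GAF 2.x (columns 2, 5 and 9: gene id, term id, aspect) or a plain
#' two-column TSV (`gene_id<TAB>term_id`). Returns the direct annotation map
#' restricted to one namespace.
#'
#' @param path annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @param namespace for GAF input, which aspect to keep (`"BP"` or `"MF"`);
#'   ignored for TSV (a TSV is assumed single-namespace).
#' @return named list mapping `gene_id` to a character vector of term ids.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf"),
                             namespace = c("BP", "MF", "CC")) {
  format <- match.arg(format)
  namespace <- match.arg(namespace)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "gaf") {
    aspect_map <- c(P = "BP", F = "MF", C = "CC")
    keep <- vapply(parts, function(p) length(p) >= 9L &&
                     identical(unname(aspect_map[p[[9L]]]), namespace), TRUE)
    parts <- parts[keep]
    genes <- vapply(parts, `[[`, "", 2L)
    terms <- vapply(parts, `[[`, "", 5L)
  } else {
    if (length(parts) && grepl("^gene_id\\b", lines[[1L]])) {
      parts <- parts[-1L]
    }
    bad <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad)) stop("malformed annotation row at line ", bad[[1L]])
    genes <- vapply(parts, `[[`, "", 1L)
    terms <- vapply(parts, `[[`, "", 2L)
  }
  lapply(split(terms, genes), unique)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Closes each gene's direct term set under ancestry, counts genes per term
#' and computes information content `ic(t) = -ln(count(t) / n_annotated)`.
#' Annotations to obsolete terms are dropped with a warning; genes left with
#' zero terms are excluded from the annotated-gene count.
#'
#' @param graph an `OntologyGraph`.
#' @param direct named list gene_id -> character vector of term ids, all in
#'   one namespace.
#' @param n_genes_total total number of genes in the genome, used as the
#'   denominator of the generality filter. Defaults to the number of
#'   annotated genes.
#' @return an object of class `AnnotationCorpus`: list with `namespace`,
#'   `direct`, `propagated`, `term_gene_count`, `n_annotated_genes`,
#'   `n_genes_total` and `ic` (nats).
#' @export
propagate_annotations <- function(graph, direct, n_genes_total = NULL) {
  all_terms <- unique(unlist(direct, use.names = FALSE))
  unknown <- setdiff(all_terms, graph$terms$term_id)
  if (length(unknown)) stop("unknown terms in annotations: ",
                            paste(utils::head(unknown, 5L), collapse = ", "))
  nsv <- unique(graph$terms[all_terms, "namespace"])
  if (length(nsv) > 1L)
    stop("annotations span multiple namespaces: ", paste(nsv, collapse = ", "))
  obsolete <- all_terms[graph$terms[all_terms, "obsolete"]]
  if (length(obsolete)) {
    warning("dropping annotations to obsolete terms: ",
            paste(obsolete, collapse = ", "))
    direct <- lapply(direct, setdiff, y = obsolete)
  }
  direct <- direct[lengths(direct) > 0L]

  anc_sets <- lapply(setdiff(all_terms, obsolete),
                     function(t) anc_of(graph, t))
  names(anc_sets) <- setdiff(all_terms, obsolete)
  propagated <- lapply(direct, function(tt)
    unique(unlist(anc_sets[tt], use.names = FALSE)))

  n_annot <- length(propagated)
  counts <- table(unlist(propagated, use.names = FALSE))
  term_gene_count <- stats::setNames(as.integer(counts), names(counts))
  ic <- -log(term_gene_count / n_annot)
  structure(list(namespace = if (length(nsv)) nsv else NA_character_,
                 direct = direct, propagated = propagated,
                 term_gene_count = term_gene_count,
                 n_annotated_genes = n_annot,
                 n_genes_total = n_genes_total %||% n_annot,
                 ic = ic),
            class = "AnnotationCorpus")
}

#' Lin similarity between two terms
#'
#' `sim(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2))`, where the MICA is the
#' common ancestor (terms included as their own ancestors) with maximal
#' information content. Both terms must carry at least one propagated
#' annotation. The degenerate pair with `IC(t1) + IC(t2) = 0` (both
#' effectively the root) returns 0 so best-match averages stay finite.
#'
#' @param corpus an `AnnotationCorpus`.
#' @param graph the `OntologyGraph` the corpus was built on.
#' @param t1,t2 term ids in the same namespace.
#' @return similarity in `[0, 1]`.
#' @export
lin_similarity <- function(corpus, graph, t1, t2) {
  for (t in c(t1, t2)) {
    if (is.na(corpus$term_gene_count[t]) || corpus$term_gene_count[t] < 1L)
      stop("term ", t, " has no annotated genes; IC undefined")
  }
  if (graph$terms[t1, "namespace"] != graph$terms[t2, "namespace"])
    stop("cross-namespace pair: ", t1, " vs ", t2)
  denom <- corpus$ic[[t1]] + corpus$ic[[t2]]
  if (denom == 0) return(0)
  common <- intersect(anc_of(graph, t1), anc_of(graph, t2))
  ic_common <- corpus$ic[common]
  ic_common <- ic_common[!is.na(ic_common)]
  mica_ic <- if (length(ic_common)) max(ic_common) else 0
  unname(2 * mica_ic / denom)
}

#' Pairwise Lin similarity matrix for a set of terms
#'
#' Computes the upper triangle once and mirrors it; used as the term-level
#' similarity cache shared by all trait pairs. The `termsim_fun` hook allows
#' plugging in an alternative term similarity (e.g. an integrated/adjusted
#' measure); it must have signature `function(corpus, graph, t1, t2)`.
#'
#' @param corpus an `AnnotationCorpus`.
#' @param graph an `OntologyGraph`.
#' @param terms character vector of term ids with positive annotation count.
#' @param termsim_fun term-level similarity function; default [lin_similarity].
#' @return symmetric numeric matrix with `terms` as dimnames.
#' @export
termsim_matrix <- function(corpus, graph, terms,
                           termsim_fun = lin_similarity) {
  terms <- unique(terms)
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  if (n == 0L) return(m)
  anc <- lapply(terms, function(t) anc_of(graph, t))
  ics <- corpus$ic[terms]
  plain_lin <- identical(termsim_fun, lin_similarity)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (plain_lin) {
        denom <- ics[[i]] + ics[[j]]
        if (denom == 0) { s <- 0 } else {
          common <- intersect(anc[[i]], anc[[j]])
          icc <- corpus$ic[common]
          icc <- icc[!is.na(icc)]
          s <- if (length(icc)) 2 * max(icc) / denom else 0
        }
      } else {
        s <- termsim_fun(corpus, graph, terms[[i]], terms[[j]])
      }
      m[i, j] <- m[j, i] <- s
    }
  }
  m
}
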