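# Shared fixtures and independent oracles.
# Oracles are deliberately written without reusing package internals: ancestor
# closures by iterative expansion, IC by direct counting, the Fisher tail by
# exhaustive choose() sums.

# -- tiny OBO builders --------------------------------------------------------

obo_header <- c("format-version: 1.2")

obo_stanza <- function(id, namespace = "biological_process", parents = NULL,
                       name = id, extra = NULL) {
  c("", "[Term]", paste0("id: ", id), paste0("name: ", name),
    paste0("namespace: ", namespace),
    if (length(parents)) paste0("is_a: ", parents), extra)
}

write_obo <- function(stanzas) {
  path <- tempfile(fileext = ".obo")
  writeLines(c(obo_header, stanzas), path)
  path
}

# chain r <- a <- b in BP
chain_obo <- function() {
  write_obo(c(obo_stanza("GO:0000001"),
              obo_stanza("GO:0000002", parents = "GO:0000001"),
              obo_stanza("GO:0000003", parents = "GO:0000002")))
}

# diamond: d is_a b, d is_a c; b, c is_a a
diamond_obo <- function() {
  write_obo(c(obo_stanza("GO:0000001"),
              obo_stanza("GO:0000002", parents = "GO:0000001"),
              obo_stanza("GO:0000003", parents = "GO:0000001"),
              obo_stanza("GO:0000004", parents = c("GO:0000002", "GO:0000003"))))
}

# -- independent oracles ------------------------------------------------------

# ancestor closure by iterative frontier expansion over a parents list
oracle_ancestors <- function(parents, term) {
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)),
                        seen)
  }
  seen
}

# propagated gene->term sets, term counts and IC computed from scratch
oracle_corpus <- function(parents, direct) {
  prop <- lapply(direct, function(tt)
    unique(unlist(lapply(tt, oracle_ancestors, parents = parents))))
  prop <- prop[lengths(prop) > 0L]
  counts <- table(unlist(prop, use.names = FALSE))
  n <- length(prop)
  list(propagated = prop,
       counts = stats::setNames(as.integer(counts), names(counts)),
       ic = stats::setNames(-log(as.integer(counts) / n), names(counts)),
       n = n)
}

# Lin similarity by brute-force maximization over enumerated common ancestors
oracle_lin <- function(parents, oc, t1, t2) {
  denom <- oc$ic[[t1]] + oc$ic[[t2]]
  if (denom == 0) return(0)
  common <- intersect(oracle_ancestors(parents, t1),
                      oracle_ancestors(parents, t2))
  ics <- oc$ic[common]
  ics <- ics[!is.na(ics)]
  2 * max(0, ics) / denom
}

# exhaustive hypergeometric upper tail via choose()
oracle_fisher <- function(k, K, n, N) {
  js <- seq(k, min(K, n))
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# random DAG as a parents list (term "t1" is the root), plus a random corpus
random_dag_corpus <- function(n_terms, n_genes = 30L) {
  ids <- paste0("t", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  for (i in seq_len(n_terms)[-1L]) {
    n_par <- min(i - 1L, sample(1:2, 1L))
    parents[[i]] <- ids[sample(i - 1L, n_par)]
  }
  direct <- lapply(seq_len(n_genes), function(g)
    ids[sample(n_terms, sample(1:3, 1L))])
  names(direct) <- paste0("g", seq_len(n_genes))
  list(ids = ids, parents = parents, direct = direct)
}

# write a parents-list DAG as an OBO file (single namespace)
dag_to_obo <- function(ids, parents) {
  stanzas <- unlist(lapply(ids, function(id)
    obo_stanza(id, parents = parents[[id]])), use.names = FALSE)
  write_obo(stanzas)
}

# -- tiny genome / QTL fixtures ----------------------------------------------

# genome of n genes tiled on one or more chromosomes, 1 kb genes, 1 kb gaps
toy_genome <- function(n_genes, n_chrom = 1L) {
  per <- ceiling(n_genes / n_chrom)
  chrom <- rep(paste0("chr", seq_len(n_chrom)), each = per)[seq_len(n_genes)]
  idx <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  start <- (idx - 1L) * 2000L
  g <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)), chrom = chrom,
                  start = start, end = start + 1000L, strand = "+",
                  stringsAsFactors = FALSE)
  structure(g, chrom_lengths = tapply(g$end + 1000L, g$chrom, max),
            class = c("gene_loci", "data.frame"))
}

toy_regions <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df$region_id <- sprintf("%s_r%d", df$trait_id,
                          stats::ave(seq_len(nrow(df)), df$trait_id,
                                     FUN = seq_along))
  df[, c("region_id", "trait_id", "trait_type", "chrom", "start", "end")]
}

# small planted world reused by several tests (cheap to generate)
small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_terms = 80L, n_genes = 200L, n_chromosomes = 2L,
         n_traits = c(macroscopic = 3L, metabolite = 3L, expression = 3L),
         n_planted_traits = 4L, group_size = 2L,
         signal_terms_per_group = 2L, carriers_per_term = 4L,
         generality_max_fraction = 0.05),
    list(...))
  do.call(synthetic_spec, args)
}
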