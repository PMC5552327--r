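test_that("parse_obo reads stanzas, edges, roots and obsolete flags", {
  g <- parse_obo(chain_obo())
  expect_s3_class(g, "OntologyGraph")
  expect_equal(nrow(g$terms), 3L)
  expect_equal(unname(g$roots["BP"]), "GO:0000001")
  expect_equal(g$parents[["GO:0000003"]], "GO:0000002")

  obs <- write_obo(c(obo_stanza("GO:0000001"),
                     obo_stanza("GO:0000002", parents = "GO:0000001",
                                extra = "is_obsolete: true")))
  g2 <- parse_obo(obs)
  expect_true(g2$terms["GO:0000002", "obsolete"])
  expect_error(ancestors(g2, "GO:0000002"), "obsolete")
})

test_that("parse_obo enforces namespace and acyclicity invariants", {
  cross <- write_obo(c(obo_stanza("GO:0000001"),
                       obo_stanza("GO:0000002", namespace = "molecular_function"),
                       obo_stanza("GO:0000003", parents = "GO:0000002")))
  expect_error(parse_obo(cross), "namespace")

  cyc <- write_obo(c(obo_stanza("GO:0000001"),
                     obo_stanza("GO:0000002", parents = "GO:0000003"),
                     obo_stanza("GO:0000003", parents = "GO:0000002")))
  expect_error(parse_obo(cyc), "cycle|root")

  no_ns <- tempfile(fileext = ".obo")
  writeLines(c(obo_header, "", "[Term]", "id: GO:0000001", "name: x"), no_ns)
  expect_error(parse_obo(no_ns), "namespace")

  # part_of treated as is_a by default, configurable off
  po <- write_obo(c(obo_stanza("GO:0000001"),
                    obo_stanza("GO:0000002", parents = "GO:0000001"),
                    obo_stanza("GO:0000003", parents = "GO:0000001",
                               extra = "relationship: part_of GO:0000002")))
  expect_setequal(ancestors(parse_obo(po), "GO:0000003"),
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_setequal(ancestors(parse_obo(po, part_of_as_parent = FALSE),
                            "GO:0000003"),
                  c("GO:0000001", "GO:0000003"))
})

test_that("ancestors includes self and closes the diamond", {
  g <- parse_obo(chain_obo())
  expect_equal(ancestors(g, "GO:0000001"), "GO:0000001")
  expect_setequal(ancestors(g, "GO:0000003"),
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  gd <- parse_obo(diamond_obo())
  expect_setequal(ancestors(gd, "GO:0000004"),
                  c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"))
  expect_error(ancestors(g, "GO:9999999"), "unknown")
})

test_that("propagate_annotations closes sets, counts genes and computes IC", {
  g <- parse_obo(chain_obo())
  # 8 genes: 4 reach GO:0000002 (A), 2 of those reach the leaf
  direct <- c(lapply(1:2, function(i) "GO:0000003"),
              lapply(3:4, function(i) "GO:0000002"),
              lapply(5:8, function(i) "GO:0000001"))
  names(direct) <- paste0("g", 1:8)
  corpus <- propagate_annotations(g, direct)
  expect_setequal(corpus$propagated$g1,
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(corpus$n_annotated_genes, 8L)
  expect_equal(unname(corpus$term_gene_count["GO:0000002"]), 4L)
  expect_equal(unname(corpus$ic["GO:0000001"]), 0)        # on all genes
  expect_equal(unname(corpus$ic["GO:0000002"]), log(2))   # -ln(4/8)
  expect_true(all(corpus$ic >= 0))
})

test_that("propagation drops obsolete annotations and empty genes", {
  obs <- write_obo(c(obo_stanza("GO:0000001"),
                     obo_stanza("GO:0000002", parents = "GO:0000001",
                                extra = "is_obsolete: true")))
  g <- parse_obo(obs)
  expect_warning(
    corpus <- propagate_annotations(g, list(g1 = "GO:0000001",
                                            g2 = "GO:0000002")),
    "obsolete")
  expect_equal(corpus$n_annotated_genes, 1L)
  expect_false("g2" %in% names(corpus$propagated))
})

test_that("lin_similarity matches the closed-form chain value", {
  g <- parse_obo(chain_obo())
  direct <- c(lapply(1:2, function(i) "GO:0000003"),
              lapply(3:4, function(i) "GO:0000002"),
              lapply(5:8, function(i) "GO:0000001"))
  names(direct) <- paste0("g", 1:8)
  corpus <- propagate_annotations(g, direct)
  # root 8 genes, A 4 genes, B 2 genes: 2 ln2 / (ln2 + ln4) = 2/3
  expect_equal(lin_similarity(corpus, g, "GO:0000002", "GO:0000003"), 2 / 3)
  expect_equal(lin_similarity(corpus, g, "GO:0000002", "GO:0000002"), 1)
  expect_equal(lin_similarity(corpus, g, "GO:0000001", "GO:0000003"), 0)
  expect_equal(lin_similarity(corpus, g, "GO:0000001", "GO:0000001"), 0)
})

test_that("lin_similarity rejects cross-namespace and zero-count terms", {
  two_ns <- write_obo(c(obo_stanza("GO:0000001"),
                        obo_stanza("GO:0000002", parents = "GO:0000001"),
                        obo_stanza("GO:0000010",
                                   namespace = "molecular_function"),
                        obo_stanza("GO:0000011", parents = "GO:0000010",
                                   namespace = "molecular_function")))
  g <- parse_obo(two_ns)
  corp_bp <- propagate_annotations(g, list(g1 = "GO:0000002"))
  expect_error(lin_similarity(corp_bp, g, "GO:0000002", "GO:0000011"),
               "no annotated genes|namespace")
  expect_error(lin_similarity(corp_bp, g, "GO:0000002", "GO:0000011"))
})

test_that("propagation is idempotent and counts are monotone along edges", {
  set.seed(11)
  for (rep in 1:10) {
    rc <- random_dag_corpus(n_terms = 25L, n_genes = 20L)
    obo <- dag_to_obo(rc$ids, rc$parents)
    g <- parse_obo(obo)
    corpus <- propagate_annotations(g, rc$direct)
    # idempotence at the gene->term set level
    corpus2 <- propagate_annotations(g, corpus$propagated)
    expect_identical(lapply(corpus$propagated, sort),
                     lapply(corpus2$propagated, sort))
    # parent count >= child count on every edge
    for (id in rc$ids) {
      for (p in rc$parents[[id]]) {
        cc <- corpus$term_gene_count[id]
        pc <- corpus$term_gene_count[p]
        if (!is.na(cc)) expect_gte(unname(pc), unname(cc))
      }
    }
  }
})

test_that("termsim_matrix is symmetric with unit diagonal and [0,1] entries", {
  set.seed(21)
  rc <- random_dag_corpus(n_terms = 30L, n_genes = 25L)
  g <- parse_obo(dag_to_obo(rc$ids, rc$parents))
  corpus <- propagate_annotations(g, rc$direct)
  terms <- names(corpus$term_gene_count)
  m <- termsim_matrix(corpus, g, terms)
  expect_identical(m, t(m))
  expect_true(all(m >= 0 & m <= 1 + 1e-12))
  pos_ic <- terms[corpus$ic[terms] > 0]
  expect_true(all(abs(diag(m)[pos_ic] - 1) < 1e-12))
})

test_that("lin_similarity agrees with the brute-force oracle on random DAGs", {
  set.seed(31)
  for (rep in 1:25) {
    rc <- random_dag_corpus(n_terms = sample(5:40, 1L))
    g <- parse_obo(dag_to_obo(rc$ids, rc$parents))
    corpus <- propagate_annotations(g, rc$direct)
    oc <- oracle_corpus(rc$parents, rc$direct)
    terms <- names(corpus$term_gene_count)
    pick <- matrix(sample(terms, 20L, replace = TRUE), ncol = 2L)
    for (i in seq_len(nrow(pick))) {
      expect_equal(lin_similarity(corpus, g, pick[i, 1], pick[i, 2]),
                   oracle_lin(rc$parents, oc, pick[i, 1], pick[i, 2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("read_annotations handles two-column TSV and GAF", {
  tsv <- tempfile()
  writeLines(c("gene_id\tterm_id", "g1\tGO:0000002", "g1\tGO:0000003",
               "g2\tGO:0000002"), tsv)
  ann <- read_annotations(tsv, format = "tsv")
  expect_setequal(ann$g1, c("GO:0000002", "GO:0000003"))
  expect_equal(ann$g2, "GO:0000002")

  gaf <- tempfile()
  row <- function(gene, term, aspect)
    paste(c("DB", gene, gene, "", term, "REF", "IEA", "", aspect,
            "", "", "gene", "taxon:4530", "20170101", "DB"), collapse = "\t")
  writeLines(c("!gaf-version: 2.1",
               row("g1", "GO:0000002", "P"),
               row("g1", "GO:0000010", "F"),
               row("g2", "GO:0000003", "P")), gaf)
  bp <- read_annotations(gaf, format = "gaf", namespace = "BP")
  expect_equal(bp$g1, "GO:0000002")
  mf <- read_annotations(gaf, format = "gaf", namespace = "MF")
  expect_equal(mf$g1, "GO:0000010")
  expect_null(mf$g2)
})
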