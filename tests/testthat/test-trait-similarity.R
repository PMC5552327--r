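# hand-built term similarity matrices make BMA values exactly computable
ts_matrix <- function(vals, ids) matrix(vals, length(ids), length(ids),
                                        dimnames = list(ids, ids))

test_that("best_match_average matches hand-evaluated directional means", {
  ids <- c("a", "b")
  s <- ts_matrix(c(1, 0.4, 0.4, 1), ids)
  expect_equal(best_match_average(c("a", "b"), c("a", "b"), s), 1)
  expect_equal(best_match_average("a", "b", s), 0.4)
  # X = {a,b}, Y = {a}: mean_X(best) = (1 + 0.4)/2, mean_Y(best) = 1
  expect_equal(best_match_average(c("a", "b"), "a", s),
               ((1 + 0.4) / 2 + 1) / 2)
  expect_equal(best_match_average(c("a", "b"), "a", s, symmetric = FALSE),
               (1 + 0.4) / 2)
  expect_error(best_match_average(character(0), "a", s), "empty")
})

test_that("BMA is symmetric and well-behaved on random sets", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(3:8, 1L)
    ids <- paste0("t", seq_len(n))
    m <- matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids))
    m <- (m + t(m)) / 2; diag(m) <- 1
    x <- sample(ids, sample(1:n, 1L))
    y <- sample(ids, sample(1:n, 1L))
    expect_equal(best_match_average(x, y, m), best_match_average(y, x, m),
                 tolerance = 1e-12)
    expect_equal(best_match_average(x, x, m), 1)
    v <- best_match_average(x, y, m)
    expect_true(v >= 0 && v <= 1 + 1e-12)
    # adding to Y a term identical to one in X cannot decrease the X->Y mean
    extra <- x[[1L]]
    expect_gte(best_match_average(x, unique(c(y, extra)), m,
                                  symmetric = FALSE),
               best_match_average(x, y, m, symmetric = FALSE) - 1e-12)
  }
})

three_trait_links <- function() {
  # chain ontology with graded IC gives known pairwise term similarities
  g <- parse_obo(chain_obo())
  direct <- c(lapply(1:2, function(i) "GO:0000003"),
              lapply(3:4, function(i) "GO:0000002"),
              lapply(5:8, function(i) "GO:0000001"))
  names(direct) <- paste0("g", 1:8)
  corpus <- propagate_annotations(g, direct)
  links <- data.frame(
    trait_id = c("tA", "tB", "tC", "tC"),
    trait_type = c("macroscopic", "metabolite", "expression", "expression"),
    namespace = "BP",
    term_id = c("GO:0000002", "GO:0000003", "GO:0000002", "GO:0000003"),
    stringsAsFactors = FALSE)
  list(g = g, corpus = corpus, links = links)
}

test_that("similarity_matrix reproduces a hand-computed 3-trait matrix", {
  w <- three_trait_links()
  m <- similarity_matrix(w$links, w$corpus, w$g)
  # term sims: s(2,2)=1, s(3,3)=1, s(2,3)=2/3
  s23 <- 2 / 3
  expect_equal(m$values["tA", "tB"], s23)
  # tA={2} vs tC={2,3}: X->Y mean = 1; Y->X mean = (1 + s23)/2
  expect_equal(m$values["tA", "tC"], (1 + (1 + s23) / 2) / 2)
  expect_equal(m$values["tB", "tC"], (1 + (1 + s23) / 2) / 2)
  expect_equal(diag(m$values), c(tA = 1, tB = 1, tC = 1))
  expect_identical(m$values, t(m$values))
  expect_equal(m$sim_max, max(m$values["tA", "tC"], s23))
  expect_true(m$set_identical["tA", "tA"])
  expect_false(m$set_identical["tA", "tC"])
  expect_error(similarity_matrix(w$links[1, ], w$corpus, w$g), "2 traits")
})

test_that("identical link sets give similarity exactly 1", {
  w <- three_trait_links()
  links <- rbind(w$links,
                 data.frame(trait_id = "tD", trait_type = "metabolite",
                            namespace = "BP",
                            term_id = c("GO:0000002", "GO:0000003")))
  m <- similarity_matrix(links, w$corpus, w$g)
  expect_identical(m$values["tC", "tD"], 1)
  expect_true(m$set_identical["tC", "tD"])
})

test_that("max_similarity_links picks per-category maxima with tie rule", {
  w <- three_trait_links()
  m <- similarity_matrix(w$links, w$corpus, w$g)
  ml <- max_similarity_links(m)
  # tA: one candidate per category (tB metabolite, tC expression)
  tA <- ml[ml$source == "tA", ]
  expect_setequal(tA$target_type, c("metabolite", "expression"))
  expect_equal(tA$target[tA$target_type == "metabolite"], "tB")
  # 2 macroscopic + 1 metabolite: each trait links to every present category
  # except an empty own-category pool
  expect_equal(nrow(ml[ml$source == "tC", ]), 2L)

  # tie-break: two equal targets -> lexicographically smaller id
  ids <- c("t1", "t2", "t3")
  vals <- ts_matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), ids)
  fake <- list(namespace = "BP", trait_ids = ids, values = vals,
               sim_max = .5,
               trait_types = stats::setNames(rep("macroscopic", 3), ids),
               term_sets = NULL, set_identical = NULL)
  class(fake) <- "trait_sim_matrix"
  ml2 <- max_similarity_links(fake)
  expect_equal(ml2$target[ml2$source == "t3"], "t1")
})

test_that("f_bp covers the pure and mixed cases", {
  expect_equal(f_bp(10L, 10L), 0.5)
  expect_equal(f_bp(7L, 0L), 1)
  expect_equal(f_bp(0L, 3L), 0)
  expect_true(is.na(f_bp(0L, 0L)))
  tab <- f_bp_table(
    data.frame(trait_id = c("x", "x", "y"), trait_type = "macroscopic",
               namespace = "BP", term_id = c("a", "b", "a")),
    data.frame(trait_id = "x", trait_type = "macroscopic",
               namespace = "MF", term_id = "c"))
  expect_equal(tab$f_bp[tab$trait_id == "x"], 2 / 3)
  expect_equal(tab$f_bp[tab$trait_id == "y"], 1)
})

test_that("ks_two_sample matches brute-force sup of ECDF differences", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11, 12))$D, 1)
  expect_equal(ks_two_sample(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))$D, 1 / 3)
  set.seed(9)
  a <- stats::runif(20); b <- stats::rbeta(30, 2, 1)
  grid <- sort(unique(c(a, b)))
  brute_D <- max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
  expect_equal(ks_two_sample(a, b)$D, brute_D, tolerance = 1e-12)
})
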