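make_gff3 <- function(df, chrom_len = NULL) {
  path <- tempfile(fileext = ".gff3")
  head <- "##gff-version 3"
  if (!is.null(chrom_len))
    head <- c(head, sprintf("##sequence-region %s 1 %d",
                            names(chrom_len), chrom_len))
  writeLines(c(head,
               sprintf("%s\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       df$chrom, df$start1, df$end1, df$gene_id)), path)
  path
}

test_that("load_genome converts GFF3 to 0-based half-open and keeps BED", {
  gff <- make_gff3(data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                              start1 = c(101L, 301L), end1 = c(200L, 400L)))
  g <- load_genome(gff, format = "GFF3")
  expect_equal(g$start, c(100L, 300L))
  expect_equal(g$end, c(200L, 400L))

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tgA\t0\t+", "chr1\t300\t400\tgB\t0\t-"), bed)
  b <- load_genome(bed, format = "BED")
  expect_equal(b$start, c(100L, 300L))
  expect_equal(b$end, c(200L, 400L))
  expect_equal(b$strand, c("+", "-"))

  dup <- make_gff3(data.frame(gene_id = c("gA", "gA"), chrom = "chr1",
                              start1 = c(101L, 301L), end1 = c(200L, 400L)))
  expect_error(load_genome(dup, format = "GFF3"), "duplicate")
})

test_that("GFF3 and BED ingestion round-trip coordinates exactly", {
  genes <- toy_genome(20L, n_chrom = 2L)
  gff <- make_gff3(data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                              start1 = genes$start + 1L, end1 = genes$end))
  bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+", genes$chrom, genes$start,
                     genes$end, genes$gene_id), bed)
  from_gff <- load_genome(gff, format = "GFF3")
  from_bed <- load_genome(bed, format = "BED")
  expect_equal(from_gff$start, from_bed$start)
  expect_equal(from_gff$end, from_bed$end)
})

test_that("genes_in_region applies the any-overlap half-open rule", {
  genes <- toy_genome(5L)  # genes at [0,1000), [2000,3000), ...
  expect_equal(genes_in_region(genes, list(chrom = "chr1", start = 2100,
                                           end = 2200)), "g002")
  # 1 bp overlap at the region start
  expect_true("g002" %in% genes_in_region(genes, list(chrom = "chr1",
                                                      start = 2999,
                                                      end = 3500)))
  # abutting half-open region: zero overlap
  expect_false("g002" %in% genes_in_region(genes, list(chrom = "chr1",
                                                       start = 3000,
                                                       end = 3500)))
  expect_warning(res <- genes_in_region(genes, list(chrom = "chrX",
                                                    start = 0, end = 100)),
                 "absent")
  expect_length(res, 0L)
})

test_that("trait gene sets equal a brute-force per-bp overlap scan", {
  set.seed(5)
  genes <- toy_genome(30L, n_chrom = 2L)
  starts <- sample(0:25000, 5L)
  regions <- toy_regions(
    trait_id = rep(c("t1", "t2"), c(3L, 2L)),
    trait_type = "macroscopic",
    chrom = sample(c("chr1", "chr2"), 5L, replace = TRUE),
    start = starts, end = starts + sample(2000:9000, 5L))
  ds <- build_qtl_dataset(regions, genes)
  brute <- function(region) {
    hit <- character(0)
    for (i in seq_len(nrow(genes))) {
      bps <- seq(genes$start[i], genes$end[i] - 1L)
      if (genes$chrom[i] == region$chrom &&
          any(bps >= region$start & bps < region$end))
        hit <- c(hit, genes$gene_id[i])
    }
    hit
  }
  for (r in seq_len(nrow(regions)))
    expect_setequal(ds$region_genes[[regions$region_id[r]]],
                    brute(regions[r, ]))
  tg <- trait_gene_sets(ds)
  expect_setequal(tg$t1,
                  unique(unlist(ds$region_genes[regions$region_id[1:3]])))
})

test_that("apply_filters enforces the gene cap and min-region rules", {
  genes <- toy_genome(500L)  # single chromosome, 2 kb pitch
  # region covering 451 genes vs exactly 450
  regions <- toy_regions(
    trait_id = c("big", "big", "ok", "ok", "expr", "expr"),
    trait_type = c("macroscopic", "macroscopic", "macroscopic",
                   "macroscopic", "expression", "expression"),
    chrom = "chr1",
    start = c(0L, 0L, 0L, 4000L, 0L, 4000L),
    end = c(451L * 2000L - 1000L, 3000L, 3000L, 7000L, 3000L, 7000L))
  ds <- build_qtl_dataset(regions, genes)
  expect_equal(length(ds$region_genes[["big_r1"]]), 451L)
  cfg <- pipeline_config()
  filt <- apply_filters(ds, cfg)
  log <- attr(filt, "exclusion_log")
  # big_r1 dropped (451 > 450), trait "big" left with 1 region -> dropped;
  # "expr" has 2 regions < 3 -> dropped; "ok" kept
  expect_true("big_r1" %in% log$id[log$kind == "region"])
  expect_setequal(log$trait_id[log$kind == "trait"], c("big", "expr"))
  expect_equal(filt$traits$trait_id, "ok")

  # a region with exactly 450 genes is kept
  regions450 <- toy_regions(
    trait_id = c("t", "t"), trait_type = "macroscopic", chrom = "chr1",
    start = c(0L, 0L), end = c(450L * 2000L - 1000L, 3000L))
  ds450 <- build_qtl_dataset(regions450, genes)
  expect_equal(length(ds450$region_genes[["t_r1"]]), 450L)
  filt450 <- apply_filters(ds450, cfg)
  expect_equal(nrow(filt450$regions), 2L)

  # idempotence
  again <- apply_filters(filt, cfg)
  expect_equal(again$regions, filt$regions)
  expect_equal(nrow(attr(again, "exclusion_log")), 0L)
})

test_that("dataset_summary reports mean (sd) with deduplicated gene counts", {
  genes <- toy_genome(20L)
  # two overlapping regions: 3 genes and 5 genes sharing exactly 1 gene
  regions <- toy_regions(trait_id = c("t1", "t1"),
                         trait_type = "macroscopic", chrom = "chr1",
                         start = c(0L, 4100L), end = c(4500L, 13000L))
  ds <- build_qtl_dataset(regions, genes)
  expect_equal(lengths(ds$region_genes), c(t1_r1 = 3L, t1_r2 = 5L))
  expect_length(intersect(ds$region_genes[[1]], ds$region_genes[[2]]), 1L)
  s <- dataset_summary(ds)
  mac <- s[s$trait_type == "macroscopic", ]
  expect_equal(mac$n_traits, 1L)
  expect_equal(mac$mean_genes_per_trait, 7)   # union, dedup
  expect_equal(mac$genes_per_region, "4.0 (1.4)")
  expect_equal(s$n_traits[s$trait_type == "expression"], 0L)
})

test_that("read_qtl_table validates and converts coordinates", {
  path <- tempfile()
  writeLines(c("trait_id\ttrait_type\tchrom\tstart\tend",
               "t1\tmacroscopic\tchr1\t101\t200",
               "t1\tmacroscopic\tchr1\t301\t400"), path)
  bed <- read_qtl_table(path)
  expect_equal(bed$start[1], 101L)
  one <- read_qtl_table(path, coordinate_convention = "one_based")
  expect_equal(one$start[1], 100L)
  expect_equal(one$end[1], 200L)
  expect_equal(one$region_id, c("t1_r1", "t1_r2"))

  bad <- tempfile()
  writeLines(c("trait_id\ttrait_type\tchrom\tstart\tend",
               "t1\tweird\tchr1\t1\t2"), bad)
  expect_error(read_qtl_table(bad), "trait_type")
})
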