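#' Read a pipeline configuration file
#'
#' YAML with an `inputs` block (paths to `ontology`, `genome`,
#' `annotations_bp`, `annotations_mf`, `qtl_table`), an optional `params`
#' block overriding [pipeline_config()] defaults, and `output_dir`. Relative
#' input paths are resolved against the config file's directory.
#'
#' @param path YAML config file.
#' @return list with `inputs`, `config` (a `pipeline_config`), `output_dir`,
#'   `genome_format`, `annotation_format`, `coordinate_convention`,
#'   `namespaces`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^/", p)) p else file.path(base, p)
  }
  inputs <- lapply(y$inputs, resolve)
  params <- y$params %||% list()
  if (!is.null(params$min_regions))
    params$min_regions <- unlist(params$min_regions)
  config <- do.call(pipeline_config, params)
  list(inputs = inputs, config = config,
       output_dir = resolve(y$output_dir) %||% file.path(base, "output"),
       genome_format = toupper(y$genome_format %||% "GFF3"),
       annotation_format = tolower(y$annotation_format %||% "tsv"),
       coordinate_convention = y$coordinate_convention %||% "bed",
       namespaces = y$namespaces %||% c("BP", "MF"))
}

#' Run the full pipeline
#'
#' Stages: genome/QTL ingestion and filtering; per-namespace enrichment
#' (trait-term links); trait-trait similarity; both permutation tests;
#' clustering, network and table export. Writes a manifest
#' (`manifest.json`) with the config snapshot, input checksums, seed and
#' per-stage output paths.
#'
#' @param config_path path to a YAML config file, or a list as returned by
#'   [read_pipeline_config()].
#' @param n_permutations override the configured replicate count (useful for
#'   smoke runs).
#' @return invisibly, a list of in-memory results (`links`, `matrices`,
#'   `region_perm`, `maxsim`, `summary`, `output_dir`).
#' @export
run_pipeline <- function(config_path, n_permutations = NULL) {
  cfg <- if (is.character(config_path)) read_pipeline_config(config_path)
         else config_path
  config <- cfg$config
  if (!is.null(n_permutations))
    config$n_permutations <- as.integer(n_permutations)
  outdir <- cfg$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("ontology", "genome", "annotations_bp", "annotations_mf",
              "qtl_table")) {
    nsv_needed <- toupper(sub("annotations_", "", f))
    if (f %in% c("annotations_bp", "annotations_mf") &&
        !nsv_needed %in% cfg$namespaces) next
    if (is.null(cfg$inputs[[f]]) || !file.exists(cfg$inputs[[f]]))
      stop("missing input file for '", f, "'")
  }

  log_msg("loading ontology and annotations")
  graph <- parse_obo(cfg$inputs$ontology)
  genes <- load_genome(cfg$inputs$genome, format = cfg$genome_format)
  corpora <- list()
  for (nsv in cfg$namespaces) {
    ann <- read_annotations(cfg$inputs[[paste0("annotations_",
                                               tolower(nsv))]],
                            format = cfg$annotation_format, namespace = nsv)
    corpora[[nsv]] <- propagate_annotations(graph, ann,
                                            n_genes_total = nrow(genes))
  }

  log_msg("building QTL dataset")
  regions <- read_qtl_table(cfg$inputs$qtl_table,
                            coordinate_convention = cfg$coordinate_convention)
  dataset <- build_qtl_dataset(regions, genes)
  filtered <- apply_filters(dataset, config)
  excl <- attr(filtered, "exclusion_log")
  utils::write.table(excl, file.path(outdir, "exclusion_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset_summary(filtered),
                     file.path(outdir, "dataset_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  links <- list(); matrices <- list(); maxsim <- list()
  for (nsv in cfg$namespaces) {
    log_msg("enrichment: ", nsv)
    links[[nsv]] <- link_traits_to_terms(filtered, corpora[[nsv]], graph,
                                         config)
    utils::write.table(links[[nsv]],
                       file.path(outdir, sprintf("links_%s.tsv", nsv)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n_linked <- length(unique(links[[nsv]]$trait_id))
    if (n_linked < 2L) {
      log_msg("fewer than 2 linked traits in ", nsv,
              "; skipping similarity stage", level = "WARN")
      next
    }
    m <- similarity_matrix(links[[nsv]], corpora[[nsv]], graph,
                           symmetric = config$symmetric_bma)
    matrices[[nsv]] <- m
    long <- data.frame(
      trait_a = rep(m$trait_ids, times = length(m$trait_ids)),
      trait_b = rep(m$trait_ids, each = length(m$trait_ids)),
      namespace = nsv, similarity = as.vector(m$values),
      set_identical = as.vector(m$set_identical))
    long <- long[long$trait_a < long$trait_b, ]
    utils::write.table(long,
                       file.path(outdir, sprintf("similarity_%s.tsv", nsv)),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    log_msg("max-similarity link significance: ", nsv)
    ms <- maxsim_link_significance(links[[nsv]], corpora[[nsv]], graph,
                                   config)
    maxsim[[nsv]] <- ms
    utils::write.table(ms,
                       file.path(outdir, sprintf("maxsim_links_%s.tsv", nsv)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- ms[ms$significant, , drop = FALSE]
    net <- export_network(sig, m$trait_types,
                          prefix = file.path(outdir,
                                             sprintf("network_%s", nsv)))
    utils::write.table(net$category_counts,
                       file.path(outdir,
                                 sprintf("link_counts_%s.tsv", nsv)),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    log_msg("clustering: ", nsv)
    d <- similarity_to_distance(m)
    dn <- complete_linkage(d)
    writeLines(to_newick(dn),
               file.path(outdir, sprintf("dendrogram_%s.newick", nsv)))
  }

  if (all(c("BP", "MF") %in% names(links))) {
    fb <- f_bp_table(links$BP, links$MF)
    utils::write.table(fb, file.path(outdir, "f_bp.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  log_msg("region-randomization permutation test (",
          config$n_permutations, " reps)")
  perm <- region_permutation_test(dataset, genes, corpora, graph, config)
  utils::write.table(perm, file.path(outdir, "region_permutation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("qtlgosem")),
    config = unclass(config),
    inputs = cfg$inputs,
    input_md5 = as.list(tools::md5sum(unlist(cfg$inputs))),
    master_seed = config$rng_seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(c(list.files(outdir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(links = links, matrices = matrices, region_perm = perm,
                 maxsim = maxsim, output_dir = outdir,
                 exclusion_log = excl))
}
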