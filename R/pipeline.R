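# End-to-end orchestration: (simulate | load) -> funnel -> inheritance ->
# network -> enrichment, with a provenance manifest.

default_config <- function() {
  list(
    inputs = list(fixture = "table1"),
    cascade = list(),
    network = list(threshold = 0.150, top_k = 6L),
    enrichment = list(alpha = 0.05),
    seed = 1L
  )
}

merge_config <- function(user) {
  cfg <- default_config()
  for (nm in names(user)) {
    if (nm %in% c("inputs", "simulate")) {
      # input sources replace the default wholesale: a user-supplied input
      # block must not inherit the packaged fixture
      cfg[[nm]] <- user[[nm]]
    } else if (is.list(user[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  if (!is.null(cfg$simulate)) cfg$inputs <- NULL
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!is.null(cfg$simulate)) return(invisible(cfg))
  inp <- cfg$inputs
  if (!is.null(inp$fixture)) {
    if (!identical(inp$fixture, "table1")) {
      stop_config("unknown packaged fixture; only 'table1' is available")
    }
    return(invisible(cfg))
  }
  if (!is.null(inp$dir)) {
    if (!dir.exists(inp$dir)) stop_config(paste0("cohort directory not found: ", inp$dir))
    return(invisible(cfg))
  }
  if (is.null(inp$vcf) || is.null(inp$sidecar) || is.null(inp$ped)) {
    stop_config("inputs must provide a packaged fixture, a cohort directory, or vcf + sidecar + ped paths")
  }
  paths <- c(unlist(inp$vcf), unlist(inp$sidecar), inp$ped)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop_config(paste0("input file(s) not found: ", paste(missing, collapse = ", ")))
  }
  invisible(cfg)
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    if (!is.null(sim_args$planted)) sim_args$planted <- unlist(sim_args$planted)
    cohort <- simulate_cohort(do.call(sim_config, sim_args))
    return(list(variants = cohort$variants, calls = cohort$calls,
                members = cohort$members, truth = cohort$truth))
  }
  inp <- cfg$inputs
  if (!is.null(inp$fixture)) return(load_table1_fixture())
  if (!is.null(inp$dir)) return(read_cohort_dir(inp$dir))
  members <- read_ped(inp$ped)
  parts <- purrr::map2(unlist(inp$vcf), unlist(inp$sidecar),
                       ~ read_family_vcf(.x, .y, members))
  list(variants = bind_rows(lapply(parts, `[[`, "variants")),
       calls = bind_rows(lapply(parts, `[[`, "calls")),
       members = members)
}

#' Run the full prioritisation pipeline
#'
#' Orchestrates one reproducible run: load the input cohort (a packaged
#' fixture, a cohort directory, explicit VCF/sidecar/PED paths, or an
#' on-the-fly simulation), run the filtering funnel, classify inheritance
#' of the survivors, build the thresholded interaction network over the
#' surviving genes with MCC hub ranking, and test the gene list for
#' over-representation. All tables are written as TSV beside a JSON
#' manifest capturing the configuration snapshot, input digests, seed,
#' package version and per-stage row counts. Configuration errors are
#' raised before any output is written.
#'
#' @param config A configuration list or the path to a YAML file. Sections:
#'   `inputs` (one of `fixture: table1`, `dir:`, or `vcf:`/`sidecar:`/
#'   `ped:` lists) or `simulate` (fields of [sim_config()]); `cascade`
#'   (fields of [cascade_config()]); `network` (`edges` path -- defaults to
#'   the packaged synthetic edge list -- `threshold`, `top_k`);
#'   `enrichment` (`gmt` path -- defaults to the packaged demo collection
#'   -- `alpha`); `seed`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the computed objects (`funnel`,
#'   `inheritance`, `graph`, `hubs`, `enrichment`) and the `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- merge_config(cfg)
  validate_pipeline_config(cfg)

  set.seed(cfg$seed)
  data <- load_pipeline_inputs(cfg)

  cascade_cfg <- do.call(cascade_config, cfg$cascade)
  funnel <- run_cascade(data$variants, cascade_cfg)
  survivors <- surviving_variants(data$variants, funnel)

  surv_keys <- paste(survivors$family_id, survivors$variant_key)
  calls <- data$calls[paste(data$calls$family_id, data$calls$variant_key) %in%
                        surv_keys, ]
  inheritance <- classify_cohort(survivors, calls, data$members)

  genes <- sort(unique(survivors$gene))
  edge_path <- cfg$network$edges %||% synthetic_edge_file()
  edges <- read_edge_list(edge_path)
  graph <- suppressWarnings(
    build_ppi_graph(genes, edges, threshold = cfg$network$threshold))
  hubs <- mcc_scores(graph)

  gmt_path <- cfg$enrichment$gmt %||% demo_gmt_file()
  collection <- read_gmt(gmt_path)
  # background: the gene-set universe extended by the query itself, so
  # cohort-specific genes missing from the collection stay testable
  collection <- gene_set_collection(collection$sets, collection$names,
                                    universe = union(collection$universe, genes))
  enrichment <- run_enrichment(genes, collection, alpha = cfg$enrichment$alpha)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(funnel$decisions, file.path(out_dir, "funnel.tsv"), progress = FALSE)
  readr::write_tsv(inheritance$calls, file.path(out_dir, "inheritance.tsv"), progress = FALSE)
  readr::write_tsv(inheritance$compound_hets,
                   file.path(out_dir, "compound_hets.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(hubs), file.path(out_dir, "hubs.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(enrichment), file.path(out_dir, "enrichment.tsv"),
                   progress = FALSE)

  input_files <- c(
    if (!is.null(cfg$inputs$vcf)) unlist(cfg$inputs$vcf),
    if (!is.null(cfg$inputs$sidecar)) unlist(cfg$inputs$sidecar),
    cfg$inputs$ped, edge_path, gmt_path)
  manifest <- list(
    tool = "triofunnel",
    version = as.character(utils::packageVersion("triofunnel")),
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    input_digests = as.list(tools::md5sum(input_files[file.exists(input_files)])),
    stage_counts = list(
      input_variants = nrow(data$variants),
      funnel_survivors = sum(funnel$decisions$final),
      inheritance_calls = nrow(inheritance$calls),
      compound_het_pairs = nrow(inheritance$compound_hets),
      network_nodes = length(graph$nodes),
      network_edges = nrow(graph$edges),
      enrichment_rows = nrow(enrichment)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(funnel = funnel, inheritance = inheritance, graph = graph,
                 hubs = hubs, enrichment = enrichment, manifest = manifest))
}
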