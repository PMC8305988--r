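#' Run the full genomic-fabric analysis of a configured study
#'
#' Orchestrates all stages over a set of spot tables: ingestion
#' (parse, filter, normalize, assemble), per-region fabric fitting,
#' regulation scoring of every region against the reference, pathway
#' summaries, a coordination census on a configured panel, the gene
#' hierarchy and Gene Master Regulator of every region, and an
#' overexpression forecast for each non-reference region's GMR. All stage
#' outputs are written under `out_dir` together with a JSON run manifest.
#'
#' @param config Either a named list or a path to a YAML file with fields:
#'   `regions` (named list label -> spot TSV path), `reference` (label),
#'   optional `gene_sets` (GMT path), `alpha` (default 0.05),
#'   `indep_band` (0.05), `p_cut` (0.05), `top_k` (25), `median_units`
#'   (TRUE), `census_panel` (gene vector or a panel size, default 25),
#'   `seed` (1), `out_dir` (required to write outputs; `NULL` keeps
#'   everything in memory).
#' @return A `gfp_run` object: list with `fabrics`, `regulation`,
#'   `pathways`, `census`, `hierarchies`, `forecasts`, `manifest`.
#' @export
run_gfp <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(alpha = 0.05, indep_band = 0.05, p_cut = 0.05, top_k = 25L,
         median_units = TRUE, census_panel = 25L, seed = 1L,
         gene_sets = NULL, out_dir = NULL),
    config)
  if (is.null(cfg$regions) || is.null(names(cfg$regions)))
    stop("configuration error: 'regions' must be a named label -> path map")
  if (is.null(cfg$reference) || !cfg$reference %in% names(cfg$regions))
    stop("configuration error: reference label '", cfg$reference,
         "' not among regions")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("configuration error: alpha must be in (0, 1)")
  set.seed(cfg$seed)

  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  labels <- names(cfg$regions)
  fabrics <- lapply(labels, function(lb) stage(paste0("region_io:", lb), {
    fb <- fabric(read_region_set(cfg$regions[[lb]], lb,
                                 median_units = cfg$median_units))
    if (!is.null(out)) write_gene_stats(fb, file.path(
      out, paste0("gene_stats_", lb, ".tsv")))
    fb
  }))
  names(fabrics) <- labels

  ref <- cfg$reference
  contrasts <- setdiff(labels, ref)
  regulation <- lapply(contrasts, function(lb) stage(
    paste0("regulation:", lb), {
      r <- regulate(fabrics[[ref]], fabrics[[lb]], p_cut = cfg$p_cut)
      if (!is.null(out)) utils::write.table(
        r, file.path(out, paste0("regulation_", ref, "_to_", lb, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      r
    }))
  names(regulation) <- contrasts

  gene_sets <- if (!is.null(cfg$gene_sets)) read_gmt(cfg$gene_sets)
  pathways <- if (!is.null(gene_sets)) {
    lapply(regulation, function(r) stage("pathways", {
      s <- summarize_pathways(r, gene_sets)
      if (!is.null(out)) utils::write.table(
        s, file.path(out, paste0("pathways_", attr(r, "contrast"),
                                 ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      s
    }))
  }

  panel <- cfg$census_panel
  if (is.numeric(panel) && length(panel) == 1L) {
    shared <- Reduce(intersect, lapply(fabrics, function(f) f$stats$gene))
    panel <- utils::head(sort(shared), panel)
  }
  census <- lapply(fabrics, function(fb) stage("coordination", {
    cs <- coordination_census(fb, panel, cfg$alpha, cfg$indep_band)
    if (!is.null(out)) write_edge_list(cs$pairs, file.path(
      out, paste0("census_", fb$region, ".tsv")))
    cs
  }))

  hierarchies <- lapply(fabrics, function(fb) stage("hierarchy", {
    h <- build_hierarchy(fb, top_k = cfg$top_k)
    if (!is.null(out)) utils::write.table(
      h$table, file.path(out, paste0("hierarchy_", fb$region, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    h
  }))

  forecasts <- lapply(contrasts, function(lb) stage("forecast", {
    fc <- forecast_overexpression(fabrics[[lb]], hierarchies[[lb]]$gmr,
                                  regulation[[lb]],
                                  alpha = cfg$alpha,
                                  indep_band = cfg$indep_band)
    if (!is.null(out)) jsonlite::write_json(
      list(target = fc$target, region = fc$region, totals = fc$totals,
           table = fc$table),
      file.path(out, paste0("forecast_", lb, ".json")),
      auto_unbox = TRUE, digits = NA)
    fc
  }))
  names(forecasts) <- contrasts

  manifest <- list(
    package = "gfabric",
    version = as.character(utils::packageVersion("gfabric")),
    r_version = as.character(getRversion()),
    config = cfg[setdiff(names(cfg), "out_dir")],
    config_hash = config_hash(cfg),
    regions = labels, reference = ref,
    gmr = vapply(hierarchies, function(h) h$gmr, ""),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(out))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

  structure(list(fabrics = fabrics, regulation = regulation,
                 pathways = pathways, census = census,
                 hierarchies = hierarchies, forecasts = forecasts,
                 manifest = manifest),
            class = "gfp_run")
}

config_hash <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(keep[order(names(keep))], tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' @export
print.gfp_run <- function(x, ...) {
  cat("Genomic fabric run: ", length(x$fabrics), " regions (reference '",
      x$manifest$reference, "')\n", sep = "")
  for (lb in names(x$hierarchies))
    cat("  ", lb, ": GMR = ", x$hierarchies[[lb]]$gmr, " (GCH = ",
        signif(x$hierarchies[[lb]]$table$GCH[1L], 4), ")\n", sep = "")
  invisible(x)
}
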