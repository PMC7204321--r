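#' Run the full network-pharmacology workflow
#'
#' Executes the stages in order: compound screen, target assembly, disease
#' intersection, PPI centrality screening, enrichment. Stages whose inputs
#' are unavailable are skipped with a logged notice, never fabricated: the
#' packaged paper tables carry no PPI edges or annotations, so a
#' `fixtures = "paper"` run stops after the intersection unless the config
#' supplies those inputs.
#'
#' The configuration is an R list (or path to a JSON file with the same
#' shape) with elements:
#'
#' * `fixtures = "paper"` to use the packaged study tables, or
#'   `synthetic = TRUE` (all inputs generated from `seed` via the
#'   `sim_config` defaults, overridable through `sim`), or explicit
#'   `compounds` / `targets` / `disease` / `ppi` / `gmt` entries, each a
#'   file path or an already-loaded object;
#' * `seed` - integer, used for synthetic generation (default 1);
#' * `criteria` - named list overriding [screening_criteria()] defaults;
#' * `score_min` - disease inference-score cutoff (default 0: keep all);
#' * `ppi_score_min` - edge confidence cutoff (default 0.7);
#' * `ppi_scale` - `"unit"` or `"string1000"` for a `ppi` file path;
#' * `rounds` - list of named lists with `dc_min`, `cc_min`, `bc_min`; when
#'   absent, synthetic runs use [planted_core_rounds()] and other runs the
#'   two published cutoffs (20/0.685/0.011 then 26/0.771/0.029);
#' * `background` - optional gene vector or file for the enrichment stage.
#'
#' Every intermediate is written as TSV/SIF/plain text under `out_dir`, plus
#' a structured `report.json`. Rerunning with the same config gives
#' byte-identical outputs.
#'
#' @param config list or path to a JSON config file
#' @param out_dir output directory, created if needed
#' @param quiet suppress progress messages? default FALSE
#' @return the report, invisibly (also written to `report.json`)
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[netpharm] ", sprintf(...))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  synthetic <- isTRUE(config$synthetic)
  paper <- identical(config$fixtures, "paper")
  sim <- NULL
  if (synthetic) {
    sim_args <- c(list(seed = seed), config$sim)
    sim <- do.call(sim_config, sim_args[!duplicated(names(sim_args))])
  }

  load_df <- function(x, reader) if (is.character(x)) reader(x) else x

  # ---- inputs ----
  compounds <- if (paper) dchd_compounds()
    else if (synthetic) gen_compound_table(sim)$compounds
    else if (!is.null(config$compounds)) load_df(config$compounds, read_compound_table)
    else stop("configuration error in stage 'screen': no compound table")

  targets_df <- NULL; drug_genes <- NULL; disease <- NULL
  if (paper) {
    targets_df <- dchd_targets()
    drug_genes <- targets_df$gene_symbol
    disease <- t2dm_targets()
  } else if (synthetic) {
    ts <- gen_target_sets(sim)
    drug_genes <- ts$drug
    disease <- ts$disease
  } else {
    if (is.null(config$targets))
      stop("configuration error in stage 'assemble': no target table")
    targets_df <- load_df(config$targets, read_target_table)
    drug_genes <- targets_df$gene_symbol
    if (is.null(config$disease))
      stop("configuration error in stage 'intersect': no disease table")
    disease <- load_df(config$disease, read_disease_table)
  }

  crit <- do.call(screening_criteria,
                  if (is.null(config$criteria)) list() else config$criteria)
  score_min <- if (is.null(config$score_min)) 0 else config$score_min
  ppi_score_min <- if (is.null(config$ppi_score_min)) 0.7 else config$ppi_score_min

  # ---- stage 1: screen ----
  scr <- screen_compounds(compounds, crit)
  say("screen: kept %d of %d entries (%d unique molecules)",
      scr$n_kept, nrow(compounds), scr$n_unique)
  write_compound_table(scr$kept, file.path(out_dir, "kept_compounds.tsv"))

  # ---- stage 2: assemble ----
  uniq <- unique_targets(drug_genes)
  hc <- herb_compound_network(scr$kept)
  write_bip_sif(hc, file.path(out_dir, "herb_compound.sif"))
  ct <- compound_target_network(scr$kept, uniq, config$compound_target_map)
  write_bip_sif(ct, file.path(out_dir, "compound_target.sif"))
  say("assemble: %d unique targets; compound-target network has %d nodes",
      length(uniq), ct$n_nodes)

  # ---- stage 3: intersect ----
  disease_kept <- filter_disease_targets(disease, score_min)
  shared <- intersect_targets(uniq, disease_kept$gene_symbol)
  say("intersect: %d drug x %d disease targets -> %d shared genes",
      length(uniq), nrow(disease_kept), length(shared))
  write_gene_list(shared, file.path(out_dir, "intersection_genes.txt"))

  # ---- stage 4: ppi screen ----
  ppi <- NULL; planted_core <- NULL
  if (synthetic) {
    pc <- gen_planted_core_network(sim)
    ppi <- pc$network; planted_core <- pc$core
  } else if (!is.null(config$ppi)) {
    ppi <- if (is.character(config$ppi)) {
      scale <- if (is.null(config$ppi_scale)) "unit" else config$ppi_scale
      read_edge_list(config$ppi, scale)
    } else config$ppi
  }
  screen_rounds <- NULL; core <- NULL
  if (is.null(ppi)) {
    say("ppi-screen: skipped (no PPI input supplied)")
  } else {
    ppi <- filter_confidence(ppi, ppi_score_min)
    rounds <- if (!is.null(config$rounds)) {
      lapply(config$rounds, function(r) do.call(screen_criteria, as.list(r)))
    } else if (synthetic) {
      planted_core_rounds(centralities(ppi), sim$core_size)
    } else {
      list(screen_criteria(20, 0.685, 0.011), screen_criteria(26, 0.771, 0.029))
    }
    screen_rounds <- iterative_screen(ppi, rounds)
    core <- screen_rounds[[length(screen_rounds)]]$survivors
    say("ppi-screen: %d nodes / %d edges -> %s -> %d core targets",
        n_nodes(ppi), n_edges(ppi),
        paste(vapply(screen_rounds, function(r) length(r$survivors),
                     integer(1)), collapse = " -> "),
        length(core))
    write_gene_list(sort(core), file.path(out_dir, "core_targets.txt"))
    for (k in seq_along(screen_rounds))
      write_network(induced_subnetwork(ppi, screen_rounds[[k]]$survivors),
                    file.path(out_dir, sprintf("ppi_round%d.sif", k)), "sif")
  }

  # ---- stage 5: enrichment ----
  enrich_path <- NULL
  collection <- NULL; query <- NULL; background <- NULL
  if (synthetic) {
    ann <- gen_annotation_collection(sim)
    collection <- ann$collection; query <- ann$query
    background <- ann$background
  } else if (!is.null(config$gmt)) {
    collection <- if (is.character(config$gmt)) read_gmt(config$gmt)
                  else config$gmt
    query <- if (length(shared) > 0) shared else uniq
    if (!is.null(config$background))
      background <- if (is.character(config$background) &&
                        file.exists(config$background[1]))
        read_gene_list(config$background) else config$background
  }
  if (is.null(collection)) {
    say("enrich: skipped (no annotation collection supplied)")
  } else {
    enr <- hypergeom_enrich(query, collection, background)
    enrich_path <- "enrichment.tsv"   # relative: reports stay byte-stable
    write.table(enr, file.path(out_dir, enrich_path), sep = "\t",
                quote = FALSE, row.names = FALSE)
    say("enrich: %d sets tested, top set %s (p_adj %.3g)",
        nrow(enr), enr$set_id[1], enr$p_adj[1])
  }

  report <- list(
    seed = seed,
    criteria = unclass(crit),
    score_min = score_min,
    ppi_score_min = ppi_score_min,
    screened = list(total = scr$n_kept, per_herb = as.list(scr$per_herb),
                    unique_molecules = scr$n_unique),
    targets = list(raw = length(drug_genes), unique = length(uniq)),
    compound_target_nodes = ct$n_nodes,
    intersection = list(count = length(shared), genes = shared),
    ppi = if (is.null(ppi)) "skipped" else list(
      nodes = n_nodes(ppi), edges = n_edges(ppi),
      rounds = lapply(screen_rounds, function(r) list(
        criteria = unclass(r$criteria),
        survivors = sort(r$survivors),
        induced_edge_count = r$induced_edge_count)),
      core_targets = sort(core),
      planted_core = if (!is.null(planted_core)) sort(planted_core)),
    enrichment = if (is.null(enrich_path)) "skipped" else enrich_path)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

# SIF export for bipartite networks (relation label "pp"); isolated nodes as
# single-field lines, matching write_network().
write_bip_sif <- function(bip, path) {
  lines <- character(0)
  if (nrow(bip$edges) > 0)
    lines <- sprintf("%s\tpp\t%s", bip$edges$left, bip$edges$right)
  isolated <- setdiff(c(bip$left, bip$right),
                      c(bip$edges$left, bip$edges$right))
  writeLines(c(lines, isolated), path)
  invisible(path)
}
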