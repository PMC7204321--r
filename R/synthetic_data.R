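#' Simulation configuration
#'
#' Defaults mirror the scale of the packaged study so synthetic runs look
#' like the real one: 200 candidate compounds screened down to 77
#' (`pass_fraction = 0.385`), 161 drug targets vs 200 disease targets with a
#' planted overlap of 38, a 38-node PPI network with a planted 7-clique core
#' and 31-node sparse periphery, and an annotation collection of 50 decoy
#' sets plus one planted set over a 1000-gene background queried with 38
#' genes.
#'
#' @param seed integer master seed; every generator derives its own RNG
#'   stream from `(seed, generator name)`, so adding a generator never
#'   perturbs the others' output
#' @param n_compounds number of compound rows to generate
#' @param pass_fraction fraction (in \[0,1\]) of rows that pass the default
#'   [screening_criteria()]; exactly `round(pass_fraction * n_compounds)`
#'   rows pass
#' @param n_targets,n_disease,overlap drug / disease target list sizes and
#'   planted intersection size (`overlap <= min(n_targets, n_disease)`)
#' @param score_min disease inference-score cutoff the generated scores are
#'   reported against (default 57.56, the usual CTD-style cutoff here)
#' @param core_size,n_periphery,periphery_edge_prob,core_attach planted-core
#'   PPI generator: clique size (>= 2), periphery size, Erdos-Renyi edge
#'   probability among periphery nodes, and number of core attachments per
#'   periphery node
#' @param n_sets,planted_set_size,planted_overlap,background_size,query_size
#'   annotation generator: decoy set count, set size, planted query/set
#'   overlap, background size and query size
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       n_compounds = 200L, pass_fraction = 0.385,
                       n_targets = 161L, n_disease = 200L, overlap = 38L,
                       score_min = 57.56,
                       core_size = 7L, n_periphery = 31L,
                       periphery_edge_prob = 0.05, core_attach = 2L,
                       n_sets = 50L, planted_set_size = 40L,
                       planted_overlap = 10L, background_size = 1000L,
                       query_size = 38L) {
  cfg <- list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
              pass_fraction = pass_fraction, n_targets = as.integer(n_targets),
              n_disease = as.integer(n_disease), overlap = as.integer(overlap),
              score_min = score_min, core_size = as.integer(core_size),
              n_periphery = as.integer(n_periphery),
              periphery_edge_prob = periphery_edge_prob,
              core_attach = as.integer(core_attach),
              n_sets = as.integer(n_sets),
              planted_set_size = as.integer(planted_set_size),
              planted_overlap = as.integer(planted_overlap),
              background_size = as.integer(background_size),
              query_size = as.integer(query_size))
  stopifnot(cfg$pass_fraction >= 0, cfg$pass_fraction <= 1,
            cfg$overlap <= min(cfg$n_targets, cfg$n_disease),
            cfg$core_size >= 2, cfg$core_attach >= 1,
            cfg$core_attach <= cfg$core_size,
            cfg$periphery_edge_prob >= 0, cfg$periphery_edge_prob <= 1,
            cfg$planted_overlap <= min(cfg$planted_set_size, cfg$query_size),
            cfg$planted_set_size <= cfg$background_size,
            cfg$query_size <= cfg$background_size)
  structure(cfg, class = "sim_config")
}

# Run expr under an RNG stream derived from (seed, stream name); restores the
# caller's RNG state afterwards so generators never perturb each other.
with_stream <- function(seed, name, expr) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 100000L
  derived <- (as.integer(seed) %% 20000L) * 100000L + h  # < 2^31
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(derived, kind = "Mersenne-Twister")
  expr
}

#' Generate a compound descriptor table with a planted pass-set
#'
#' Exactly `round(pass_fraction * n_compounds)` rows satisfy the default
#' [screening_criteria()]; passing rows are drawn uniformly inside the
#' criteria box (MW in \[180, 500\] Da, the range typical of orally active
#' drugs), failing rows violate exactly one criterion chosen uniformly (all
#' other descriptors drawn from passing ranges). Herbs are assigned
#' round-robin over the eight [HERB_CODES]. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()]
#' @return list with `compounds` (data.frame in [read_compound_table()]
#'   shape) and `pass_index` (integer positions of the planted pass rows)
#' @export
gen_compound_table <- function(cfg) {
  n <- cfg$n_compounds
  n_pass <- round(cfg$pass_fraction * n)
  with_stream(cfg$seed, "compounds", {
    draw_pass <- function(m) data.frame(
      mw = runif(m, 180, 500), alogp = runif(m, -2, 5),
      hdon = sample(0:5, m, replace = TRUE),
      hacc = sample(0:10, m, replace = TRUE),
      ob = runif(m, 30, 110), dl = runif(m, 0.18, 1))
    df <- draw_pass(n)
    pass_index <- sort(sample.int(n, n_pass))
    fail_index <- setdiff(seq_len(n), pass_index)
    for (i in fail_index) {
      switch(sample.int(6, 1),
             df$mw[i] <- runif(1, 500.5, 800),
             df$alogp[i] <- runif(1, 5.1, 9),
             df$hdon[i] <- sample(6:10, 1),
             df$hacc[i] <- sample(11:16, 1),
             df$ob[i] <- runif(1, 0, 29.9),
             df$dl[i] <- runif(1, 0, 0.17))
    }
    compounds <- data.frame(
      mol_id = sprintf("SIM%05d", seq_len(n)),
      name = sprintf("simulated-compound-%d", seq_len(n)),
      herb = rep_len(HERB_CODES, n),
      df, stringsAsFactors = FALSE)
    list(compounds = compounds, pass_index = pass_index)
  })
}

#' Generate drug / disease target lists with a planted intersection
#'
#' Draws disjoint symbol pools, plants an overlap of exactly `cfg$overlap`
#' genes, and attaches CTD-style inference scores to the disease list:
#' uniform on \[0, 120\], so roughly half clear the default 57.56 cutoff.
#' The retained count at `cfg$score_min` is computed at generation time and
#' returned so the filter can be cross-checked.
#'
#' @param cfg a [sim_config()]
#' @return list with `drug` (character symbols), `disease` (data.frame
#'   `gene_symbol`, `inference_score`), `expected_intersection` (sorted
#'   character), `score_min` and `expected_kept` (count of disease rows with
#'   score >= `score_min`)
#' @export
gen_target_sets <- function(cfg) {
  with_stream(cfg$seed, "targets", {
    pool <- sprintf("GENE%05d", sample.int(99999, cfg$n_targets +
                                             cfg$n_disease - cfg$overlap))
    drug <- pool[seq_len(cfg$n_targets)]
    shared <- sample(drug, cfg$overlap)
    disease_only <- pool[cfg$n_targets + seq_len(cfg$n_disease - cfg$overlap)]
    disease_genes <- sample(c(shared, disease_only))
    scores <- runif(cfg$n_disease, 0, 120)
    list(drug = drug,
         disease = data.frame(gene_symbol = disease_genes,
                              inference_score = scores,
                              stringsAsFactors = FALSE),
         expected_intersection = sort(shared),
         score_min = cfg$score_min,
         expected_kept = sum(scores >= cfg$score_min))
  })
}

#' Generate a planted-core PPI network
#'
#' A clique of `core_size` nodes (the planted core), plus `n_periphery`
#' nodes each attached to `core_attach` uniformly chosen core nodes, with
#' sparse Erdos-Renyi edges among the periphery at `periphery_edge_prob`.
#' Edge confidences are uniform on \[0.7, 0.999\] so the whole network
#' survives the standard 0.7 construction cutoff. With the defaults (7-core,
#' 31 periphery, p = 0.05, 2 attachments) every core node dominates every
#' periphery node on degree, closeness and betweenness with high
#' probability, which is what makes threshold screening recover the core.
#'
#' @param cfg a [sim_config()]
#' @return list with `network` (an [interaction_network()]) and `core`
#'   (character vector of planted core node ids)
#' @export
gen_planted_core_network <- function(cfg) {
  with_stream(cfg$seed, "ppi", {
    core <- sprintf("CORE%02d", seq_len(cfg$core_size))
    periphery <- if (cfg$n_periphery > 0)
      sprintf("PER%02d", seq_len(cfg$n_periphery)) else character()
    ce <- t(combn(core, 2))
    from <- ce[, 1]; to <- ce[, 2]
    for (p in periphery) {
      att <- sample(core, cfg$core_attach)
      from <- c(from, rep(p, length(att))); to <- c(to, att)
    }
    if (length(periphery) >= 2) {
      pe <- t(combn(periphery, 2))
      keep <- runif(nrow(pe)) < cfg$periphery_edge_prob
      from <- c(from, pe[keep, 1]); to <- c(to, pe[keep, 2])
    }
    conf <- runif(length(from), 0.7, 0.999)
    net <- interaction_network(
      nodes = c(core, periphery),
      edges = data.frame(from = from, to = to, confidence = conf))
    list(network = net, core = core)
  })
}

#' Generate an annotation collection with one planted enriched set
#'
#' Builds a background of `background_size` genes, a query of `query_size`
#' genes, one planted set sharing exactly `planted_overlap` genes with the
#' query, and `n_sets` decoy sets drawn uniformly from the background (so
#' decoy/query overlaps follow the hypergeometric null).
#'
#' @param cfg a [sim_config()]
#' @return list with `collection` (a [gene_set_collection()] including the
#'   planted set), `planted_id` (`"SET_PLANTED"`), `query` and `background`
#'   (character vectors)
#' @export
gen_annotation_collection <- function(cfg) {
  with_stream(cfg$seed, "annotations", {
    background <- sprintf("BG%05d", seq_len(cfg$background_size))
    query <- sample(background, cfg$query_size)
    in_both <- sample(query, cfg$planted_overlap)
    planted <- c(in_both,
                 sample(setdiff(background, query),
                        cfg$planted_set_size - cfg$planted_overlap))
    sets <- lapply(seq_len(cfg$n_sets), function(i)
      sample(background, cfg$planted_set_size))
    names(sets) <- sprintf("SET%03d", seq_len(cfg$n_sets))
    sets[["SET_PLANTED"]] <- sample(planted)  # shuffled member order
    desc <- stats::setNames(
      c(sprintf("decoy set %d", seq_len(cfg$n_sets)), "planted enriched set"),
      names(sets))
    list(collection = gene_set_collection(sets, desc),
         planted_id = "SET_PLANTED", query = query, background = background)
  })
}

#' Two-round quantile thresholds for planted-core screening
#'
#' A generic recipe when no hand-picked cutoffs exist: round 1 thresholds at
#' the medians (drops the sparse half), round 2 at the `1 - core_size / N`
#' quantile (the thresholds land in the centrality gap between a dominating
#' core of `core_size` nodes and the rest). Both rounds are evaluated
#' against the full network's centralities in `"fixed-centralities"` mode.
#'
#' @param cent full-network [centralities()] data.frame
#' @param core_size expected core size
#' @return list of two [screen_criteria()]
#' @export
planted_core_rounds <- function(cent, core_size) {
  stopifnot(core_size < nrow(cent))
  list(quantile_thresholds(cent, 0.5),
       quantile_thresholds(cent, 1 - core_size / nrow(cent)))
}
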