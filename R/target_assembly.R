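#' Collapse duplicate gene symbols, preserving first occurrence
#'
#' Target tables list one row per protein, but after symbol mapping several
#' rows can share a gene symbol; the potential-target list is the
#' deduplicated symbol sequence. Matching is case-sensitive after trimming.
#'
#' @param gene_symbols character vector (e.g. the `gene_symbol` column of
#'   [dchd_targets()])
#' @return character vector of unique symbols in first-occurrence order
#' @examples
#' length(unique_targets(dchd_targets()$gene_symbol))  # 161
#' @export
unique_targets <- function(gene_symbols) {
  unique(trimws(as.character(gene_symbols)))
}

#' Filter disease targets by inference score
#'
#' Keeps records whose score is at or above `score_min` (inclusive, the
#' CTD-style ">= cutoff" convention). Records without a score are kept only
#' when `score_min <= 0`, i.e. when the filter is vacuous.
#'
#' @param disease data.frame with `gene_symbol` and `inference_score`
#'   columns (see [read_disease_table()])
#' @param score_min finite score cutoff
#' @return filtered data.frame, input order preserved
#' @export
filter_disease_targets <- function(disease, score_min) {
  stopifnot(is.finite(score_min))
  s <- disease$inference_score
  keep <- if (score_min <= 0) is.na(s) | s >= score_min
          else !is.na(s) & s >= score_min
  disease[keep, , drop = FALSE]
}

#' Intersect drug and disease gene sets
#'
#' Symbol-level intersection (trimmed, case-sensitive exact match, no alias
#' expansion): the overlap between a remedy's potential targets and a
#' disease gene list is the set of candidate therapeutic targets.
#'
#' @param drug_genes,disease_genes character vectors of gene symbols
#' @return sorted character vector of shared symbols
#' @examples
#' shared <- intersect_targets(dchd_targets()$gene_symbol,
#'                             t2dm_targets()$gene_symbol)
#' length(shared)  # 38
#' @export
intersect_targets <- function(drug_genes, disease_genes) {
  sort(intersect(trimws(as.character(drug_genes)),
                 trimws(as.character(disease_genes))))
}

#' Construct a bipartite network
#'
#' Left and right node sets with edges allowed only between sides; the
#' container behind compound-target and herb-compound networks. Node count
#' is always `|left| + |right|`, so ids must not collide across sides.
#'
#' @param left,right character node id vectors (deduplicated)
#' @param edges data.frame with columns `left`, `right`; may have zero rows
#'   (published studies often print node sets without the edge list)
#' @return a `bipartite_network`: list with `left`, `right`, `edges`,
#'   `n_nodes`
#' @export
build_bipartite <- function(left, right,
                            edges = data.frame(left = character(),
                                               right = character())) {
  left <- unique(as.character(left))
  right <- unique(as.character(right))
  if (length(intersect(left, right)) > 0)
    stop("left and right node ids overlap")
  stopifnot(is.data.frame(edges), all(c("left", "right") %in% names(edges)))
  edges <- data.frame(left = as.character(edges$left),
                      right = as.character(edges$right),
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    if (!all(edges$left %in% left))
      stop("edge endpoint not among declared left nodes: ",
           setdiff(edges$left, left)[1])
    if (!all(edges$right %in% right))
      stop("edge endpoint not among declared right nodes: ",
           setdiff(edges$right, right)[1])
    edges <- edges[!duplicated(paste(edges$left, edges$right, sep = "\r")), ,
                   drop = FALSE]
  }
  structure(list(left = left, right = right, edges = edges,
                 n_nodes = length(left) + length(right)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %d + %d nodes, %d edges\n",
              length(x$left), length(x$right), nrow(x$edges)))
  invisible(x)
}

#' Degree of every node in a bipartite network
#' @param net a `bipartite_network`
#' @return named integer vector over all nodes (zeros for isolated nodes)
#' @export
bipartite_degrees <- function(net) {
  nodes <- c(net$left, net$right)
  tab <- table(factor(c(net$edges$left, net$edges$right), levels = nodes))
  stats::setNames(as.integer(tab), nodes)
}

#' Entry-level node key for a screened compound row
#'
#' Herb-compound entries are the network currency (the same molecule listed
#' under two herbs is two nodes), so compound node ids are `herb:mol_id`.
#'
#' @param compounds data.frame with `herb` and `mol_id` columns
#' @return character vector of entry keys
#' @export
compound_entry_key <- function(compounds) {
  paste(compounds$herb, compounds$mol_id, sep = ":")
}

#' Herb-compound bipartite network
#'
#' One edge per screened herb-compound entry, linking the herb to the entry
#' node; with the packaged study table this gives 8 herb nodes, 77 compound
#' nodes and 77 edges.
#'
#' @param compounds data.frame of (screened) compound entries
#' @return a `bipartite_network` with herbs on the left
#' @export
herb_compound_network <- function(compounds) {
  entries <- compound_entry_key(compounds)
  build_bipartite(left = unique(compounds$herb), right = unique(entries),
                  edges = data.frame(left = compounds$herb, right = entries))
}

#' Compound-target bipartite network
#'
#' Compound entries on the left, target gene symbols on the right, edges
#' from a user-supplied compound-target map (which may be empty: node counts
#' are defined regardless). Per-target compound counts are available via
#' [bipartite_degrees()].
#'
#' @param compounds data.frame of screened compound entries
#' @param gene_symbols character vector of target symbols (deduplicated via
#'   [unique_targets()])
#' @param compound_target_map optional data.frame with columns `compound`
#'   (entry key, see [compound_entry_key()]) and `gene_symbol`
#' @return a `bipartite_network`
#' @export
compound_target_network <- function(compounds, gene_symbols,
                                    compound_target_map = NULL) {
  edges <- if (is.null(compound_target_map)) {
    data.frame(left = character(), right = character())
  } else {
    data.frame(left = as.character(compound_target_map$compound),
               right = as.character(compound_target_map$gene_symbol))
  }
  build_bipartite(left = unique(compound_entry_key(compounds)),
                  right = unique_targets(gene_symbols),
                  edges = edges)
}
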