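#' Read a compound descriptor table
#'
#' Reads a delimited table of herb-compound entries with the six ADME /
#' drug-likeness descriptors used for screening: molecular weight (`mw`,
#' Dalton), octanol/water partition estimate (`alogp`), hydrogen-bond donor
#' and acceptor counts (`hdon`, `hacc`, integers), oral bioavailability
#' (`ob`, percent; values above 100 occur in published tables) and
#' drug-likeness (`dl`, in \[0, 1\]). Herb codes are validated against
#' [HERB_CODES]; the variant spelling "RRER" is canonicalized to "RERR".
#'
#' @param path file path
#' @param sep field delimiter, default tab
#' @return data.frame with columns `mol_id`, `name`, `herb`, `mw`, `alogp`,
#'   `hdon`, `hacc`, `ob`, `dl`, one row per herb-compound entry in file
#'   order. Zero data rows give a zero-row data.frame.
#' @seealso [dchd_compounds()] for the packaged study table
#' @export
read_compound_table <- function(path, sep = "\t") {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  required <- c("mol_id", "name", "herb", "mw", "alogp", "hdon", "hacc",
                "ob", "dl")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("compound table is missing column(s): ",
         paste(missing, collapse = ", "))
  df <- df[required]
  for (col in c("mw", "alogp", "hdon", "hacc", "ob", "dl")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(df[[col]])) | is.na(v))
    if (length(bad) > 0)
      stop(sprintf("unparseable numeric value in column '%s', data row %d",
                   col, bad[1]))
    df[[col]] <- v
  }
  df$herb <- canonical_herb(df$herb)
  unknown <- which(!df$herb %in% HERB_CODES)
  if (length(unknown) > 0)
    stop(sprintf("unknown herb code '%s' in data row %d",
                 df$herb[unknown[1]], unknown[1]))
  validate_compounds(df)
  df
}

validate_compounds <- function(df) {
  if (nrow(df) == 0) return(invisible(TRUE))
  stopifnot(all(df$mw > 0), all(df$hdon >= 0), all(df$hacc >= 0),
            all(df$hdon == round(df$hdon)), all(df$hacc == round(df$hacc)),
            all(df$ob >= 0), all(df$dl >= 0 & df$dl <= 1))
  invisible(TRUE)
}

#' Write a compound descriptor table
#' @param compounds data.frame as returned by [read_compound_table()]
#' @param path output file path
#' @param sep field delimiter, default tab
#' @export
write_compound_table <- function(compounds, path, sep = "\t") {
  write.table(compounds, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein target table
#'
#' Expects columns `uniprot_id`, `target_name`, `gene_symbol` and `herbs`
#' (slash-separated herb codes). Herb codes are validated and canonicalized.
#'
#' @param path file path
#' @param sep field delimiter, default tab
#' @return data.frame with those four columns plus `herb_list`, a list column
#'   of per-row herb code vectors.
#' @export
read_target_table <- function(path, sep = "\t") {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character")
  required <- c("uniprot_id", "target_name", "gene_symbol", "herbs")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("target table is missing column(s): ",
         paste(missing, collapse = ", "))
  df <- df[required]
  df$gene_symbol <- trimws(df$gene_symbol)
  if (nrow(df) > 0 && any(!nzchar(df$gene_symbol)))
    stop("empty gene_symbol in target table")
  df$herb_list <- lapply(strsplit(df$herbs, "/", fixed = TRUE),
                         canonical_herb)
  bad <- which(vapply(df$herb_list,
                      function(h) length(h) == 0 || !all(h %in% HERB_CODES),
                      logical(1)))
  if (length(bad) > 0)
    stop(sprintf("invalid herb attribution '%s' in data row %d",
                 df$herbs[bad[1]], bad[1]))
  df$herbs <- vapply(df$herb_list, paste, character(1), collapse = "/")
  df
}

#' Write a protein target table
#' @param targets data.frame as returned by [read_target_table()]
#' @param path output file path
#' @param sep field delimiter, default tab
#' @export
write_target_table <- function(targets, path, sep = "\t") {
  keep <- c("uniprot_id", "target_name", "gene_symbol", "herbs")
  write.table(targets[keep], path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a disease target table
#'
#' A gene list with an optional CTD-style `inference_score` column; any other
#' columns are preserved. Scores, when present, must be non-negative.
#'
#' @param path file path
#' @param sep field delimiter, default tab
#' @return data.frame with at least `gene_symbol`, plus `inference_score`
#'   (numeric, `NA` when the file has no score column).
#' @export
read_disease_table <- function(path, sep = "\t") {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!"gene_symbol" %in% names(df))
    stop("disease table is missing column: gene_symbol")
  df$gene_symbol <- trimws(as.character(df$gene_symbol))
  if (!"inference_score" %in% names(df)) {
    df$inference_score <- NA_real_
  } else {
    df$inference_score <- as.numeric(df$inference_score)
    if (any(df$inference_score < 0, na.rm = TRUE))
      stop("inference_score must be non-negative")
  }
  df
}

#' Read a STRING-style scored edge list
#'
#' Three whitespace- or tab-delimited columns `nodeA nodeB score`, with or
#' without a header line. STRING exports use integer combined scores on a
#' 0-999 scale (`score_scale = "string1000"`, divided by 1000 on input);
#' unit-interval scores use `score_scale = "unit"`. Self-loop rows are
#' dropped with a warning; duplicate A-B / B-A rows collapse to one edge
#' keeping the maximum confidence.
#'
#' @param path file path
#' @param score_scale `"unit"` (scores already in \[0,1\]) or
#'   `"string1000"` (integers 0-999, divided by 1000)
#' @return an [interaction_network()]
#' @export
read_edge_list <- function(path, score_scale = c("unit", "string1000")) {
  score_scale <- match.arg(score_scale)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(interaction_network())
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < 3))
    stop(sprintf("edge list row %d has fewer than 3 fields",
                 which(lengths(fields) < 3)[1]))
  m <- t(vapply(fields, function(f) f[1:3], character(3)))
  # tolerate a header row (non-numeric score in row 1)
  if (is.na(suppressWarnings(as.numeric(m[1, 3])))) {
    m <- m[-1, , drop = FALSE]
    if (nrow(m) == 0) return(interaction_network())
  }
  score <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(score))
    stop(sprintf("unparseable score in edge list row %d", which(is.na(score))[1]))
  if (score_scale == "string1000") {
    bad <- which(score < 0 | score > 999 | score != round(score))
    if (length(bad) > 0)
      stop(sprintf("score %s outside 0-999 integer scale in row %d",
                   format(score[bad[1]]), bad[1]))
    score <- score / 1000
  } else {
    bad <- which(score < 0 | score > 1)
    if (length(bad) > 0)
      stop(sprintf("score %s outside [0,1] in row %d",
                   format(score[bad[1]]), bad[1]))
  }
  loops <- m[, 1] == m[, 2]
  if (any(loops))
    warning(sprintf("dropped %d self-loop row(s)", sum(loops)))
  interaction_network(
    nodes = unique(c(m[, 1], m[, 2])),
    edges = data.frame(from = m[!loops, 1], to = m[!loops, 2],
                       confidence = score[!loops]))
}

#' Write a network as an edge list, SIF, or GraphML
#'
#' Cytoscape-compatible exports. SIF uses the relation label `pp`; isolated
#' nodes appear as single-field SIF lines. GraphML carries the node ids and
#' edge confidences and round-trips through [read_graphml()].
#'
#' @param net an [interaction_network()]
#' @param path output file path
#' @param format `"sif"`, `"graphml"` or `"edges"` (3-column TSV, unit scale)
#' @param node_attrs optional data.frame of node attributes keyed by a
#'   `node` column; written alongside as `<path>.attrs.tsv`. Rows naming
#'   unknown nodes are an error.
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, format = c("sif", "graphml", "edges"),
                          node_attrs = NULL) {
  format <- match.arg(format)
  if (!is.null(node_attrs)) {
    stopifnot(is.data.frame(node_attrs), "node" %in% names(node_attrs))
    unknown <- setdiff(node_attrs$node, net$nodes)
    if (length(unknown) > 0)
      stop("node attribute row(s) for unknown node(s): ",
           paste(head(unknown, 3), collapse = ", "))
    write.table(node_attrs, paste0(path, ".attrs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (format == "sif") {
    lines <- character(0)
    if (nrow(net$edges) > 0)
      lines <- sprintf("%s\tpp\t%s", net$edges$from, net$edges$to)
    isolated <- setdiff(net$nodes, c(net$edges$from, net$edges$to))
    writeLines(c(lines, isolated), path)
  } else if (format == "edges") {
    write.table(data.frame(nodeA = net$edges$from, nodeB = net$edges$to,
                           score = net$edges$confidence),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(graphml_lines(net), path)
  }
  invisible(path)
}

graphml_lines <- function(net) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="confidence" for="edge" attr.name="confidence" attr.type="double"/>',
    '  <graph edgedefault="undirected">',
    sprintf('    <node id="%s"/>', esc(net$nodes)),
    if (nrow(net$edges) > 0)
      sprintf(paste0('    <edge source="%s" target="%s">',
                     '<data key="confidence">%s</data></edge>'),
              esc(net$edges$from), esc(net$edges$to),
              format(net$edges$confidence, digits = 15)),
    "  </graph>", "</graphml>")
}

#' Read a network written by [write_network()]
#' @param path file path
#' @return an [interaction_network()] (SIF edges get confidence 1)
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  edge_rows <- lengths(fields) >= 3
  edges <- if (any(edge_rows)) {
    m <- t(vapply(fields[edge_rows], function(f) f[c(1, 3)], character(2)))
    data.frame(from = m[, 1], to = m[, 2])
  } else data.frame(from = character(), to = character())
  isolated <- vapply(fields[!edge_rows], `[`, character(1), 1)
  interaction_network(nodes = isolated, edges = edges)
}

#' @rdname read_sif
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//g:node", ns), "id")
  edge_nodes <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- data.frame(
    from = xml2::xml_attr(edge_nodes, "source"),
    to = xml2::xml_attr(edge_nodes, "target"),
    confidence = vapply(edge_nodes, function(e) {
      d <- xml2::xml_find_first(e, ".//g:data", ns)
      if (inherits(d, "xml_missing")) 1 else as.numeric(xml2::xml_text(d))
    }, numeric(1)))
  interaction_network(nodes = nodes, edges = edges)
}

#' Read / write gene-set collections in GMT format
#'
#' GMT is the tab-delimited gene-set format: one set per line as
#' `set_id TAB description TAB member TAB member ...`. Duplicate members
#' within a line are collapsed.
#'
#' @param path file path
#' @return for `read_gmt`, a `gene_set_collection`: a list with `sets`
#'   (named list of character vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  desc <- vapply(fields, `[`, character(1), 2)
  names(desc) <- names(sets)
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection`
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a gene-set collection
#' @param sets named list of character member vectors (each non-empty)
#' @param descriptions optional named character, defaults to set ids
#' @return a `gene_set_collection`
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0) {
    stopifnot(!is.null(names(sets)), all(nzchar(names(sets))),
              !anyDuplicated(names(sets)))
    if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  structure(list(sets = lapply(sets, unique),
                 descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, %d distinct genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Read / write plain-text gene lists (one symbol per line)
#' @param path file path
#' @return character vector of trimmed non-empty symbols
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes character vector
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

# ---- packaged study fixtures ----

fixture_path <- function(name) {
  system.file("extdata", name, package = "netpharm", mustWork = TRUE)
}

#' Packaged study tables
#'
#' The three printed tables of the eight-herb decoction / type 2 diabetes
#' study, shipped as UTF-8 TSV (molecule names ASCII-normalized):
#' `dchd_compounds()` - 77 herb-compound entries (72 unique molecules) with
#' the six screening descriptors; `dchd_targets()` - 161 protein targets
#' with gene symbols and herb attributions; `t2dm_targets()` - the 38
#' disease genes shared between remedy and disease.
#'
#' @return data.frames in the shapes of [read_compound_table()],
#'   [read_target_table()] and [read_disease_table()] respectively.
#' @export
dchd_compounds <- function() read_compound_table(fixture_path("dchd_compounds.tsv"))

#' @rdname dchd_compounds
#' @export
dchd_targets <- function() read_target_table(fixture_path("dchd_targets.tsv"))

#' @rdname dchd_compounds
#' @export
t2dm_targets <- function() read_disease_table(fixture_path("t2dm_targets.tsv"))
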