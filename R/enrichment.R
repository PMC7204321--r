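#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric tests (equivalently Fisher's exact, alternative
#' "greater") of a query gene set against every set in a collection, with
#' Benjamini-Hochberg adjustment across all tested sets. For a set of size
#' `K` in a background of size `N` and a query of size `n` overlapping it in
#' `k` genes, `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, computed by
#' exact summation of point masses.
#'
#' The background defaults to the union of all collection members. Query
#' genes outside the background and set members outside the background are
#' dropped with a warning before counting, so `k <= min(K, n)` always holds.
#'
#' An `ease = TRUE` toggle applies the DAVID-style EASE jackknife, scoring
#' `max(k - 1, 0)` instead of `k` (more conservative for small overlaps).
#'
#' @param query character vector of gene symbols
#' @param collection a [gene_set_collection()]
#' @param background optional character vector; default: union of members
#' @param ease use the EASE `k - 1` variant? default FALSE
#' @return data.frame with columns `set_id`, `description`, `k`, `K`, `n`,
#'   `N`, `p`, `p_adj`, `fold` (`(k/n)/(K/N)`), `neg_log10_p`, sorted by `p`
#'   ascending with ties broken by `set_id`
#' @export
hypergeom_enrich <- function(query, collection, background = NULL,
                             ease = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(trimws(as.character(query)))
  if (is.null(background))
    background <- unique(unlist(collection$sets, use.names = FALSE))
  background <- unique(trimws(as.character(background)))
  if (length(background) == 0) stop("empty background")
  if (length(query) == 0) stop("empty query")
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside background dropped")
    query <- intersect(query, background)
    if (length(query) == 0) stop("no query genes inside background")
  }
  sets <- lapply(collection$sets, intersect, background)
  n_dropped <- sum(lengths(collection$sets) - lengths(sets))
  if (n_dropped > 0)
    warning(n_dropped, " set member(s) outside background dropped")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    members <- sets[[id]]
    K <- length(members)
    k <- length(intersect(query, members))
    k_eff <- if (ease) max(k - 1L, 0L) else k
    data.frame(set_id = id,
               description = unname(collection$descriptions[[id]]),
               k = k, K = K, n = n, N = N,
               p = hyper_tail(k_eff, K, n, N),
               fold = if (K > 0) (k / n) / (K / N) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), fold = numeric())
  out$p_adj <- bh_adjust(out$p)
  out$neg_log10_p <- -log10(out$p)
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out[c("set_id", "description", "k", "K", "n", "N", "p", "p_adj",
        "fold", "neg_log10_p")]
}

# P(X >= k), X ~ Hypergeometric(N, K, n): exact summation of point masses.
hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  # summation can overshoot 1 by an ulp; clamp into (0, 1]
  min(1, sum(dhyper(k:hi, K, N - K, n)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: p-values are ranked ascending, each is
#' multiplied by `m / rank`, and monotonicity is enforced by a running
#' minimum from the largest rank down. Input order is preserved.
#'
#' @param p numeric vector of p-values in (0, 1\]
#' @return adjusted p-values, same length and order
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

#' Top gene sets of an enrichment table
#' @param rows data.frame from [hypergeom_enrich()]
#' @param m number of sets to keep (>= 0)
#' @param by `"p_adj"` (default) or `"p"`
#' @return the first `m` rows under ascending `by`, ties broken by `set_id`
#' @export
top_sets <- function(rows, m, by = c("p_adj", "p")) {
  by <- match.arg(by)
  if (m < 0) stop("m must be non-negative")
  ord <- rows[order(rows[[by]], rows$set_id), , drop = FALSE]
  head(ord, m)
}
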