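#' Right-tailed Fisher exact test for set over-representation
#'
#' Upper-tail hypergeometric probability `P(X >= overlap)` with
#' `X ~ Hypergeom(universe_size, set_size, query_size)`: the chance of
#' drawing at least `overlap` set members in a query of `query_size`
#' molecules sampled without replacement from the universe. Equivalent to a
#' one-sided Fisher exact test on the 2x2 membership table.
#'
#' @param overlap observed query/set intersection size.
#' @param query_size number of query molecules.
#' @param set_size number of set members in the universe.
#' @param universe_size background size.
#' @return p-value in (0, 1].
#' @examples
#' fisher_right_tail(5, 5, 5, 10)  # 1/choose(10, 5)
#' @export
fisher_right_tail <- function(overlap, query_size, set_size, universe_size) {
  if (any(c(overlap, query_size, set_size, universe_size) < 0))
    stop("counts must be non-negative")
  if (overlap > query_size || overlap > set_size)
    stop("overlap exceeds query or set size")
  if (query_size > universe_size || set_size > universe_size)
    stop("query or set exceeds universe")
  if (overlap < query_size + set_size - universe_size)
    stop("overlap below the hypergeometric support minimum")
  if (overlap == 0) return(1)
  phyper(overlap - 1, set_size, universe_size - set_size, query_size,
         lower.tail = FALSE)
}

#' Gene-set enrichment of a query against a collection
#'
#' One right-tailed Fisher test per reference set with at least one member
#' in the universe. The universe defaults to "all molecules quantified in
#' the experiment" and must contain the query. A direction overlay reports
#' the unweighted mean treatment-vs-baseline log2 fold change over each
#' query/set overlap: its sign is the red (up) / green (down) shading of a
#' pathway figure. Significance is called at `-log10(p) >= cutoff`
#' (default 1.3, i.e. p <= 0.05 to the stated precision); no multiple-set
#' correction is applied unless `adjust = TRUE`.
#'
#' @param query character vector of molecule ids (subset of `universe`).
#' @param collection a `GeneSetCollection`.
#' @param universe character vector: the background.
#' @param log2fc_of optional named numeric vector, molecule -> S1 log2fc,
#'   for the direction overlay.
#' @param cutoff non-negative `-log10(p)` significance cutoff.
#' @param adjust also BH-adjust p across sets and report `q`.
#' @return data.frame with one row per set, columns `set_name`, `overlap`,
#'   `query_size`, `set_size_in_universe`, `universe_size`, `p_right`,
#'   `neg_log10_p`, `mean_log2fc`, `passes_cutoff` (plus `q` when
#'   `adjust`), sorted by descending `neg_log10_p`, ties broken by
#'   `set_name`.
#' @export
enrich_collection <- function(query, collection, universe, log2fc_of = NULL,
                              cutoff = 1.3, adjust = FALSE) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (cutoff < 0) stop("`cutoff` must be >= 0")
  query <- unique(toupper(as.character(query)))
  universe <- unique(toupper(as.character(universe)))
  stray <- setdiff(query, universe)
  if (length(stray))
    stop("query molecule(s) outside the universe: ", paste(stray, collapse = ", "))
  if (!is.null(log2fc_of)) names(log2fc_of) <- toupper(names(log2fc_of))

  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    if (!length(members)) return(NULL)
    ov <- intersect(query, members)
    p <- fisher_right_tail(length(ov), length(query), length(members),
                           length(universe))
    mean_fc <- if (!is.null(log2fc_of) && length(ov))
      mean(log2fc_of[ov], na.rm = TRUE) else NA_real_
    data.frame(set_name = nm, overlap = length(ov),
               query_size = length(query),
               set_size_in_universe = length(members),
               universe_size = length(universe),
               p_right = p, neg_log10_p = -log10(p),
               mean_log2fc = mean_fc, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(set_name = character(0), overlap = integer(0),
                      query_size = integer(0), set_size_in_universe = integer(0),
                      universe_size = integer(0), p_right = numeric(0),
                      neg_log10_p = numeric(0), mean_log2fc = numeric(0),
                      passes_cutoff = logical(0)))
  if (adjust) res$q <- bh_adjust(res$p_right)
  res$passes_cutoff <- res$neg_log10_p >= cutoff
  res <- res[order(-res$neg_log10_p, res$set_name), ]
  rownames(res) <- NULL
  res
}
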