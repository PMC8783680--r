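#' Venn partition of two or three named molecule sets
#'
#' Places every molecule in exactly one region keyed by its membership
#' signature — the sorted set names it belongs to, joined by
#' `"&"` (e.g. `"A"`, `"A&B"`, `"A&B&C"`). All `2^k - 1` signatures are
#' reported, empty regions included, so region sizes are diff-stable across
#' runs.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return A `VennPartition`: list with `regions` (named list of molecule
#'   vectors over all signatures) and `input_names`.
#' @examples
#' vp <- venn_partition(list(A = c(1, 4, 5, 7), B = c(2, 4, 6, 7),
#'                           C = c(3, 5, 6, 7)))
#' lengths(vp$regions)  # seven regions of size 1
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 3) stop("venn_partition takes 2 or 3 sets, got ", k)
  if (is.null(names(sets)) || any(names(sets) == "") || anyDuplicated(names(sets)))
    stop("sets must have unique non-empty names")
  nms <- names(sets)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  signature <- apply(member, 1, function(row) paste(nms[row], collapse = "&"))

  all_sigs <- unlist(lapply(seq_len(k), function(m)
    apply(utils::combn(nms, m), 2, paste, collapse = "&")))
  regions <- lapply(setNames(all_sigs, all_sigs), function(s)
    universe[signature == s])
  structure(list(regions = regions, input_names = nms), class = "VennPartition")
}

#' @export
print.VennPartition <- function(x, ...) {
  cat("VennPartition of:", paste(x$input_names, collapse = ", "), "\n")
  sz <- lengths(x$regions)
  for (i in seq_along(sz)) cat(sprintf("  %-12s %d\n", names(sz)[i], sz[i]))
  invisible(x)
}

#' Region sizes of a Venn partition
#' @param x a `VennPartition`.
#' @return named integer vector over all membership signatures.
#' @export
venn_sizes <- function(x) {
  stopifnot(inherits(x, "VennPartition"))
  lengths(x$regions)
}

#' Overlay a molecule set against a reference collection
#'
#' Splits `molecules` into those matched by the reference collection (the
#' union of its member sets, optionally restricted to sets carrying a tissue
#' tag) and those unmatched, with per-set intersection counts. Identifiers
#' are uppercased before matching, the same convention [read_gmt()] applies
#' to the reference; an optional alias map renames query symbols first.
#'
#' @param molecules character vector of molecule ids.
#' @param collection a `GeneSetCollection`.
#' @param tissue_tag optional tag: only sets whose tags include it are used.
#' @param alias optional named character vector mapping query symbols to
#'   reference symbols (applied before case normalization).
#' @return list with `matched`, `unmatched` (disjoint, union = input) and
#'   `per_set_counts` (named integer vector over the sets used).
#' @export
overlay_reference <- function(molecules, collection, tissue_tag = NULL,
                              alias = NULL) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  mols <- as.character(molecules)
  if (!is.null(alias)) {
    hit <- mols %in% names(alias)
    mols[hit] <- alias[mols[hit]]
  }
  mols_uc <- toupper(mols)
  sets <- collection$sets
  if (!is.null(tissue_tag)) {
    tagged <- names(sets)[vapply(names(sets), function(nm)
      tissue_tag %in% (collection$tissue_tags[[nm]] %||% character(0)), logical(1))]
    if (!length(tagged)) {
      avail <- sort(unique(unlist(collection$tissue_tags)))
      stop("unknown tissue tag '", tissue_tag, "'; available: ",
           if (length(avail)) paste(avail, collapse = ", ") else "(none)")
    }
    sets <- sets[tagged]
  }
  members <- unique(unlist(sets))
  is_match <- mols_uc %in% members
  list(matched = unique(molecules[is_match]),
       unmatched = unique(molecules[!is_match]),
       per_set_counts = vapply(sets, function(s) sum(unique(mols_uc) %in% s),
                               integer(1)))
}
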