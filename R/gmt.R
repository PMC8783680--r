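#' Gene-set collection
#'
#' Named sets of molecule identifiers, as read from a GMT file. Identifiers
#' are uppercased on construction so data/reference matching is
#' case-insensitive (mouse symbols are Titlecase, human ALLCAPS; curated
#' mitochondrial or senescence inventories mix both). Tissue tags let a
#' collection carry per-set annotations such as `tissue=skeletal_muscle`.
#'
#' @param sets named list of character vectors (set members).
#' @param name collection name.
#' @param tissue_tags optional named list of character vectors of tags, named
#'   by set; sets without tags may be omitted.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, name = "collection", tissue_tags = list()) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a non-empty named list")
  dup <- names(sets)[duplicated(names(sets))]
  if (length(dup)) stop("duplicate set name(s): ", paste(unique(dup), collapse = ", "))
  sets <- lapply(sets, function(m) unique(toupper(as.character(m))))
  if (any(lengths(sets) == 0)) stop("empty set(s): ",
    paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  structure(list(name = name, sets = sets, tissue_tags = tissue_tags),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection '%s': %d sets, %d distinct members\n",
              x$name, length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then members. Member lists are deduplicated. A token of the
#' form `tissue=<tag>` anywhere in the description field (whitespace- or
#' semicolon-separated) becomes a tissue tag for that set.
#'
#' @param path GMT file path.
#' @param name collection name; defaults to the file basename.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list(); tags <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                   i, length(f)))
    nm <- f[[1]]
    if (nm %in% names(sets)) stop("duplicate set name: ", nm)
    sets[[nm]] <- f[-(1:2)]
    toks <- unlist(strsplit(f[[2]], "[;[:space:]]+"))
    tis <- sub("^tissue=", "", grep("^tissue=", toks, value = TRUE))
    if (length(tis)) tags[[nm]] <- tis
  }
  gene_set_collection(sets, name = name %||% basename(path), tissue_tags = tags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a gene-set collection to GMT
#'
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- if (!is.null(collection$tissue_tags[[nm]]))
      paste0("tissue=", collection$tissue_tags[[nm]], collapse = ";") else "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
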