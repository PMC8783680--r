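#' Expression matrix with condition labels
#'
#' Light container for a molecules-by-samples abundance matrix plus the
#' condition of every sample and a tag recording the measurement scale.
#' The pipeline's testing operations assume `scale_tag = "log2"`; raw counts
#' and raw intensities are carried untransformed until explicitly normalized
#' or log-transformed.
#'
#' @param values numeric matrix, rows = molecules, columns = samples; must
#'   carry unique rownames and colnames.
#' @param conditions named character vector mapping every sample id (names)
#'   to a condition label; every condition label must be used by at least one
#'   sample.
#' @param scale_tag one of `"log2"`, `"raw_count"`, `"raw_intensity"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `condition_of`, `scale_tag`.
#' @examples
#' v <- matrix(rnorm(12, 20), 2, 6,
#'             dimnames = list(c("A", "B"), paste0("s", 1:6)))
#' cond <- setNames(rep(c("UnT", "TRT"), each = 3), paste0("s", 1:6))
#' em <- expression_matrix(v, cond)
#' @export
expression_matrix <- function(values,
                              conditions,
                              scale_tag = c("log2", "raw_count", "raw_intensity")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (molecules) and colnames (samples)")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate molecule id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  conditions <- as.character(conditions) |> setNames(names(conditions))
  missing <- setdiff(colnames(values), names(conditions))
  if (length(missing))
    stop("sample(s) absent from condition map: ", paste(missing, collapse = ", "))
  conditions <- conditions[colnames(values)]
  structure(list(values = values,
                 condition_of = conditions,
                 scale_tag = scale_tag),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d molecules x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  tab <- table(x$condition_of)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Molecule and sample accessors
#' @param x an `ExpressionMatrix`.
#' @return character vector of ids.
#' @export
molecule_ids <- function(x) rownames(x$values)

#' @rdname molecule_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Conditions present in an expression matrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of unique condition labels, in sample order.
#' @export
conditions_of <- function(x) unique(unname(x$condition_of))

.subset_molecules <- function(x, keep) {
  x$values <- x$values[keep, , drop = FALSE]
  x
}

#' Load an expression table plus condition map
#'
#' The table is TSV/CSV (dialect auto-detected from the extension: `.csv`
#' comma, otherwise tab) with first column `molecule_id` and one column per
#' sample. The condition map is a two-column TSV/CSV (`sample_id`,
#' `condition`) covering every sample column.
#'
#' Values are loaded as-is: pass `scale_tag` to record what they are; no
#' transformation is applied here.
#'
#' @param table_path path to the expression table.
#' @param condition_map_path path to the condition map.
#' @param scale_tag measurement scale of the stored values.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(table_path, condition_map_path,
                            scale_tag = c("log2", "raw_count", "raw_intensity")) {
  scale_tag <- match.arg(scale_tag)
  tab <- .read_table_auto(table_path)
  if (ncol(tab) < 2) stop("expression table needs a molecule_id column plus samples")
  ids <- as.character(tab[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate molecule id(s): ", paste(unique(dup), collapse = ", "))
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  cm <- .read_table_auto(condition_map_path)
  if (ncol(cm) < 2) stop("condition map needs columns sample_id, condition")
  conditions <- setNames(as.character(cm[[2]]), as.character(cm[[1]]))
  expression_matrix(values, conditions, scale_tag)
}

.read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write an expression matrix (and optionally its condition map)
#'
#' @param x an `ExpressionMatrix`.
#' @param table_path output path for the expression table (TSV).
#' @param condition_map_path optional output path for the condition map.
#' @return `table_path`, invisibly.
#' @export
write_expression <- function(x, table_path, condition_map_path = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(molecule_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  write_tsv(df, table_path, extra = paste0("scale=", x$scale_tag))
  if (!is.null(condition_map_path)) {
    cm <- data.frame(sample_id = names(x$condition_of),
                     condition = unname(x$condition_of))
    write_tsv(cm, condition_map_path)
  }
  invisible(table_path)
}
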