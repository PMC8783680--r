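#' Minimum-peptide evidence filter
#'
#' Retains the molecules backed by at least `min_peptides` quantifiable
#' peptides, the standard positive-identification rule for label-free
#' proteomics (default 2). Molecules absent from the evidence table are
#' dropped. Row order is preserved.
#'
#' @param x an `ExpressionMatrix`.
#' @param evidence data.frame with columns `protein_id`, `n_peptides`
#'   (non-negative integers).
#' @param min_peptides minimum quantifiable peptides, >= 1.
#' @return The filtered `ExpressionMatrix` (possibly zero rows).
#' @export
filter_min_peptides <- function(x, evidence, min_peptides = 2L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (min_peptides < 1) stop("`min_peptides` must be >= 1")
  if (!all(c("protein_id", "n_peptides") %in% names(evidence)))
    stop("`evidence` needs columns protein_id, n_peptides")
  if (any(evidence$n_peptides < 0)) stop("negative peptide counts in evidence")
  counts <- setNames(as.integer(evidence$n_peptides),
                     as.character(evidence$protein_id))
  n <- counts[molecule_ids(x)]
  keep <- !is.na(n) & n >= min_peptides
  .subset_molecules(x, keep)
}

#' Total-intensity normalization
#'
#' Scales each sample column so all column sums equal the mean of the
#' original column sums (normalization by total peptide amount per sample).
#' Within-column value ratios are preserved exactly.
#'
#' @param x an `ExpressionMatrix` with `scale_tag = "raw_intensity"`,
#'   non-negative values and strictly positive column sums.
#' @return The normalized `ExpressionMatrix` (scale_tag unchanged).
#' @export
normalize_total_intensity <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale_tag != "raw_intensity")
    stop("normalize_total_intensity expects scale_tag = 'raw_intensity', got ",
         x$scale_tag)
  if (any(x$values < 0, na.rm = TRUE)) stop("negative intensities")
  sums <- colSums(x$values, na.rm = TRUE)
  zero <- names(sums)[sums <= 0]
  if (length(zero)) stop("zero column sum in sample(s): ", paste(zero, collapse = ", "))
  target <- mean(sums)
  x$values <- sweep(x$values, 2, target / sums, `*`)
  x
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM = count / ((length/1e3) * (column_total/1e6))`, with the per-sample
#' total mapped reads taken as the column sum. The result is tagged
#' `raw_intensity` (a continuous abundance, no longer a count).
#'
#' @param x an `ExpressionMatrix` with `scale_tag = "raw_count"`.
#' @param lengths named numeric vector, molecule id -> transcript length in
#'   bp (> 0); every molecule in `x` must be present.
#' @return The FPKM-normalized `ExpressionMatrix`.
#' @export
normalize_fpkm <- function(x, lengths) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale_tag != "raw_count")
    stop("normalize_fpkm expects scale_tag = 'raw_count', got ", x$scale_tag)
  len <- lengths[molecule_ids(x)]
  miss <- molecule_ids(x)[is.na(len)]
  if (length(miss)) stop("missing length for molecule(s): ", paste(miss, collapse = ", "))
  if (any(len <= 0)) stop("non-positive transcript length(s)")
  totals <- colSums(x$values, na.rm = TRUE)
  x$values <- x$values / (len / 1e3) / rep(totals / 1e6, each = nrow(x$values))
  x$scale_tag <- "raw_intensity"
  x
}

#' Log2 transform with pseudo-count
#'
#' Converts a raw matrix to log2 scale: `log2(x + eps)`. For counts/FPKM the
#' pseudo-count defaults to 1; for intensities it defaults to the smallest
#' positive value in the matrix (no universal convention exists and intensity
#' dynamic ranges vary by instrument).
#'
#' @param x an `ExpressionMatrix` with raw scale_tag.
#' @param eps pseudo-count; `NULL` for the default above.
#' @return The `ExpressionMatrix` on log2 scale.
#' @export
log2_transform <- function(x, eps = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale_tag == "log2") stop("matrix is already on log2 scale")
  if (is.null(eps)) {
    eps <- if (x$scale_tag == "raw_count") 1
    else {
      pos <- x$values[is.finite(x$values) & x$values > 0]
      if (!length(pos)) stop("no positive values to set a pseudo-count from")
      min(pos)
    }
  }
  x$values <- log2(x$values + eps)
  x$scale_tag <- "log2"
  x
}
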