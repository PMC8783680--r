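#' Classify one trajectory profile
#'
#' Applies the fixed decision table to a molecule's three contrast results
#' (S1 = treatment vs baseline, S2 = withdrawal vs treatment,
#' S3 = withdrawal vs baseline). Rules fire in order, with
#' `d = direction(S1)`:
#'
#' 0. S1 not significant: `unchanged`.
#' 1. S3 significant opposite to d: `overcorrection` (moved beyond baseline
#'    in the opposite direction; S2's call is deliberately not consulted, so
#'    a noisy S2 cannot mask an unambiguous S3).
#' 2. S2 and S3 both significant in direction d: `progressive`.
#' 3. S2 not significant, S3 significant in direction d: `persistent`.
#' 4. S2 significant opposite to d, S3 significant in direction d:
#'    `partially_reversed`.
#' 5. S2 significant opposite to d, S3 not significant:
#'    `completely_reversed` (withdrawal indistinguishable from baseline).
#' 6. anything else: `ambiguous` (e.g. S2 significant in direction d with S3
#'    not significant — contradictory calls are surfaced, not forced).
#'
#' "Partial" versus "complete" reversal is operationalized purely by
#' significance against baseline, the only criterion the design states: a
#' magnitude threshold would add an arbitrary parameter.
#'
#' @param s1_sig,s2_sig,s3_sig logical significance calls.
#' @param d1,d2,d3 directions in `{-1, 0, 1}` (sign of each log2fc).
#' @return list with `letter` (`"a"`-`"j"` or `NA`), `pattern`, `direction`.
#' @export
classify_profile <- function(s1_sig, d1, s2_sig, d2, s3_sig, d3) {
  if (anyNA(c(s1_sig, d1, s2_sig, d2, s3_sig, d3)))
    stop("incomplete profile: NA significance or direction")
  pattern <- .classify_one(s1_sig, d1, s2_sig, d2, s3_sig, d3)
  direction <- if (pattern %in% c("unchanged", "ambiguous")) 0L else as.integer(d1)
  list(letter = .letter_for(pattern, direction),
       pattern = pattern, direction = direction)
}

.classify_one <- function(s1, d1, s2, d2, s3, d3) {
  if (!s1) return("unchanged")
  d <- d1
  if (s3 && d3 == -d) return("overcorrection")
  if (s2 && d2 == d && s3 && d3 == d) return("progressive")
  if (!s2 && s3 && d3 == d) return("persistent")
  if (s2 && d2 == -d && s3 && d3 == d) return("partially_reversed")
  if (s2 && d2 == -d && !s3) return("completely_reversed")
  "ambiguous"
}

.letter_for <- function(pattern, direction) {
  tc <- trajectory_classes()
  i <- which(tc$pattern == pattern & tc$direction == direction)
  if (length(i) == 1) tc$letter[i] else NA_character_
}

#' Classify every molecule in a contrast table
#'
#' Pivots the long-format output of [run_contrasts()] (or
#' [import_contrasts()]) into per-molecule profiles and classifies each into
#' a cluster letter, `unchanged` or `ambiguous`.
#'
#' @param contrasts data.frame from [run_contrasts()]; must contain exactly
#'   three contrasts.
#' @param contrast_order optional character triple naming S1, S2, S3; by
#'   default taken from the `conditions` attribute, falling back to first
#'   appearance order.
#' @param incomplete `"error"` (default) or `"drop"`: what to do with
#'   molecules flagged insufficient in any contrast.
#' @return list with `assignments` (data.frame `molecule_id`, `letter`,
#'   `pattern`, `direction`) and `counts` (named integer vector over the ten
#'   letters plus `unchanged` and `ambiguous`; sums to the number of
#'   classified molecules).
#' @export
classify_dataset <- function(contrasts, contrast_order = NULL,
                             incomplete = c("error", "drop")) {
  incomplete <- match.arg(incomplete)
  if (!nrow(contrasts)) stop("empty contrast table")
  if (is.null(contrast_order)) {
    conds <- attr(contrasts, "conditions")
    contrast_order <- if (!is.null(conds)) .contrast_names(conds)
    else unique(contrasts$contrast)
  }
  if (length(contrast_order) != 3 ||
      !all(contrast_order %in% contrasts$contrast))
    stop("need exactly the three contrasts: ", paste(contrast_order, collapse = ", "))

  wide <- lapply(setNames(contrast_order, c("S1", "S2", "S3")), function(ct) {
    sub <- contrasts[contrasts$contrast == ct, ]
    sub[match(unique(contrasts$molecule_id), sub$molecule_id), ]
  })
  ids <- unique(contrasts$molecule_id)
  bad <- Reduce(`|`, lapply(wide, function(w)
    is.na(w$significant) | w$insufficient | is.na(w$direction)))
  if (any(bad)) {
    if (incomplete == "error")
      stop("incomplete profile(s): ", paste(utils::head(ids[bad], 5), collapse = ", "),
           if (sum(bad) > 5) sprintf(" (+%d more)", sum(bad) - 5),
           "; use incomplete = 'drop' to discard them")
    ids <- ids[!bad]
    wide <- lapply(wide, function(w) w[!bad, ])
  }

  pattern <- character(length(ids))
  for (i in seq_along(ids))
    pattern[i] <- .classify_one(wide$S1$significant[i], wide$S1$direction[i],
                                wide$S2$significant[i], wide$S2$direction[i],
                                wide$S3$significant[i], wide$S3$direction[i])
  direction <- ifelse(pattern %in% c("unchanged", "ambiguous"), 0L,
                      as.integer(wide$S1$direction))
  tc <- trajectory_classes()
  key <- paste(pattern, direction)
  letter <- tc$letter[match(key, paste(tc$pattern, tc$direction))]
  assignments <- data.frame(molecule_id = ids, letter = letter,
                            pattern = pattern, direction = direction,
                            stringsAsFactors = FALSE)
  lvl <- c(tc$letter, "unchanged", "ambiguous")
  counts <- table(factor(ifelse(is.na(letter), pattern, letter), levels = lvl))
  list(assignments = assignments,
       counts = setNames(as.integer(counts), lvl))
}

#' Confusion matrix of recovered vs true trajectory classes
#'
#' @param assignments data.frame from [classify_dataset()]`$assignments`.
#' @param truth data.frame from [simulate_dataset()]`$truth` (columns
#'   `molecule_id`, `class`).
#' @return list with `confusion` (12 x 12 matrix, rows = truth, columns =
#'   predicted, levels: letters a-j, unchanged, ambiguous), `per_class`
#'   (named accuracy per truth class present) and `overall` accuracy.
#' @export
recovery_confusion <- function(assignments, truth) {
  if (!setequal(assignments$molecule_id, truth$molecule_id))
    stop("assignments and truth cover different molecule sets")
  truth <- truth[match(assignments$molecule_id, truth$molecule_id), ]
  lvl <- c(trajectory_classes()$letter, "unchanged", "ambiguous")
  pred <- ifelse(is.na(assignments$letter), assignments$pattern,
                 assignments$letter)
  conf <- table(factor(truth$class, levels = lvl), factor(pred, levels = lvl))
  conf <- unclass(conf)
  names(dimnames(conf)) <- c("truth", "predicted")
  present <- rownames(conf)[rowSums(conf) > 0]
  per_class <- vapply(present, function(cl) conf[cl, cl] / sum(conf[cl, ]),
                      numeric(1))
  list(confusion = conf,
       per_class = per_class,
       overall = sum(diag(conf)) / sum(conf))
}
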