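#' Significance policy
#'
#' How a contrast's p-values become significance calls: `raw_p` thresholds
#' the unadjusted p (the convention for label-free proteomics, alpha 0.05;
#' relaxed to 0.10 for low-power tissue data), `bh_fdr` thresholds the
#' Benjamini-Hochberg adjusted value (the convention for RNA-seq, alpha
#' 0.05). Thresholds are strict (`p < alpha`).
#'
#' @param mode `"raw_p"` or `"bh_fdr"`.
#' @param alpha significance level in (0, 1).
#' @return A `SignificancePolicy` list.
#' @export
significance_policy <- function(mode = c("raw_p", "bh_fdr"), alpha = 0.05) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  structure(list(mode = mode, alpha = alpha), class = "SignificancePolicy")
}

.contrast_names <- function(conditions) {
  paste0(conditions[c(2, 3, 3)], "_vs_", conditions[c(1, 2, 1)])
}

.group_values <- function(x, molecule, condition) {
  v <- x$values[molecule, x$condition_of == condition]
  v[is.finite(v)]
}

#' Log2 fold change between two conditions
#'
#' Mean difference on the log2 scale: `mean(A) - mean(B)`, over finite
#' values.
#'
#' @param x an `ExpressionMatrix` on log2 scale.
#' @param molecule molecule id.
#' @param condition_a,condition_b condition labels (A vs B).
#' @return log2 fold change; `NA` with a warning if either condition has no
#'   finite value (insufficient data).
#' @export
log2_fold_change <- function(x, molecule, condition_a, condition_b) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  a <- .group_values(x, molecule, condition_a)
  b <- .group_values(x, molecule, condition_b)
  if (!length(a) || !length(b)) {
    warning("insufficient data for ", molecule)
    return(NA_real_)
  }
  mean(a) - mean(b)
}

#' Unpaired two-sided Student t-test
#'
#' Equal-variance (pooled) two-sample t-test:
#' `t = (mean(A) - mean(B)) / (s_p * sqrt(1/nA + 1/nB))`, df `nA + nB - 2`.
#' Degenerate zero-pooled-variance groups give p = 1 when the means are
#' equal and p = 0 when they differ (the noiseless limit). A Welch variant
#' is available for unequal variances.
#'
#' @inheritParams log2_fold_change
#' @param welch use the Welch (unequal-variance) test instead.
#' @return two-sided p-value; `NA` with a warning when either condition has
#'   fewer than 2 finite values.
#' @export
t_test_two_sided <- function(x, molecule, condition_a, condition_b,
                             welch = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  a <- .group_values(x, molecule, condition_a)
  b <- .group_values(x, molecule, condition_b)
  if (length(a) < 2 || length(b) < 2) {
    warning("insufficient data for ", molecule)
    return(NA_real_)
  }
  .t_p(mean(a), mean(b), var(a), var(b), length(a), length(b), welch)
}

.t_p <- function(ma, mb, va, vb, na, nb, welch = FALSE) {
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 <= 0) return(if (ma == mb) 1 else 0)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    t <- (ma - mb) / sqrt(se2)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 <= 0) return(if (ma == mb) 1 else 0)
    df <- na + nb - 2
    t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  2 * pt(-abs(t), df)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: for sorted p-values, `q_(i) = min_{j >= i}(p_(j) * m / j)`,
#' capped at 1, returned in input order. `NA` entries propagate and do not
#' count toward `m`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(q)
  o <- order(p[ok])
  ranked <- p[ok][o] * m / seq_len(m)
  q[ok][o] <- pmin(1, rev(cummin(rev(ranked))))
  q
}

#' Run the three perturbation-withdrawal contrasts
#'
#' For every molecule, computes log2 fold change, Student p and BH q for the
#' contrasts treatment vs baseline (S1), withdrawal vs treatment (S2) and
#' withdrawal vs baseline (S3), then applies the significance policy. FDR is
#' adjusted per contrast across molecules. A molecule enters a contrast only
#' when both of its conditions have >= 2 finite values; otherwise that row is
#' flagged `insufficient = TRUE` (never silently dropped).
#'
#' @param x an `ExpressionMatrix` on log2 scale with >= 2 replicates in each
#'   of the three conditions.
#' @param policy a [significance_policy()].
#' @param conditions ordered triple `c(baseline, treatment, withdrawal)`;
#'   defaults to the conditions of `x` in sample order.
#' @param welch use Welch instead of Student t.
#' @return data.frame (long format) with columns `molecule_id`, `contrast`
#'   (`<TRT>_vs_<UnT>` etc.), `log2fc`, `p`, `q`, `significant`, `direction`
#'   (sign of log2fc), `insufficient`.
#' @export
run_contrasts <- function(x, policy = significance_policy(),
                          conditions = NULL, welch = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(policy, "SignificancePolicy"))
  if (x$scale_tag != "log2")
    stop("run_contrasts expects log2-scale data; see log2_transform()")
  if (is.null(conditions)) conditions <- conditions_of(x)
  if (length(conditions) != 3) stop("exactly 3 conditions required")
  missing <- setdiff(conditions, x$condition_of)
  if (length(missing)) stop("condition(s) not in matrix: ", paste(missing, collapse = ", "))

  v <- x$values
  stats_for <- function(cond) {
    cols <- v[, x$condition_of == cond, drop = FALSE]
    fin <- is.finite(cols)
    n <- rowSums(fin)
    cols[!fin] <- 0
    m <- rowSums(cols) / n
    ss <- rowSums((cols - ifelse(fin, m, 0))^2 * fin)
    list(n = n, mean = m, var = ifelse(n > 1, ss / (n - 1), NA_real_))
  }
  gs <- lapply(setNames(conditions, conditions), stats_for)

  pairs <- list(c(2, 1), c(3, 2), c(3, 1))
  cnames <- .contrast_names(conditions)
  out <- vector("list", 3)
  for (k in 1:3) {
    A <- gs[[pairs[[k]][1]]]; B <- gs[[pairs[[k]][2]]]
    suff <- A$n >= 2 & B$n >= 2
    lfc <- ifelse(A$n >= 1 & B$n >= 1, A$mean - B$mean, NA_real_)
    p <- rep(NA_real_, nrow(v))
    if (any(suff)) {
      if (welch) {
        se2 <- A$var / A$n + B$var / B$n
        df <- se2^2 / ((A$var / A$n)^2 / (A$n - 1) + (B$var / B$n)^2 / (B$n - 1))
        t <- (A$mean - B$mean) / sqrt(se2)
        p[suff] <- 2 * pt(-abs(t[suff]), df[suff])
        deg <- suff & se2 <= 0
      } else {
        sp2 <- ((A$n - 1) * A$var + (B$n - 1) * B$var) / (A$n + B$n - 2)
        t <- (A$mean - B$mean) / sqrt(sp2 * (1 / A$n + 1 / B$n))
        p[suff] <- 2 * pt(-abs(t[suff]), (A$n + B$n - 2)[suff])
        deg <- suff & sp2 <= 0
      }
      p[deg] <- ifelse(lfc[deg] == 0, 1, 0)
    }
    q <- bh_adjust(p)
    crit <- if (policy$mode == "raw_p") p else q
    out[[k]] <- data.frame(molecule_id = rownames(v),
                           contrast = cnames[k],
                           log2fc = lfc,
                           p = p,
                           q = q,
                           significant = !is.na(crit) & crit < policy$alpha,
                           direction = sign(lfc),
                           insufficient = !suff,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$molecule_id, rownames(v)), match(res$contrast, cnames)), ]
  rownames(res) <- NULL
  attr(res, "conditions") <- conditions
  attr(res, "policy") <- policy
  res
}

#' Import an external differential-expression table
#'
#' Bypasses the internal t-test engine: accepts any caller's per-contrast
#' results (e.g., a negative-binomial RNA-seq model) as a long table with
#' columns `molecule_id`, `contrast`, `log2fc`, `p`, recomputes BH q per
#' contrast and applies the significance policy, yielding the same shape as
#' [run_contrasts()].
#'
#' @param de data.frame or TSV path with the four columns above.
#' @param policy a [significance_policy()].
#' @return data.frame as in [run_contrasts()].
#' @export
import_contrasts <- function(de, policy = significance_policy()) {
  if (is.character(de)) de <- read_tsv(de)
  need <- c("molecule_id", "contrast", "log2fc", "p")
  if (!all(need %in% names(de)))
    stop("external DE table needs columns: ", paste(need, collapse = ", "))
  de <- de[, need]
  de$q <- NA_real_
  for (ct in unique(de$contrast)) {
    i <- de$contrast == ct
    de$q[i] <- bh_adjust(de$p[i])
  }
  crit <- if (policy$mode == "raw_p") de$p else de$q
  de$significant <- !is.na(crit) & crit < policy$alpha
  de$direction <- sign(de$log2fc)
  de$insufficient <- is.na(de$p)
  attr(de, "policy") <- policy
  de
}
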