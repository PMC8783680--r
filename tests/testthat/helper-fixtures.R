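# Shared fixture builders and independent oracles for the test suite.
# Oracles are deliberately written as brute-force/enumeration routines,
# independent of the package's implementation paths.

make_em <- function(values, conditions, scale_tag = "log2") {
  expression_matrix(values, conditions, scale_tag)
}

# 3-condition matrix from explicit per-condition group means (one molecule)
em_from_groups <- function(unt, trt, wd, reps = length(unt)) {
  v <- matrix(c(unt, trt, wd), nrow = 1)
  samples <- paste0(rep(c("UnT", "TRT", "WD"), c(length(unt), length(trt), length(wd))),
                    "_", c(seq_along(unt), seq_along(trt), seq_along(wd)))
  colnames(v) <- samples
  rownames(v) <- "m1"
  cond <- setNames(rep(c("UnT", "TRT", "WD"), c(length(unt), length(trt), length(wd))),
                   samples)
  expression_matrix(v, cond, "log2")
}

# random log2-scale matrix: m molecules x (3 conditions x reps)
random_em <- function(m = 10, reps = 3, seed = 1, sd = 1) {
  set.seed(seed)
  v <- matrix(rnorm(m * 3 * reps, 20, sd), nrow = m)
  rownames(v) <- sprintf("g%02d", seq_len(m))
  samples <- paste0(rep(c("UnT", "TRT", "WD"), each = reps), "_", seq_len(reps))
  colnames(v) <- samples
  cond <- setNames(rep(c("UnT", "TRT", "WD"), each = reps), samples)
  expression_matrix(v, cond, "log2")
}

# --- independent oracles ------------------------------------------------

# BH step-up straight from the definition: q_(i) = min_{j>=i}(p_(j) * m / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# pooled-variance two-sided t straight from the textbook formula
oracle_student_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(t), na + nb - 2)
}

# hypergeometric upper tail by explicit enumeration of binomial coefficients
oracle_hyper_right <- function(ov, q, K, N) {
  lo <- max(0, q + K - N)
  hi <- min(q, K)
  support <- lo:hi
  probs <- choose(K, support) * choose(N - K, q - support) / choose(N, q)
  sum(probs[support >= ov])
}

# ARI via O(n^2) pair counting (2x2 pair-agreement table formula)
oracle_ari <- function(a, b) {
  n <- length(a)
  a11 <- a10 <- a01 <- a00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) a11 <- a11 + 1
    else if (sa && !sb) a10 <- a10 + 1
    else if (!sa && sb) a01 <- a01 + 1
    else a00 <- a00 + 1
  }
  num <- 2 * (a11 * a00 - a10 * a01)
  den <- (a11 + a10) * (a10 + a00) + (a11 + a01) * (a01 + a00)
  if (den == 0) 1 else num / den
}

# trajectory decision rules re-evaluated independently over the full
# significance x direction grid (each contrast: significant or not, log2fc
# sign +1/-1): every non-fallback rule's firing condition is computed for
# every profile, and the oracle also reports how many fired (exhaustiveness /
# mutual-exclusivity check). Non-significant contrasts still carry a sign.
oracle_classify_grid <- function() {
  grid <- expand.grid(s1 = c(FALSE, TRUE), d1 = c(-1L, 1L),
                      s2 = c(FALSE, TRUE), d2 = c(-1L, 1L),
                      s3 = c(FALSE, TRUE), d3 = c(-1L, 1L))
  grid$pattern <- NA_character_
  grid$n_rules <- 0L
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    not_over <- !(g$s3 && g$d3 == -g$d1)   # guard shared by rules 2-5
    fired <- character(0)
    if (!g$s1) fired <- c(fired, "unchanged")
    if (g$s1 && g$s3 && g$d3 == -g$d1) fired <- c(fired, "overcorrection")
    if (g$s1 && not_over && g$s2 && g$d2 == g$d1 && g$s3 && g$d3 == g$d1)
      fired <- c(fired, "progressive")
    if (g$s1 && not_over && !g$s2 && g$s3 && g$d3 == g$d1)
      fired <- c(fired, "persistent")
    if (g$s1 && not_over && g$s2 && g$d2 == -g$d1 && g$s3 && g$d3 == g$d1)
      fired <- c(fired, "partially_reversed")
    if (g$s1 && not_over && g$s2 && g$d2 == -g$d1 && !g$s3)
      fired <- c(fired, "completely_reversed")
    grid$n_rules[r] <- length(fired)
    grid$pattern[r] <- if (length(fired)) fired[1] else "ambiguous"
  }
  grid
}

# tiny GMT written to a temp file
write_test_gmt <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}
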