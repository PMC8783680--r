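test_that("log2 fold change is the mean difference on the log2 scale", {
  em <- em_from_groups(c(20, 20, 20), c(22, 22, 22), c(21, 21, 21))
  expect_equal(log2_fold_change(em, "m1", "TRT", "UnT"), 2)
  expect_equal(log2_fold_change(em, "m1", "UnT", "UnT"), 0)
  # antisymmetry
  expect_equal(log2_fold_change(em, "m1", "UnT", "TRT"),
               -log2_fold_change(em, "m1", "TRT", "UnT"))
  # random fixture vs brute force
  set.seed(3)
  em2 <- em_from_groups(rnorm(4, 20), rnorm(4, 21), rnorm(4, 20))
  a <- em2$values[1, em2$condition_of == "TRT"]
  b <- em2$values[1, em2$condition_of == "UnT"]
  expect_equal(log2_fold_change(em2, "m1", "TRT", "UnT"), mean(a) - mean(b),
               tolerance = 1e-12)
})

test_that("Student t matches the closed form and stats::t.test, with degenerate limits", {
  set.seed(8)
  for (rep in 1:5) {
    a <- rnorm(3, 20, 0.5); b <- rnorm(3, 21, 0.5)
    em <- em_from_groups(b, a, b)
    p <- t_test_two_sided(em, "m1", "TRT", "UnT")
    expect_equal(p, oracle_student_p(a, b), tolerance = 1e-10)
    expect_equal(p, stats::t.test(a, b, var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
    # Welch variant agrees with stats::t.test default
    expect_equal(t_test_two_sided(em, "m1", "TRT", "UnT", welch = TRUE),
                 stats::t.test(a, b)$p.value, tolerance = 1e-12)
  }
  # equal group means, nonzero variance -> t = 0, p = 1
  em0 <- em_from_groups(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3))
  expect_equal(t_test_two_sided(em0, "m1", "TRT", "UnT"), 1)
  # identical samples -> p = 1
  emi <- em_from_groups(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(t_test_two_sided(emi, "m1", "TRT", "UnT"), 1)
  # zero pooled variance: p = 1 when means equal, 0 when they differ
  emz <- em_from_groups(c(5, 5, 5), c(5, 5, 5), c(7, 7, 7))
  expect_equal(t_test_two_sided(emz, "m1", "TRT", "UnT"), 1)
  expect_equal(t_test_two_sided(emz, "m1", "WD", "UnT"), 0)
  # <2 values per group -> NA with insufficient-data warning
  emna <- em_from_groups(c(5, NA, NA), c(5, 6, 7), c(5, 6, 7))
  expect_warning(pna <- t_test_two_sided(emna, "m1", "TRT", "UnT"),
                 "insufficient")
  expect_true(is.na(pna))
})

test_that("BH adjustment matches step-up enumeration and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(21)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_equal(q, stats::p.adjust(p, method = "BH"))
    expect_true(all(q >= p))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
    # q non-decreasing in p after sorting
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("run_contrasts produces the three calls a constructed profile implies", {
  # noiseless persistent-up molecule plus an unchanged one
  v <- rbind(m_per = c(20, 20, 20, 22, 22, 22, 22, 22, 22),
             m_unc = c(20, 20, 20, 20, 20, 20, 20, 20, 20))
  samples <- paste0(rep(c("UnT", "TRT", "WD"), each = 3), "_", 1:3)
  colnames(v) <- samples
  em <- expression_matrix(v, setNames(rep(c("UnT", "TRT", "WD"), each = 3),
                                      samples), "log2")
  res <- run_contrasts(em, significance_policy("raw_p", 0.05))
  per <- res[res$molecule_id == "m_per", ]
  expect_identical(per$contrast,
                   c("TRT_vs_UnT", "WD_vs_TRT", "WD_vs_UnT"))
  expect_identical(per$significant, c(TRUE, FALSE, TRUE))
  expect_identical(per$direction, c(1, 0, 1))
  expect_equal(per$log2fc, c(2, 0, 2))
  unc <- res[res$molecule_id == "m_unc", ]
  expect_identical(unc$significant, c(FALSE, FALSE, FALSE))

  # monotone threshold: significant set at 0.05 subset of that at 0.10
  em2 <- random_em(m = 200, reps = 3, seed = 14, sd = 0.5)
  r05 <- run_contrasts(em2, significance_policy("raw_p", 0.05))
  r10 <- run_contrasts(em2, significance_policy("raw_p", 0.10))
  expect_true(all(r10$significant[r05$significant]))

  # per-molecule q matches BH across molecules within each contrast
  s1 <- r05[r05$contrast == "TRT_vs_UnT", ]
  expect_equal(s1$q, bh_adjust(s1$p))

  expect_error(run_contrasts(em2, conditions = c("UnT", "TRT", "XX")), "XX")
})

test_that("run_contrasts agrees with per-molecule scalar routines", {
  em <- random_em(m = 25, reps = 3, seed = 99, sd = 0.4)
  res <- run_contrasts(em)
  for (mol in sample(molecule_ids(em), 5)) {
    row <- res[res$molecule_id == mol & res$contrast == "WD_vs_UnT", ]
    expect_equal(row$log2fc, log2_fold_change(em, mol, "WD", "UnT"),
                 tolerance = 1e-12)
    expect_equal(row$p, t_test_two_sided(em, mol, "WD", "UnT"),
                 tolerance = 1e-12)
  }
})

test_that("null simulation raw-p call rate is calibrated at alpha", {
  props <- setNames(c(rep(0, 10), 1), c(trajectory_classes()$letter, "unchanged"))
  d <- simulate_dataset(sim_config(n_molecules = 2000, noise_sd = 0.25,
                                   class_proportions = props, seed = 404))
  res <- run_contrasts(d$matrix, significance_policy("raw_p", 0.05))
  s1 <- res[res$contrast == "TRT_vs_UnT", ]
  hits <- sum(s1$significant)
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.05)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("insufficient-data molecules are flagged, not dropped", {
  em <- random_em(m = 4, reps = 3, seed = 6)
  em$values[2, em$condition_of == "TRT"] <- NA
  em$values[3, em$condition_of == "WD"][1:2] <- NA
  res <- run_contrasts(em)
  expect_setequal(unique(res$molecule_id), molecule_ids(em))
  g2 <- res[res$molecule_id == "g02", ]
  expect_identical(g2$insufficient, c(TRUE, TRUE, FALSE))
  g3 <- res[res$molecule_id == "g03", ]
  expect_identical(g3$insufficient, c(FALSE, TRUE, TRUE))
})

test_that("external DE tables import with per-contrast BH and policy calls", {
  de <- data.frame(molecule_id = rep(c("x", "y"), each = 3),
                   contrast = rep(c("S1", "S2", "S3"), 2),
                   log2fc = c(2, -1, 1, 0.1, 0, -0.1),
                   p = c(0.001, 0.2, 0.01, 0.8, 0.9, 0.7))
  got <- import_contrasts(de, significance_policy("bh_fdr", 0.05))
  expect_equal(got$q[got$contrast == "S1"],
               bh_adjust(de$p[de$contrast == "S1"]))
  expect_identical(got$significant[1], TRUE)
  expect_identical(got$direction, sign(de$log2fc))
  expect_error(import_contrasts(de[, 1:2]), "needs columns")
})
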