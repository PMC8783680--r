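test_that("single-profile classification matches the documented cases", {
  # persistent-up: S1 sig +, S2 ns, S3 sig +
  got <- classify_profile(TRUE, 1, FALSE, 1, TRUE, 1)
  expect_identical(got[c("letter", "pattern", "direction")],
                   list(letter = "b", pattern = "persistent", direction = 1L))
  # completely-reversed-up: S1 sig +, S2 sig -, S3 ns
  got <- classify_profile(TRUE, 1, TRUE, -1, FALSE, -1)
  expect_identical(got$letter, "e")
  expect_identical(got$pattern, "completely_reversed")
  # S1 not significant -> unchanged, no letter
  got <- classify_profile(FALSE, 1, TRUE, 1, TRUE, 1)
  expect_identical(got$pattern, "unchanged")
  expect_true(is.na(got$letter))
  expect_identical(got$direction, 0L)
  # contradictory: S2 sig same direction, S3 ns -> ambiguous
  got <- classify_profile(TRUE, 1, TRUE, 1, FALSE, 1)
  expect_identical(got$pattern, "ambiguous")
  expect_error(classify_profile(TRUE, 1, NA, 1, TRUE, 1), "incomplete")
})

test_that("classifier matches the exhaustive truth-table oracle; rules are exclusive and exhaustive", {
  grid <- oracle_classify_grid()
  # exactly one rule fires for every significance/direction profile
  expect_true(all(grid$n_rules <= 1))
  expect_true(all(grid$pattern[grid$n_rules == 0] == "ambiguous"))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    got <- classify_profile(g$s1, g$d1, g$s2, g$d2, g$s3, g$d3)
    expect_identical(got$pattern, g$pattern,
                     label = sprintf("row %d (%s)", r, paste(g[1:6], collapse = ",")))
    # letter <-> (pattern, direction) bijection
    if (!got$pattern %in% c("unchanged", "ambiguous")) {
      tc <- trajectory_classes()
      i <- match(got$letter, tc$letter)
      expect_identical(tc$pattern[i], got$pattern)
      expect_identical(tc$direction[i], got$direction)
    }
  }
})

test_that("mirror equivariance: negating every fold change swaps partner letters", {
  partners <- c(a = "j", b = "i", c = "h", d = "g", e = "f",
                f = "e", g = "d", h = "c", i = "b", j = "a")
  grid <- oracle_classify_grid()
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    x <- classify_profile(g$s1, g$d1, g$s2, g$d2, g$s3, g$d3)
    y <- classify_profile(g$s1, -g$d1, g$s2, -g$d2, g$s3, -g$d3)
    expect_identical(y$pattern, x$pattern)
    expect_identical(y$direction, -x$direction)
    if (!is.na(x$letter)) expect_identical(y$letter, unname(partners[x$letter]))
  }
})

test_that("noiseless balanced dataset classifies to exact counts", {
  props <- setNames(rep(1 / 11, 11), c(trajectory_classes()$letter, "unchanged"))
  d <- simulate_dataset(sim_config(n_molecules = 110, noise_sd = 0,
                                   class_proportions = props, seed = 5))
  res <- run_contrasts(d$matrix)
  cls <- classify_dataset(res)
  expect_identical(sum(cls$counts), 110L)
  expect_identical(unname(cls$counts["ambiguous"]), 0L)
  truth_counts <- table(d$truth$class)
  for (cl in names(truth_counts))
    expect_identical(unname(cls$counts[cl]), unname(as.integer(truth_counts[cl])))
  # recovery is perfect in the noiseless limit
  conf <- recovery_confusion(cls$assignments, d$truth)
  expect_equal(conf$overall, 1)
  expect_true(all(conf$per_class == 1))
})

test_that("empty significant set classifies everything unchanged", {
  em <- random_em(m = 20, reps = 3, seed = 50, sd = 0.3)
  res <- run_contrasts(em, significance_policy("raw_p", 0.05))
  res$significant <- FALSE  # force no calls
  cls <- classify_dataset(res)
  expect_identical(unname(cls$counts["unchanged"]), 20L)
})

test_that("loosening alpha never reclassifies a lettered molecule as unchanged", {
  d <- simulate_dataset(sim_config(n_molecules = 400, noise_sd = 0.5, seed = 88))
  a1 <- classify_dataset(run_contrasts(d$matrix, significance_policy("raw_p", 0.02)))
  a2 <- classify_dataset(run_contrasts(d$matrix, significance_policy("raw_p", 0.10)))
  lettered1 <- a1$assignments$molecule_id[!is.na(a1$assignments$letter)]
  unchanged2 <- a2$assignments$molecule_id[a2$assignments$pattern == "unchanged"]
  expect_length(intersect(lettered1, unchanged2), 0)
})

test_that("recovery confusion has truth-marginal rows and counts agreements", {
  d <- simulate_dataset(sim_config(n_molecules = 150, seed = 9))
  cls <- classify_dataset(run_contrasts(d$matrix), incomplete = "drop")
  conf <- recovery_confusion(cls$assignments, d$truth)
  expect_identical(dim(conf$confusion), c(12L, 12L))
  expect_equal(unname(rowSums(conf$confusion)[names(table(d$truth$class))]),
               unname(as.numeric(table(d$truth$class))))
  # all-unchanged prediction: accuracy equals truth proportion of unchanged
  fake <- cls$assignments
  fake$letter <- NA_character_; fake$pattern <- "unchanged"; fake$direction <- 0L
  conf2 <- recovery_confusion(fake, d$truth)
  expect_equal(conf2$overall, mean(d$truth$class == "unchanged"))
  # random-permutation prediction matches a brute-force agreement count
  set.seed(1)
  perm <- sample(nrow(cls$assignments))
  shuffled <- cls$assignments
  shuffled[, c("letter", "pattern", "direction")] <-
    cls$assignments[perm, c("letter", "pattern", "direction")]
  conf3 <- recovery_confusion(shuffled, d$truth)
  pred <- ifelse(is.na(shuffled$letter), shuffled$pattern, shuffled$letter)
  truth_aligned <- d$truth$class[match(shuffled$molecule_id, d$truth$molecule_id)]
  expect_equal(conf3$overall, mean(pred == truth_aligned))
  # molecule mismatch rejected
  expect_error(recovery_confusion(cls$assignments[-1, ], d$truth), "different")
})

test_that("noisy recovery at the stated world exceeds 90% for most classes", {
  # delta = 2, sigma = 0.25, n = 3: analytic per-class recovery is ~0.95 for
  # persistent/complete/unchanged and ~0.90 for partial reversal (see the
  # methods vignette); pooled recovery comfortably exceeds 0.9
  d <- simulate_dataset(sim_config(n_molecules = 1100, noise_sd = 0.25, seed = 64))
  cls <- classify_dataset(run_contrasts(d$matrix), incomplete = "drop")
  conf <- recovery_confusion(cls$assignments, d$truth)
  expect_gt(conf$overall, 0.9)
  strong <- setdiff(names(conf$per_class), c("d", "g"))
  expect_true(all(conf$per_class[strong] >= 0.9))
})
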