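test_that("MI of a perfectly separating profile equals the group entropy", {
  cls <- sample_classification(paste0("s", 1:11), rep(c("A", "B"), c(5, 6)))
  prof <- rep(c("Tx", "Quies"), c(5, 6))
  hG <- -(5 / 11) * log2(5 / 11) - (6 / 11) * log2(6 / 11)
  expect_equal(mutual_information(prof, cls), hG, tolerance = 1e-12)

  cls8 <- sample_classification(paste0("s", 1:8), rep(c("A", "B"), each = 4))
  expect_equal(mutual_information(rep(c("X", "Y"), each = 4), cls8), 1.0)
})

test_that("degenerate profiles score zero and empty profiles error", {
  cls <- sample_classification(paste0("s", 1:6), rep(c("A", "B"), 3))
  expect_equal(mutual_information(rep("Tx", 6), cls), 0)
  # all samples in one group
  cls1 <- sample_classification(paste0("s", 1:6), rep("A", 6))
  expect_equal(mutual_information(c("Tx", "Tx", "Quies", "Tx", "Quies",
                                    "Tx"), cls1), 0)
  # fewer than two retained samples
  expect_equal(mutual_information(c("Tx", rep("undefined", 5)), cls), 0)
  expect_error(mutual_information(character(), cls), "empty profile")
})

test_that("undefined samples are excluded before frequencies are computed", {
  cls <- sample_classification(paste0("s", 1:8),
                               c("A", "A", "A", "A", "B", "B", "B", "B"))
  prof <- c("Tx", "Tx", "Tx", "undefined", "Quies", "Quies", "Quies",
            "undefined")
  # after exclusion: perfect 3-vs-3 split -> 1 bit
  expect_equal(mutual_information(prof, cls), 1.0)
  # marginals recomputed over retained samples only (4 A vs 2 B here)
  prof2 <- c("Tx", "Tx", "Tx", "Tx", "Quies", "Quies", "undefined",
             "undefined")
  hG <- -(4 / 6) * log2(4 / 6) - (2 / 6) * log2(2 / 6)
  expect_equal(mutual_information(prof2, cls), hG, tolerance = 1e-12)
})

test_that("R and C++ MI agree with a brute-force double sum", {
  set.seed(42)
  states <- c("a", "b", "c", "d")
  for (i in 1:200) {
    n <- sample(3:12, 1)
    ns <- sample(2:4, 1)
    ng <- sample(2:3, 1)
    groups <- sample(paste0("g", seq_len(ng)), n, replace = TRUE)
    # ensure >= 2 groups appear
    groups[1:2] <- c("g1", "g2")
    prof <- sample(c(states[seq_len(ns)], "undefined"), n, replace = TRUE,
                   prob = c(rep(1, ns), 0.5))
    cls <- sample_classification(paste0("s", seq_len(n)), groups)
    expect_equal(mutual_information(prof, cls),
                 mi_oracle(prof, groups), tolerance = 1e-12)
  }
})

test_that("MI respects its entropy bound and relabelling invariance", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    groups <- sample(c("A", "B", "C"), n, replace = TRUE)
    groups[1:2] <- c("A", "B")
    prof <- sample(c("x", "y", "z", "undefined"), n, replace = TRUE)
    cls <- sample_classification(paste0("s", seq_len(n)), groups)
    mi <- mutual_information(prof, cls)
    keep <- prof != "undefined"
    if (sum(keep) >= 2) {
      pg <- table(groups[keep]) / sum(keep)
      hG <- -sum(pg * log2(pg))
      expect_lte(mi, hG + 1e-12)
    }
    expect_gte(mi, 0)
    # permute state names and group names: MI unchanged
    relab <- c(x = "z", y = "x", z = "y", undefined = "undefined")
    cls2 <- sample_classification(paste0("s", seq_len(n)),
                                  c(A = "C", B = "A", C = "B")[groups])
    expect_equal(mutual_information(unname(relab[prof]), cls2), mi,
                 tolerance = 1e-12)
    # symmetry of the double sum: swap the roles of the two vectors
    if (sum(keep) >= 2) {
      cls_swap <- sample_classification(paste0("s", which(keep)),
                                        prof[keep])
      prof_swap <- stats::setNames(groups[keep], paste0("s", which(keep)))
      expect_equal(mutual_information(prof_swap, cls_swap,
                                      undefined = "<none>"),
                   mi, tolerance = 1e-12)
    }
  }
})

test_that("bh_adjust matches the step-up definition and brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.5, 7)), rep(0.5, 7))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(-0.1, 0.5)), "0, 1")
  set.seed(21)
  for (i in 1:100) {
    p <- runif(sample(1:100, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("permutation p-value is 1 for constant profiles", {
  cls <- sample_classification(paste0("s", 1:6), rep(c("A", "B"), 3))
  res <- permutation_pvalue(rep("Tx", 6), cls, mi_params(500, seed = 4))
  expect_equal(res$mi, 0)
  expect_equal(res$p_raw, 1)
})

test_that("permutation p-values are reproducible and follow conventions", {
  cls <- sample_classification(paste0("s", 1:10), rep(c("A", "B"), each = 5))
  prof <- c(rep("Tx", 5), rep("Quies", 4), "Tx")
  r1 <- permutation_pvalue(prof, cls, mi_params(2000, seed = 99))
  r2 <- permutation_pvalue(prof, cls, mi_params(2000, seed = 99))
  expect_identical(r1, r2)
  r3 <- permutation_pvalue(prof, cls, mi_params(2000, seed = 100))
  expect_equal(r1$mi, r3$mi)  # observed MI seed-independent
  # (r+1)/(n+1) convention offered behind a flag
  r4 <- permutation_pvalue(prof, cls,
                           mi_params(2000, seed = 99, p_add_one = TRUE))
  expect_equal(r4$p_raw, (r1$n_ge + 1) / 2001)
  # a perfectly aligned profile: almost no shuffle reaches the maximum
  perf <- permutation_pvalue(rep(c("Tx", "Quies"), each = 5), cls,
                             mi_params(10000, seed = 1))
  expect_lte(perf$p_raw, 0.02)  # exact p = 2/C(10,5) ~ 0.0079
})

test_that("empirical p-values agree with exhaustive enumeration", {
  set.seed(77)
  cases <- list(
    list(groups = c("A", "A", "A", "B", "B", "B"),
         prof = c("x", "x", "y", "y", "y", "x")),
    list(groups = c("A", "A", "B", "B", "B", "B"),
         prof = c("x", "x", "x", "y", "y", "undefined")),
    list(groups = c("A", "B", "A", "B", "A", "B", "A"),
         prof = c("x", "y", "x", "y", "x", "y", "z")),
    list(groups = c("A", "A", "A", "B", "B"),
         prof = c("x", "x", "x", "y", "y")))
  for (cs in cases) {
    n <- length(cs$groups)
    cls <- sample_classification(paste0("s", seq_len(n)), cs$groups)
    exact <- exact_perm_p(cs$prof, cs$groups)
    emp <- permutation_pvalue(cs$prof, cls, mi_params(10000, seed = 5))
    se <- sqrt(exact * (1 - exact) / 10000)
    expect_lte(abs(emp$p_raw - exact), max(3 * se, 1e-4))
  }
})
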