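test_that("exact signed-rank p matches full enumeration for n <= 8, with and without ties", {
  withr::with_seed(91, {
    for (n in 4:8) {
      for (rep in 1:6) {
        d <- round(rnorm(n, 0, 2), if (rep %% 2) 0 else 2)
        d <- d[d != 0]
        if (length(d) < 2) next
        for (alt in c("two.sided", "greater", "less")) {
          ours <- wilcoxon_signed_rank(d, alternative = alt)
          expect_equal(ours$p_value, enumerate_wilcoxon_p(d, alt),
                       tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("minimum attainable two-sided exact p is 2^(1-n)", {
  for (n in 5:13) {
    p <- wilcoxon_signed_rank(seq_len(n), rep(0, n))$p_value
    expect_equal(p, 2^(1 - n), tolerance = 1e-12)
  }
})

test_that("signed-rank conventions: zero differences dropped, symmetry, error paths", {
  # zeros dropped: (0, 0, 1, 2, 3) behaves as (1, 2, 3)
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, 3))$n, 3L)
  expect_equal(wilcoxon_signed_rank(c(1, -1))$p_value, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "fewer than 2")
  # agrees with the reference implementation on tie-free data
  withr::with_seed(92, d <- rnorm(12))
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  # large-sample normal path matches the reference approximation
  withr::with_seed(93, d30 <- rnorm(30, 0.3))
  expect_equal(wilcoxon_signed_rank(d30)$p_value,
               wilcox.test(d30, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("two-stage FDR matches the brute-force definition and dominates BH", {
  expect_false(any(bky_fdr(rep(1, 10))$rejected))
  expect_true(bky_fdr(0.001)$rejected)
  expect_error(bky_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  pv <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
          0.216, 0.222, 0.251, 0.269, 0.275, 0.34)
  f <- bky_fdr(pv, 0.05)
  expect_identical(f$rejected, brute_bky_reject(pv, 0.05))
  bh <- p.adjust(pv, "BH") <= 0.05
  if (f$stage1_rejections > 0) expect_true(all(f$rejected[bh] | !bh))

  # random vectors, several q levels; with r1 > 0 the two-stage set always
  # contains the BH set at the shrunken level q/(1+q), and contains the BH
  # set at q itself whenever the stage-2 level reaches q
  withr::with_seed(101, {
    for (i in 1:200) {
      m <- sample(3:40, 1)
      p <- runif(m)^sample(1:3, 1)
      q <- sample(c(0.01, 0.05, 0.1), 1)
      f <- bky_fdr(p, q, compute_qvalues = FALSE)
      expect_identical(f$rejected, brute_bky_reject(p, q))
      r1 <- f$stage1_rejections
      if (r1 > 0) {
        bh_shrunk <- p.adjust(p, "BH") <= q / (1 + q)
        expect_true(all(f$rejected[bh_shrunk]))
        if (r1 < m && q / (1 + q) * m / (m - r1) >= q) {
          bh_full <- p.adjust(p, "BH") <= q
          expect_true(all(f$rejected[bh_full]))
        }
      }
    }
  })
})

test_that("q-values invert the two-stage rule", {
  pv <- c(0.001, 0.02, 0.04, 0.2, 0.6)
  f <- bky_fdr(pv, 0.05)
  for (i in seq_along(pv)) {
    if (f$qvalues[i] < 1) {
      just_above <- bky_fdr(pv, min(1, f$qvalues[i] * 1.01),
                            compute_qvalues = FALSE)
      expect_true(just_above$rejected[i])
    }
    if (f$qvalues[i] > 0.011) {
      just_below <- bky_fdr(pv, f$qvalues[i] * 0.99,
                            compute_qvalues = FALSE)
      expect_false(just_below$rejected[i])
    }
  }
  expect_true(all(diff(f$qvalues[order(pv)]) >= -1e-12))
})

test_that("nested t-test aggregates to animal level", {
  same <- nested_t_test(list(c(1, 1), c(2, 2), c(3, 3)),
                        list(c(2), c(1), c(3)))
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)

  nt <- nested_t_test(list(1, 2, 3), list(4, 5, 6))
  expect_equal(nt$t, -3.674235, tolerance = 1e-6)
  expect_equal(nt$df, 4)
  # cross-check against the reference equal-variance t-test on animal means
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(nt$p_value, ref$p.value, tolerance = 1e-12)

  # replicating sections 10x with animal means fixed changes nothing
  rep10 <- nested_t_test(list(rep(1, 10), rep(2, 10), rep(3, 10)),
                         list(rep(4, 10), rep(5, 10), rep(6, 10)))
  expect_equal(rep10$p_value, nt$p_value)

  expect_warning(nested_t_test(list(1, 2, numeric(0)), list(3, 4)),
                 "zero sections")
  expect_error(nested_t_test(list(1), list(2, 3)), "at least 2 animals")
})

test_that("omnibus helpers: Kruskal-Wallis fixture and two-way seeded contrast", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  op <- omnibus_posthoc(y, g)
  expect_equal(op$omnibus$statistic, 7.2)
  expect_equal(op$omnibus$df, 2)

  flat <- omnibus_posthoc(c(1, 2, 3, 1, 2, 3, 1, 2, 3), g)
  expect_gt(flat$omnibus$p, 0.9)
  expect_false(any(flat$posthoc$rejected))
  expect_error(omnibus_posthoc(c(1, 2, 3), c("a", "a", "b")), "n >= 2")

  # seeded block effect: always detected, while false rejections in null
  # blocks stay within the FDR bound (E[V] <= n_blocks * q for an
  # FDR-controlling procedure with at most n_blocks rejections)
  withr::with_seed(111, {
    hits <- 0; false_rej <- 0; reps <- 100
    for (i in seq_len(reps)) {
      blocks <- rep(paste0("r", 1:4), each = 10)
      grp <- rep(rep(c("task", "ctrl"), each = 5), 4)
      y2 <- rnorm(40)
      y2[blocks == "r2" & grp == "task"] <- y2[blocks == "r2" & grp == "task"] + 4
      o2 <- omnibus_posthoc(y2, grp, block = blocks, omnibus = "anova2")
      rej <- o2$posthoc$block[o2$posthoc$rejected]
      hits <- hits + ("r2" %in% rej)
      false_rej <- false_rej + sum(rej != "r2")
    }
    expect_gte(hits / reps, 0.95)
    expect_lte(false_rej / reps, 4 * 0.05 + 0.06)
  })
})

test_that("two-stage FDR controls false rejections under the global null", {
  withr::with_seed(121, {
    any_rej <- vapply(1:500, function(i)
      any(bky_fdr(runif(100), 0.05, compute_qvalues = FALSE)$rejected),
      TRUE)
  })
  expect_lte(mean(any_rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
})
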