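test_that("log2 fold-change is the difference of arm means on the log2 scale", {
  am <- rbind(f1 = c(PS = 10, PT = 10, CS = 10, CT = 10),
              f2 = c(PS = 1, PT = 0, CS = 3, CT = 0))
  sim <- tiny_table(am, n_rep = 2)
  cs_ps <- contrast(c("control", "ASO_S"), c("proband", "ASO_S"))
  lfc <- log2_fold_change(sim$table, sim$design, cs_ps)
  expect_equal(unname(lfc["f1"]), 0)
  expect_equal(unname(lfc["f2"]), 2)
})

test_that("a log2FC of -1.9 corresponds to 26.8% of the reference level", {
  expect_equal(round(percent_of_control(-1.9), 1), 26.8)
})

test_that("Welch statistics match direct evaluation and the stats::t.test oracle", {
  m <- rbind(f1 = c(1, 2, 3, 2, 3, 4))
  tab <- abundance_table(matrix(m, 1, 6, dimnames = list("f1", paste0("s", 1:6))))
  des <- sample_design(data.frame(
    sample = paste0("s", 1:6),
    genotype = rep(c("proband", "control"), each = 3),
    treatment = "untreated", replicate = rep(1:3, 2)))
  ct <- contrast(c("proband", "untreated"), c("control", "untreated"))
  got <- two_sample_test(tab, des, ct)
  expect_equal(got$t, -1.224745, tolerance = 1e-6)
  expect_equal(got$df, 4.0)

  # antisymmetry under arm swap
  rev_ct <- contrast(c("control", "untreated"), c("proband", "untreated"))
  swapped <- two_sample_test(tab, des, rev_ct)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)

  # 100 random small arms against t.test, both welch and pooled
  set.seed(42)
  for (i in 1:100) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    tb <- abundance_table(matrix(c(x, y), 1, n1 + n2,
                                 dimnames = list("f", paste0("s", seq_len(n1 + n2)))))
    dd <- sample_design(data.frame(
      sample = paste0("s", seq_len(n1 + n2)),
      genotype = rep(c("proband", "control"), c(n1, n2)),
      treatment = "untreated",
      replicate = c(seq_len(n1), seq_len(n2))))
    method <- if (i %% 2) "welch" else "pooled"
    mine <- two_sample_test(tb, dd, ct, method = method)
    ref <- t.test(x, y, var.equal = method == "pooled")
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate variance cases are handled explicitly", {
  am <- rbind(same = c(PS = 5, PT = 0, CS = 5, CT = 0),
              diff = c(PS = 5, PT = 0, CS = 7, CT = 0))
  sim <- tiny_table(am, n_rep = 2, sd = 0)
  ct <- contrast(c("control", "ASO_S"), c("proband", "ASO_S"))
  got <- two_sample_test(sim$table, sim$design, ct)
  expect_equal(got$t[1], 0)
  expect_equal(got$p[1], 1)
  expect_equal(got$p[2], .Machine$double.xmin)
  expect_true(got$zero_var_flag[2])
  expect_false(got$zero_var_flag[1])
})

test_that("BH adjustment matches the naive step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (m in c(1, 2, 10, 137, 1000)) {
    p <- runif(m)^2
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  # ties preserved, NA excluded from the number of tests
  p <- c(0.02, 0.02, NA, 0.5)
  q <- bh_adjust(p)
  expect_equal(q[1], q[2])
  expect_true(is.na(q[3]))
  expect_equal(q[!is.na(q)], bh_brute(p[!is.na(p)]))
})

test_that("z-scores standardise each feature and flag constant ones", {
  m <- rbind(a = c(1, 2, 3, 1, 2, 3, 1, 2),
             b = rep(5, 8))
  des <- tiny_design(2)
  tab <- abundance_table(matrix(m, 2, 8, dimnames = list(c("a", "b"), des$sample)))
  z <- z_scores(tab)
  expect_equal(unname(z["a", ]), as.vector(scale(m["a", ])), tolerance = 1e-12)
  expect_equal(unname(z["b", ]), rep(0, 8))
  expect_true(attr(z, "constant")["b"])
  expect_false(attr(z, "constant")["a"])
  expect_lt(abs(mean(z["a", ])), 1e-9)
  expect_equal(sd(z["a", ]), 1, tolerance = 1e-9)

  m3 <- abundance_table(matrix(c(1, 2, 3), 1, 3,
                               dimnames = list("f", c("x", "y", "z"))))
  expect_equal(unname(z_scores(m3)[1, ]), c(-1, 0, 1))
})

test_that("run_contrast composes the pieces and respects missingness", {
  am <- rbind(f1 = c(PS = 0, PT = 0, CS = 1, CT = 0),
              f2 = c(PS = 0, PT = 0, CS = 0, CT = 0))
  sim <- tiny_table(am, n_rep = 3, sd = 0.1)
  tab <- unclass(sim$table)
  tab["f2", sim$design$sample[sim$design$genotype == "control" &
                                sim$design$treatment == "ASO_S"]] <- NA
  tab <- abundance_table(tab)
  ct <- contrast(c("control", "ASO_S"), c("proband", "ASO_S"))
  res <- run_contrast(tab, sim$design, ct)
  expect_true(is.na(res$p[res$feature == "f2"]))
  expect_true(is.na(res$q[res$feature == "f2"]))
  expect_false(res$significant[res$feature == "f2"])
  expect_equal(res$n_test[res$feature == "f2"], 0)
  # the missing feature does not count toward the BH number of tests
  expect_equal(res$q[res$feature == "f1"], res$p[res$feature == "f1"])
})

test_that("an arm with fewer than two samples is rejected at contrast time", {
  am <- rbind(f1 = c(PS = 0, PT = 0, CS = 0, CT = 0))
  sim <- tiny_table(am, n_rep = 2)
  des <- sim$design[-1, ]
  ct <- contrast(c("proband", "ASO_S"), c("control", "ASO_S"))
  expect_error(run_contrast(sim$table, sample_design(des), ct),
               "fewer than 2")
})

test_that("the null simulation keeps the significant fraction near nominal", {
  frac <- vapply(1:5, function(seed) {
    cfg <- omics_sim_config(n_null = 1000, n_rescued_full = 0,
                            n_rescued_partial = 0, n_rescued_not = 0,
                            n_off_target = 0, seed = seed)
    sim <- simulate_omics(cfg)
    res <- run_contrast(sim$table, sim$design,
                        contrast(c("control", "ASO_S"), c("proband", "ASO_S")))
    mean(res$significant)
  }, 0)
  mc <- 3 * sqrt(0.05 * 0.95 / 1000)
  expect_true(all(frac <= 0.05 + mc))
})
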