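test_that("panel site filters apply the inclusive windows", {
  gs <- genome_spec(n_contigs = 1, sites_per_contig = 4, causal_contig = 1,
    causal_site = 1)
  p <- simulate_panel(gs, n_alba = 15, n_orange = 15, missing_rate = 0,
    seed = 2)
  # site 2: 16/30 missing -> dropped; site 3: mean depth 51 -> dropped;
  # site 4: quality exactly 30 -> kept (inclusive bound)
  p$gt[2, 1:16] <- NA
  p$dp[3, ] <- 51L
  p$sites$qual[] <- 60
  p$sites$qual[4] <- 30
  kept <- attr(filter_panel_sites(p), "kept")
  expect_identical(kept, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("allelic test matches hypergeometric enumeration", {
  # fully separated 10 vs 10 alleles
  at <- allelic_test(case_gt = rep(2L, 5), control_gt = rep(0L, 5))
  expect_equal(at$p, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(at$p, fisher_enum_p(at$table), tolerance = 1e-10)

  # identical case/control counts
  expect_equal(allelic_test(c(1L, 1L, 0L), c(1L, 1L, 0L))$p, 1)
  # monomorphic site: p = 1 by convention
  expect_equal(allelic_test(rep(0L, 5), rep(0L, 5))$p, 1)

  # random tables with margins <= 30 against the enumeration oracle
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(2:15, 1)
    n2 <- sample(2:15, 1)
    case <- sample(0:2, n1, replace = TRUE)
    control <- sample(0:2, n2, replace = TRUE)
    at <- allelic_test(case, control)
    expect_equal(at$p, fisher_enum_p(at$table), tolerance = 1e-9)
  }
})

test_that("BH step-up matches the hand computation and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_hand(p), tolerance = 1e-12)
    o <- sample(seq_along(p))
    expect_equal(bh_fdr(p[o]), q[o]) # order invariance
    expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in p
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("a perfectly associated causal site is significant in a 15 vs 15 panel", {
  gs <- genome_spec(n_contigs = 3, sites_per_contig = 20)
  p <- simulate_panel(gs, n_alba = 15, n_orange = 15, seed = 9)
  res <- associate_panel(filter_panel_sites(p))
  causal <- res[res$contig == gs$causal_contig & res$pos == gs$causal_pos, ]
  expect_identical(nrow(causal), 1L)
  expect_true(causal$significant)
  expect_lt(causal$q, 0.05)
})

test_that("null panels yield essentially no q < 0.05 calls", {
  frac <- vapply(1:40, function(s) {
    mean(associate_panel(filter_panel_sites(null_panel(s)))$significant)
  }, numeric(1))
  expect_lt(mean(frac), 0.01)
})
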