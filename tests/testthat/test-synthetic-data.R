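# The cross simulator against exhaustive Mendelian enumeration.
#
# Enumerating gametes of the two designs at a fully linked marker:
#  Aa x Aa  -> Alba offspring are 1 AA : 2 Aa, so the Alba pool carries
#              the linked allele at 2/3; orange offspring are aa (0).
#  Aa x aa  -> Alba offspring are all Aa: Alba pool at 1/2; orange 0.

test_that("fully linked pool frequencies match Mendelian enumeration", {
  freqs_f <- vapply(1:150, function(s) {
    marker_pool_freqs("female_informative", seed = s)
  }, numeric(2))
  expect_equal(mean(freqs_f["alba", ]), 2 / 3, tolerance = 0.02)
  expect_true(all(freqs_f["orange", ] == 0))

  freqs_m <- vapply(1:150, function(s) {
    marker_pool_freqs("male_informative_I", seed = s)
  }, numeric(2))
  expect_true(all(freqs_m["alba", ] == 0.5)) # every Alba offspring is Aa
  expect_true(all(freqs_m["orange", ] == 0))
})

test_that("unlinked markers show no expected pool frequency difference", {
  d <- vapply(1:200, function(s) {
    f <- marker_pool_freqs("female_informative", seed = s, r = 0.5)
    f["alba"] - f["orange"]
  }, numeric(1))
  expect_lt(abs(mean(d)), 0.03)
})

test_that("offspring quotas, dominance and design validation hold", {
  cs <- simulate_cross(
    cross_config("male_informative_II", seed = 11),
    genome_spec(n_contigs = 2, sites_per_contig = 3)
  )
  expect_identical(sum(cs$morph == "alba"), 26L)
  expect_identical(sum(cs$morph == "orange"), 28L)
  expect_identical(cs$morph == "alba", cs$causal_copies >= 1L)

  expect_error(
    cross_config("male_informative_I", mother_genotype = "aa",
      father_genotype = "aa"),
    "impossible design"
  )
  expect_error(
    cross_config("female_informative", mother_genotype = "AA",
      father_genotype = "Aa"),
    "impossible design|requires mother"
  )
})

test_that("pool read sampling respects the pool's alleles and the error model", {
  sites <- data.frame(ref = c("A", "C"), alt = c("G", "T"))
  mono <- matrix(0L, nrow = 4, ncol = 2) # all chromosomes reference

  cnt <- simulate_pool_counts(mono, sites, depth_mean = 50, seq_error = 0,
    seed = 1)
  expect_identical(sum(cnt[1, setdiff(colnames(cnt), "A")]), 0L)
  expect_identical(sum(cnt[2, setdiff(colnames(cnt), "C")]), 0L)

  # frequency-0 pool with error e: expected non-reference fraction = e
  sites1 <- data.frame(ref = "A", alt = "G")
  tot <- c(err = 0, depth = 0)
  for (s in 1:50) {
    cnt <- simulate_pool_counts(matrix(0L, 4, 1), sites1,
      depth_mean = 400, seq_error = 0.1, seed = s)
    tot <- tot + c(sum(cnt[1, ]) - cnt[1, "A"], sum(cnt[1, ]))
  }
  expect_lt(abs(tot["err"] / tot["depth"] - 0.1), 0.01)

  # high depth, frequency 1/2 -> observed frequency near 1/2
  half <- rbind(rep(0L, 1), rep(1L, 1))
  cnt <- simulate_pool_counts(half, sites1, depth_mean = 20000,
    seq_error = 0, seed = 2)
  expect_equal(unname(cnt[1, "G"] / sum(cnt[1, ])), 0.5, tolerance = 0.02)
})

test_that("identical seeds reproduce identical outputs bit-for-bit", {
  gs <- genome_spec(n_contigs = 3, sites_per_contig = 5)
  cc <- cross_config("female_informative", seed = 77)
  expect_identical(simulate_cross(cc, gs), simulate_cross(cc, gs))
  expect_identical(
    simulate_cross_pools(simulate_cross(cc, gs)),
    simulate_cross_pools(simulate_cross(cc, gs))
  )
  expect_identical(
    simulate_panel(gs, seed = 5), simulate_panel(gs, seed = 5)
  )
  expect_identical(
    simulate_depth_windows(c(a = "Aa"), 30, seed = 9),
    simulate_depth_windows(c(a = "Aa"), 30, seed = 9)
  )
})

test_that("panel respects dominance, missingness and null linkage", {
  gs <- genome_spec(n_contigs = 2, sites_per_contig = 10)
  p <- simulate_panel(gs, n_alba = 10, n_orange = 10, missing_rate = 0,
    seed = 3)
  # missing_rate 0: no missing calls
  expect_false(anyNA(p$gt))
  # causal site: all orange individuals aa, all Alba carry >= 1 copy
  causal <- p$gt[p$truth$causal_index, ]
  expect_true(all(causal[p$samples$morph == "orange"] == 0L))
  expect_true(all(causal[p$samples$morph == "alba"] >= 1L))

  # unlinked sites: case/control allele-frequency difference ~ 0 on average
  d <- vapply(1:100, function(s) {
    pp <- simulate_panel(gs, n_alba = 15, n_orange = 15, missing_rate = 0,
      seed = s)
    unl <- which(!pp$sites$contig == pp$truth$causal_contig)[1]
    mean(pp$gt[unl, pp$samples$morph == "alba"]) / 2 -
      mean(pp$gt[unl, pp$samples$morph == "orange"]) / 2
  }, numeric(1))
  expect_lt(abs(mean(d)), 0.03)
})

test_that("depth windows carry the 1 / 0.5 / 0 insertion signature", {
  gt <- setNames(rep(c("AA", "Aa", "aa"), each = 200),
    sprintf("i%03d", 1:600))
  dw <- simulate_depth_windows(gt, baseline_depth = 30, seed = 4)
  calls <- genotype_insertions(dw)
  ratio_by_gt <- tapply(calls$ratio, gt[calls$individual], mean)
  expect_equal(unname(ratio_by_gt["AA"]), 1, tolerance = 0.02)
  expect_equal(unname(ratio_by_gt["Aa"]), 0.5, tolerance = 0.02)
  expect_equal(unname(ratio_by_gt["aa"]), 0, tolerance = 0.02)
})

test_that("morph measurement generators enforce their preconditions", {
  expect_error(
    simulate_morph_measurements(c(alba = 60, orange = 120), n_per_group = 1),
    "n_per_group"
  )
  gr <- simulate_morph_measurements(c(alba = 60, orange = 120),
    dispersion = 1e6, n_per_group = 40, seed = 6)
  m <- tapply(gr$count, gr$group, mean)
  expect_equal(unname(m["alba"]), 60, tolerance = 0.1)
  expect_equal(unname(m["orange"]), 120, tolerance = 0.1)

  li <- simulate_lipid_table(n_per_group = 10, seed = 7)
  # quantification round-trip: summed class amounts recover the totals
  expect_equal(total_lipid(li), li$true_total_nmol, tolerance = 1e-4)
})
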