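test_that("allele frequencies mask N/del and skip zero-depth sites", {
  f <- allele_frequencies(c(A = 10, T = 0, C = 10, G = 0, N = 3, del = 2))
  expect_equal(unname(f[c("A", "C")]), c(0.5, 0.5))
  expect_equal(sum(f), 1)
  expect_equal(unname(allele_frequencies(c(A = 30))["A"]), 1)
  expect_true(all(is.na(allele_frequencies(c(N = 5, del = 2)))))
})

test_that("pool_diff matches the cross expectations and is a metric-like score", {
  # female-cross expectation: alba {A 2/3, C 1/3} vs orange {C 1}
  expect_equal(pool_diff(c(A = 30, C = 15), c(C = 40)), 2 / 3)
  # male-cross expectation: alba {A 1/2, C 1/2} vs orange {C 1}
  expect_equal(pool_diff(c(A = 25, C = 25), c(C = 60)), 0.5)
  expect_equal(pool_diff(c(A = 7, G = 3), c(A = 7, G = 3)), 0)

  for (s in 1:50) {
    set.seed(s)
    a <- setNames(rpois(4, 20), c("A", "T", "C", "G"))
    b <- setNames(rpois(4, 20), c("A", "T", "C", "G"))
    d <- pool_diff(a, b)
    expect_identical(d, pool_diff(b, a))
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
})

test_that("female informative criteria follow the printed rules", {
  ok <- filter_female_informative(
    mother = c(A = 15, C = 15), # het at 0.5, depth 30
    alba_pool = c(A = 30, C = 15), # diff 2/3, A also in mother
    orange_pool = c(C = 40) # homozygous
  )
  expect_true(ok$is_alba_snp)
  expect_equal(ok$diff, 2 / 3)

  # difference below the 0.4 lower bound is rejected
  low <- filter_female_informative(
    mother = c(A = 15, C = 15),
    alba_pool = c(A = 31, C = 49), # diff 0.3875
    orange_pool = c(C = 40)
  )
  expect_false(low$diff_in_band)
  expect_false(low$is_alba_snp)

  # mother at 0.7 is not heterozygous
  not_het <- filter_female_informative(
    mother = c(A = 21, C = 9),
    alba_pool = c(A = 30, C = 15),
    orange_pool = c(C = 40)
  )
  expect_false(not_het$mother_het)
  expect_false(not_het$is_alba_snp)

  # the changed allele must also be a mother allele
  wrong_change <- filter_female_informative(
    mother = c(G = 15, C = 15),
    alba_pool = c(A = 30, C = 15),
    orange_pool = c(C = 40)
  )
  expect_false(wrong_change$same_change)
  expect_false(wrong_change$is_alba_snp)
})

test_that("male informative cross I criteria follow the printed rules", {
  ok <- filter_male_informative_I(
    mother = c(C = 20), orange_pool = c(C = 100),
    alba_pool = c(A = 50, C = 50) # diff 0.5
  )
  expect_true(ok$is_alba_snp)

  # difference 0.60 is outside the 0.45-0.55 band
  off_band <- filter_male_informative_I(
    mother = c(C = 20), orange_pool = c(C = 100),
    alba_pool = c(A = 60, C = 40)
  )
  expect_false(off_band$diff_in_band)
  expect_false(off_band$is_alba_snp)

  # band bounds are closed: exactly 0.55 passes
  edge <- filter_male_informative_I(
    mother = c(C = 20), orange_pool = c(C = 100),
    alba_pool = c(A = 55, C = 45)
  )
  expect_true(edge$diff_in_band)

  # minor-allele count below 3 is rejected
  rare <- filter_male_informative_I(
    mother = c(C = 20), orange_pool = c(C = 30),
    alba_pool = c(A = 2, C = 28)
  )
  expect_identical(rare$minor_count, 2)
  expect_false(rare$minor_count_ok)
  expect_false(rare$is_alba_snp)

  # heterozygous mother fails the homozygosity criterion
  het_mother <- filter_male_informative_I(
    mother = c(A = 10, C = 10), orange_pool = c(C = 100),
    alba_pool = c(A = 50, C = 50)
  )
  expect_false(het_mother$mother_hom)
  expect_false(het_mother$is_alba_snp)
})

test_that("male informative cross II criteria follow the printed rules", {
  ok <- filter_male_informative_II(
    alba_pool = c(G = 30, T = 30), orange_pool = c(G = 60)
  )
  expect_true(ok$is_alba_snp)

  # orange pool not at 100% major frequency
  not_hom <- filter_male_informative_II(
    alba_pool = c(G = 30, T = 30), orange_pool = c(G = 58, T = 2)
  )
  expect_false(not_hom$orange_hom)
  expect_false(not_hom$is_alba_snp)

  # depth 19 is excluded before the criteria
  shallow <- filter_male_informative_II(
    alba_pool = c(G = 10, T = 9), orange_pool = c(G = 60)
  )
  expect_false(shallow$depth_ok)
  expect_false(shallow$is_alba_snp)
})

test_that("depth windows act as preconditions in every design", {
  # female informative: pool depth must lie in [20, 90], mother in [15, 60]
  deep <- filter_female_informative(
    mother = c(A = 15, C = 15),
    alba_pool = c(A = 62, C = 31), # depth 93 > 90
    orange_pool = c(C = 40)
  )
  expect_false(deep$depth_ok)
  expect_false(deep$is_alba_snp)

  thin_mother <- filter_female_informative(
    mother = c(A = 7, C = 7), # depth 14 < 15
    alba_pool = c(A = 30, C = 15),
    orange_pool = c(C = 40)
  )
  expect_false(thin_mother$depth_ok)
})

test_that("indel neighbourhoods are masked by interval arithmetic", {
  sites <- data.frame(contig = "c1", pos = 90:110)
  indels <- data.frame(contig = "c1", pos = 100)
  kept <- mask_indel_neighborhood(sites, indels, window = 5)
  expect_identical(kept$pos, c(90:94, 106:110))

  only_site <- mask_indel_neighborhood(sites, indels, window = 0)
  expect_false(100 %in% only_site$pos)
  expect_identical(nrow(only_site), 20L)

  none <- mask_indel_neighborhood(sites, data.frame(contig = character(),
    pos = integer()), window = 5)
  expect_identical(none, sites)
})

test_that("contig calls require >= 3 passing SNPs in all three crosses", {
  mk <- function(n_pass, contig = "c1") {
    data.frame(contig = contig, is_alba_snp = rep(c(TRUE, FALSE),
      c(n_pass, 1)))
  }
  cc <- call_contigs(list(f = mk(3), m1 = mk(3), m2 = mk(3)))
  expect_true(cc$associated)

  cc2 <- call_contigs(list(f = mk(10), m1 = mk(10), m2 = mk(2)))
  expect_false(cc2$associated)

  cc3 <- call_contigs(list(f = mk(0), m1 = mk(0), m2 = mk(0)))
  expect_false(cc3$associated)
})

test_that("verdicts are pure functions of counts and thresholds", {
  gs <- genome_spec(n_contigs = 3, sites_per_contig = 10)
  sy <- simulate_cross_pools(
    simulate_cross(cross_config("male_informative_I", seed = 31), gs)
  )
  v1 <- bsa_verdicts(sy, "male_informative_I")
  v2 <- bsa_verdicts(sy, "male_informative_I")
  expect_identical(v1, v2)
  expect_identical(v1$is_alba_snp, with(
    v1,
    depth_ok & biallelic & minor_count_ok & mother_hom & orange_hom &
      diff_in_band
  ))
})

test_that("causal-contig sites pass their band and unlinked contigs do not", {
  gs <- genome_spec(n_contigs = 4, sites_per_contig = 40, causal_contig = 2)
  hits <- matrix(0, nrow = 30, ncol = 2)
  for (s in 1:30) {
    verdicts <- lapply(
      c("female_informative", "male_informative_I", "male_informative_II"),
      function(d) {
        cs <- simulate_cross(cross_config(d, seed = derive_seed(s, match(
          d,
          c("female_informative", "male_informative_I", "male_informative_II")
        ))), gs)
        bsa_verdicts(simulate_cross_pools(cs), d)
      }
    )
    cc <- call_contigs(verdicts, contigs = gs$contigs)
    hits[s, 1] <- gs$causal_contig %in% cc$contig[cc$associated]
    hits[s, 2] <- sum(cc$associated & cc$contig != gs$causal_contig)
  }
  expect_gte(mean(hits[, 1]), 0.9) # causal contig recovered
  expect_identical(sum(hits[, 2]), 0) # no unlinked contig ever passes all three
})
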