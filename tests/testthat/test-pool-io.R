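test_that("sync parsing handles well-formed, empty and malformed input", {
  f <- withr::local_tempfile(fileext = ".sync")
  writeLines("ctg1\t5\tA\t10:0:0:0:0:0\t0:0:0:10:0:0", f)
  s <- read_sync(f, pool_names = c("alba", "orange"))
  expect_identical(names(s$pools), c("alba", "orange"))
  expect_identical(sum(s$pools$alba[1, ]), 10L)
  expect_identical(sum(s$pools$orange[1, ]), 10L)
  expect_identical(s$sites$pos, 5L)

  writeLines(character(0), f)
  empty <- read_sync(f)
  expect_s3_class(empty, "sync_table")
  expect_identical(nrow(empty$sites), 0L)

  writeLines("ctg1\t5\tA\t10:0:0", f)
  expect_error(read_sync(f), "line 1.*3 values, expected 6")

  writeLines(c("ctg1\t5\tA\t1:0:0:0:0:0", "ctg1\t6\tA\t1:0:0:0:0:0\t2:0:0:0:0:0"), f)
  expect_error(read_sync(f), "line 2")

  writeLines("ctg1\t5\tA\t-1:0:0:0:0:0", f)
  expect_error(read_sync(f), "negative")

  writeLines("ctg1\tx\tA\t1:0:0:0:0:0", f)
  expect_error(read_sync(f), "position")
})

test_that("sync write/read round-trips bit-exactly, sorted, gzip included", {
  gs <- genome_spec(n_contigs = 3, sites_per_contig = 7)
  sy <- simulate_cross_pools(
    simulate_cross(cross_config("female_informative", seed = 5), gs)
  )
  f <- withr::local_tempfile(fileext = ".sync")
  write_sync(sy, f)
  back <- read_sync(f, pool_names = names(sy$pools))
  expect_identical(back$sites, sy$sites)
  expect_identical(back$pools, sy$pools)

  # positions sorted within contig on disk
  df <- read.table(f, sep = "\t", stringsAsFactors = FALSE)
  expect_false(is.unsorted(order(df$V1, df$V2)))

  fgz <- withr::local_tempfile(fileext = ".sync.gz")
  write_sync(sy, fgz)
  expect_identical(read_sync(fgz, pool_names = names(sy$pools))$pools, sy$pools)
})

test_that("BED coordinates are converted at the boundary", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("ctg1\t0\t100\tinsertion", f)
  b <- read_bed(f)
  expect_identical(b$start, 1L) # 0-based half-open -> 1-based inclusive
  expect_identical(b$end, 100L)
  expect_identical(b$label, "insertion")

  write_bed(b, f)
  expect_identical(readLines(f), "ctg1\t0\t100\tinsertion")
  expect_identical(read_bed(f), b)
})

test_that("per-base depth tables are averaged over windows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  base_depths <- expand.grid(
    contig = "ctg1", pos = 1:40, individual = c("a", "b"),
    stringsAsFactors = FALSE
  )
  base_depths$depth <- ifelse(base_depths$pos <= 20, 30, 15)
  write_tsv(base_depths, f)
  win <- data.frame(
    contig = "ctg1", start = c(1L, 21L), end = c(20L, 40L),
    label = c("flanking", "insertion"), stringsAsFactors = FALSE
  )
  d <- read_depth_table(f, win)
  expect_equal(d$mean_depth[d$label == "flanking"], c(30, 30))
  expect_equal(d$mean_depth[d$label == "insertion"], c(15, 15))

  bad <- data.frame(contig = "ctg1", start = 100L, end = 120L,
    label = c("insertion"), stringsAsFactors = FALSE)
  expect_error(read_depth_table(f, rbind(win, bad)), "no bases")
})

test_that("VCF subset round-trips through disk", {
  gs <- genome_spec(n_contigs = 2, sites_per_contig = 8)
  p <- simulate_panel(gs, n_alba = 5, n_orange = 5, seed = 8)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(p, f)
  back <- read_panel_vcf(f, phenotypes = p$samples)
  expect_identical(unname(back$gt), unname(p$gt))
  expect_identical(back$sites$contig, p$sites$contig)
  expect_identical(back$sites$pos, p$sites$pos)
  expect_identical(back$sites$ref, p$sites$ref)
  expect_identical(back$sites$alt, p$sites$alt)
  expect_equal(back$sites$qual, p$sites$qual)
  expect_identical(back$samples$morph, p$samples$morph)
})
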