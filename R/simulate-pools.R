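#' Simulate pooled sequencing counts for a set of chromosomes
#'
#' Per-site read depth is Poisson with mean `depth_mean`; each read samples
#' one chromosome of the pool uniformly at random and reports its base,
#' mis-read with probability `seq_error` as one of the three other bases
#' chosen uniformly. With `seq_error = 0` the counts contain only alleles
#' present in the pool.
#'
#' @param haplotypes chromosome x site 0/1 matrix (0 = reference allele,
#'   1 = alternate allele), e.g. from [pool_haplotypes()]; a single
#'   diploid individual is a two-row matrix.
#' @param sites data frame with character columns `ref` and `alt` giving
#'   each site's two alleles (rows parallel to `haplotypes` columns).
#' @param depth_mean mean read depth per site (> 0).
#' @param seq_error per-base error probability in `[0, 0.25)`.
#' @param seed integer seed or `NULL`.
#' @return An integer matrix with one row per site and columns
#'   `A, T, C, G, N, del` (sync field order); `N` and `del` are always 0
#'   (the simulator emits no ambiguous bases or indels).
#' @examples
#' hap <- rbind(c(0L, 1L), c(0L, 0L))
#' sites <- data.frame(ref = c("A", "C"), alt = c("G", "T"))
#' simulate_pool_counts(hap, sites, depth_mean = 30, seq_error = 0, seed = 1)
#' @export
simulate_pool_counts <- function(haplotypes, sites, depth_mean,
                                 seq_error = 0, seed = NULL) {
  stopifnot(
    is.matrix(haplotypes), nrow(haplotypes) >= 1,
    ncol(haplotypes) == nrow(sites),
    depth_mean > 0, seq_error >= 0, seq_error < 0.25,
    all(sites$ref %in% BASES), all(sites$alt %in% BASES),
    all(sites$ref != sites$alt)
  )
  with_seed(seed, {
    n_sites <- nrow(sites)
    freq_alt <- colMeans(haplotypes)
    depth <- rpois(n_sites, depth_mean)
    alt_n <- rbinom(n_sites, depth, freq_alt)
    ref_n <- depth - alt_n

    counts <- matrix(0L, nrow = n_sites, ncol = 6L,
      dimnames = list(NULL, SYNC_FIELDS))
    ref_col <- match(sites$ref, SYNC_FIELDS)
    alt_col <- match(sites$alt, SYNC_FIELDS)

    if (seq_error > 0) {
      err_ref <- rbinom(n_sites, ref_n, seq_error)
      err_alt <- rbinom(n_sites, alt_n, seq_error)
      ref_n <- ref_n - err_ref
      alt_n <- alt_n - err_alt
      scatter <- function(i, n_err, source_base) {
        others <- setdiff(BASES, source_base)
        add <- rmultinom(1L, n_err, rep(1 / 3, 3L))[, 1L]
        cols <- match(others, SYNC_FIELDS)
        counts[i, cols] <<- counts[i, cols] + as.integer(add)
      }
      for (i in which(err_ref > 0L)) scatter(i, err_ref[i], sites$ref[i])
      for (i in which(err_alt > 0L)) scatter(i, err_alt[i], sites$alt[i])
    }
    counts[cbind(seq_len(n_sites), ref_col)] <-
      counts[cbind(seq_len(n_sites), ref_col)] + as.integer(ref_n)
    counts[cbind(seq_len(n_sites), alt_col)] <-
      counts[cbind(seq_len(n_sites), alt_col)] + as.integer(alt_n)
    counts
  })
}

#' Construct a sync table
#'
#' The in-memory representation of a Popoolation2 sync file: a site table
#' (`contig`, 1-based `pos`, `ref`) plus one count matrix per sequenced
#' column (pool or parent), each with sync field order `A,T,C,G,N,del`.
#'
#' @param sites data frame with `contig`, `pos` (1-based), `ref`.
#' @param pools named list of integer site x 6 count matrices.
#' @return An object of class `sync_table`.
#' @export
sync_table <- function(sites, pools) {
  stopifnot(
    is.data.frame(sites), all(c("contig", "pos", "ref") %in% names(sites)),
    is.list(pools), length(pools) >= 1
  )
  if (is.null(names(pools)) || anyNA(names(pools)) || any(names(pools) == "")) {
    names(pools) <- sprintf("pool%d", seq_along(pools))
  }
  for (nm in names(pools)) {
    m <- pools[[nm]]
    if (!is.matrix(m) || nrow(m) != nrow(sites) || ncol(m) != 6L) {
      stop_("pool '%s' must be a %d x 6 count matrix", nm, nrow(sites))
    }
    if (any(m < 0)) stop_("pool '%s' has negative counts", nm)
    colnames(pools[[nm]]) <- SYNC_FIELDS
  }
  stopifnot(all(sites$pos >= 1))
  structure(
    list(sites = sites[, c("contig", "pos", "ref")], pools = pools),
    class = "sync_table"
  )
}

#' @export
print.sync_table <- function(x, ...) {
  cat(sprintf(
    "<sync_table> %d sites on %d contigs; columns: %s\n",
    nrow(x$sites), length(unique(x$sites$contig)),
    paste(names(x$pools), collapse = ", ")
  ))
  invisible(x)
}

#' Sequence a simulated cross into a sync table
#'
#' Applies [simulate_pool_counts()] to the morph-sorted offspring pools of
#' a simulated cross (and to the sequenced mother, where the design
#' includes one), producing the sync table that the BSA filters consume.
#' Sub-seeds for the mother, Alba and orange columns are derived
#' deterministically from `seed`.
#'
#' @param cross a [simulate_cross()] result.
#' @param seed integer seed; defaults to the cross config seed offset by
#'   one stream so genotype and read sampling are independent.
#' @return A [sync_table()] with columns `mother` (if sequenced), `alba`,
#'   `orange`.
#' @export
simulate_cross_pools <- function(cross, seed = NULL) {
  stopifnot(inherits(cross, "cross_sim"))
  cfg <- cross$config
  seed <- seed %||% derive_seed(cfg$seed, 1L)
  pools <- list()
  if (!is.null(cfg$mother_depth_mean)) {
    pools$mother <- simulate_pool_counts(
      cross$mother_haplotypes, cross$sites, cfg$mother_depth_mean,
      cfg$seq_error, derive_seed(seed, 0L)
    )
  }
  pools$alba <- simulate_pool_counts(
    pool_haplotypes(cross, "alba"), cross$sites, cfg$pool_depth_mean,
    cfg$seq_error, derive_seed(seed, 1L)
  )
  pools$orange <- simulate_pool_counts(
    pool_haplotypes(cross, "orange"), cross$sites, cfg$pool_depth_mean,
    cfg$seq_error, derive_seed(seed, 2L)
  )
  sync_table(cross$sites, pools)
}
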