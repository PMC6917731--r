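#' Simulate a case/control re-sequencing panel
#'
#' Generates a VCF-style genotype matrix for `n_alba` Alba (case) and
#' `n_orange` orange (control) females drawn from a population in which
#' the dominant allele `A` segregates at frequency `allele_freq_A`.
#' Orange individuals are `aa`; Alba individuals are `AA` or `Aa` with
#' Hardy-Weinberg probabilities conditioned on the Alba phenotype.
#'
#' Each marker site has a population alternate-allele frequency drawn
#' uniformly from `alt_freq_range`. Linkage with the causal locus is
#' site-wise: a chromosome copies the allele in phase with its causal
#' allele (alternate on `A`-bearing chromosomes, reference otherwise)
#' with probability `1 - 2r` and otherwise draws from the population
#' frequency, so `r = 0` sites tag the causal allele perfectly and
#' `r = 0.5` sites are independent of it.
#'
#' @param genome a [genome_spec()].
#' @param n_alba,n_orange panel sizes (default 15 and 15).
#' @param allele_freq_A population frequency of the dominant allele.
#' @param depth_mean mean per-individual per-site read depth.
#' @param qual_mean,qual_sd site quality score distribution (Gaussian,
#'   floored at 1).
#' @param missing_rate per-genotype missingness probability.
#' @param alt_freq_range range of population alternate-allele frequencies
#'   for marker sites.
#' @param seed integer seed or `NULL`.
#' @return An object of class `panel`: list with `sites` (`contig`,
#'   `pos`, `ref`, `alt`, `qual`), `gt` (site x individual matrix of
#'   alternate-allele copies 0/1/2, `NA` = missing), `dp` (matching depth
#'   matrix), `samples` (`sample`, `morph`), and `truth` (per-individual
#'   causal genotypes `AA`/`Aa`/`aa`).
#' @examples
#' p <- simulate_panel(genome_spec(n_contigs = 2, sites_per_contig = 4),
#'                     n_alba = 4, n_orange = 4, seed = 1)
#' p$truth$causal_genotype
#' @export
simulate_panel <- function(genome, n_alba = 15L, n_orange = 15L,
                           allele_freq_A = 0.2, depth_mean = 25,
                           qual_mean = 60, qual_sd = 15,
                           missing_rate = 0.05,
                           alt_freq_range = c(0.05, 0.95), seed = NULL) {
  validate_genome_spec(genome)
  stopifnot(
    n_alba >= 1, n_orange >= 1,
    allele_freq_A > 0, allele_freq_A < 1,
    depth_mean > 0, missing_rate >= 0, missing_rate <= 1
  )
  with_seed(seed, {
    sites <- genome$sites
    n_sites <- nrow(sites)
    n_ind <- n_alba + n_orange
    causal_idx <- which(sites$contig == genome$causal_contig &
      sites$pos == genome$causal_pos)

    sites$ref <- sample(BASES, n_sites, replace = TRUE)
    sites$alt <- vapply(sites$ref, function(b) sample(setdiff(BASES, b), 1L), "")
    sites$qual <- round(pmax(1, rnorm(n_sites, qual_mean, qual_sd)), 1)
    pop_freq <- runif(n_sites, alt_freq_range[1], alt_freq_range[2])
    pop_freq[causal_idx] <- allele_freq_A

    p <- allele_freq_A
    q <- 1 - p
    # P(AA | Alba phenotype) under Hardy-Weinberg
    p_AA_given_alba <- p^2 / (p^2 + 2 * p * q)
    causal_copies <- c(
      ifelse(runif(n_alba) < p_AA_given_alba, 2L, 1L),
      rep(0L, n_orange)
    )
    morph <- rep(c("alba", "orange"), c(n_alba, n_orange))
    samples <- sprintf("%s_%02d", morph, c(seq_len(n_alba), seq_len(n_orange)))

    # chromosome-level carrier state of A: 2 chromosomes per individual
    carries_A <- rbind(
      causal_copies >= 1L, # chromosome 1
      causal_copies == 2L # chromosome 2
    )
    w <- pmax(0, 1 - 2 * sites$r) # phase-copy weight per site
    gt <- matrix(0L, nrow = n_sites, ncol = n_ind,
      dimnames = list(NULL, samples))
    for (chrom in 1:2) {
      phase_allele <- outer(rep(1L, n_sites), as.integer(carries_A[chrom, ]))
      use_phase <- matrix(runif(n_sites * n_ind), n_sites, n_ind) < w
      random_allele <- matrix(
        as.integer(runif(n_sites * n_ind) < pop_freq), n_sites, n_ind
      )
      gt <- gt + ifelse(use_phase, phase_allele, random_allele)
    }
    gt[causal_idx, ] <- causal_copies

    dp <- matrix(rpois(n_sites * n_ind, depth_mean), n_sites, n_ind,
      dimnames = list(NULL, samples))
    miss <- matrix(runif(n_sites * n_ind), n_sites, n_ind) < missing_rate
    miss <- miss | dp == 0L
    gt[miss] <- NA_integer_
    storage.mode(gt) <- "integer"

    structure(
      list(
        sites = sites[, c("contig", "pos", "ref", "alt", "qual")],
        gt = gt,
        dp = dp,
        samples = data.frame(sample = samples, morph = morph,
          stringsAsFactors = FALSE),
        truth = list(
          causal_contig = genome$causal_contig,
          causal_pos = genome$causal_pos,
          causal_index = causal_idx,
          causal_genotype = setNames(
            c("aa", "Aa", "AA")[causal_copies + 1L], samples
          )
        )
      ),
      class = "panel"
    )
  })
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf(
    "<panel> %d sites x %d individuals (%d alba, %d orange); %.1f%% missing\n",
    nrow(x$gt), ncol(x$gt),
    sum(x$samples$morph == "alba"), sum(x$samples$morph == "orange"),
    100 * mean(is.na(x$gt))
  ))
  invisible(x)
}
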