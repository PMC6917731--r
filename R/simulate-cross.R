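#' Forward-simulate one informative cross
#'
#' Simulates F1 female offspring of a cross segregating a single autosomal
#' dominant allele `A`. Each offspring receives one maternal and one
#' paternal gamete; at every marker site the gamete copies the allele in
#' phase with the transmitted causal allele with probability `1 - r` and
#' the opposite-phase allele with probability `r` (sites recombine
#' independently given the transmitted causal allele). The morph is Alba
#' if and only if the offspring carries at least one `A` (complete
#' dominance). Offspring are drawn in batches and accepted until both
#' morph quotas (`n_alba_offspring`, `n_orange_offspring`) are filled,
#' mirroring fixed-size morph-sorted pools.
#'
#' Marker polymorphism: each site is "informative" in the cross with
#' probability `genome$informative_fraction`, in which case every
#' heterozygous (`Aa`) parent carries the site's alternate allele on its
#' `A`-bearing haplotype (phase known and recorded in the truth object);
#' homozygous `aa` parents are homozygous reference everywhere. The causal
#' site itself is always informative.
#'
#' @param config a [cross_config()].
#' @param genome a [genome_spec()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return An object of class `cross_sim`: a list with `sites` (marker
#'   table with `contig`, `pos`, `ref`, `alt`, `r`, `informative`),
#'   `maternal`/`paternal` offspring haplotype matrices (offspring x
#'   sites, 0 = reference, 1 = alternate), `causal_copies`, `morph`,
#'   parental haplotypes, and a `truth` list (causal contig/position,
#'   phase, per-offspring causal genotypes) recorded before any
#'   sequencing noise.
#' @examples
#' cs <- simulate_cross(cross_config("male_informative_I", seed = 2),
#'                      genome_spec(n_contigs = 3, sites_per_contig = 5))
#' table(cs$morph)
#' @export
simulate_cross <- function(config, genome, seed = NULL) {
  stopifnot(inherits(config, "cross_config"))
  validate_genome_spec(genome)
  seed <- seed %||% config$seed
  with_seed(seed, {
    sites <- genome$sites
    n_sites <- nrow(sites)
    causal_idx <- which(sites$contig == genome$causal_contig &
      sites$pos == genome$causal_pos)
    stopifnot(length(causal_idx) == 1L)

    sites$ref <- sample(BASES, n_sites, replace = TRUE)
    sites$alt <- vapply(sites$ref, function(b) sample(setdiff(BASES, b), 1L), "")
    sites$informative <- runif(n_sites) < genome$informative_fraction
    sites$informative[causal_idx] <- TRUE

    # rows: haplotype carrying A (for Aa parents), other haplotype
    parent_haps <- function(genotype) {
      h <- matrix(0L, nrow = 2L, ncol = n_sites)
      if (genotype == "Aa") h[1L, sites$informative] <- 1L
      h
    }
    mother <- parent_haps(config$mother_genotype)
    father <- parent_haps(config$father_genotype)

    gametes <- function(haps, genotype, n) {
      if (genotype == "aa") {
        return(list(
          hap = matrix(0L, nrow = n, ncol = n_sites),
          causal = integer(n)
        ))
      }
      # Aa parent: which haplotype carries the transmitted causal allele
      causal <- rbinom(n, 1L, 0.5) # 1 = transmits A
      flip <- matrix(runif(n * n_sites), n, n_sites) <
        matrix(sites$r, n, n_sites, byrow = TRUE)
      from_A_hap <- xor(causal == 1L, flip) # TRUE: copy A-haplotype allele
      hap <- matrix(0L, n, n_sites)
      hap[from_A_hap] <- matrix(haps[1L, ], n, n_sites, byrow = TRUE)[from_A_hap]
      hap[!from_A_hap] <- matrix(haps[2L, ], n, n_sites, byrow = TRUE)[!from_A_hap]
      list(hap = hap, causal = causal)
    }

    quota_alba <- config$n_alba_offspring
    quota_orange <- config$n_orange_offspring
    mat_kept <- pat_kept <- NULL
    copies_kept <- integer(0)
    morph_kept <- character(0)
    batch <- 2L * (quota_alba + quota_orange)
    got_alba <- 0L
    got_orange <- 0L
    for (iter in seq_len(1000L)) {
      gm <- gametes(mother, config$mother_genotype, batch)
      gp <- gametes(father, config$father_genotype, batch)
      copies <- gm$causal + gp$causal
      morph <- ifelse(copies >= 1L, "alba", "orange")
      need <- (morph == "alba" & got_alba + cumsum(morph == "alba") <= quota_alba) |
        (morph == "orange" & got_orange + cumsum(morph == "orange") <= quota_orange)
      mat_kept <- rbind(mat_kept, gm$hap[need, , drop = FALSE])
      pat_kept <- rbind(pat_kept, gp$hap[need, , drop = FALSE])
      copies_kept <- c(copies_kept, copies[need])
      morph_kept <- c(morph_kept, morph[need])
      got_alba <- sum(morph_kept == "alba")
      got_orange <- sum(morph_kept == "orange")
      if (got_alba >= quota_alba && got_orange >= quota_orange) break
    }
    if (got_alba < quota_alba || got_orange < quota_orange) {
      stop_("offspring quotas not filled after 1000 batches (%d alba, %d orange)",
        got_alba, got_orange)
    }

    ord <- order(factor(morph_kept, levels = c("alba", "orange")))
    structure(
      list(
        config = config,
        sites = sites,
        maternal = mat_kept[ord, , drop = FALSE],
        paternal = pat_kept[ord, , drop = FALSE],
        causal_copies = copies_kept[ord],
        morph = morph_kept[ord],
        mother_haplotypes = mother,
        father_haplotypes = father,
        truth = list(
          causal_contig = genome$causal_contig,
          causal_pos = genome$causal_pos,
          causal_index = causal_idx,
          phase = "alternate allele rides the A-bearing haplotype",
          linked_allele = sites$alt,
          informative = sites$informative,
          causal_copies = copies_kept[ord]
        )
      ),
      class = "cross_sim"
    )
  })
}

#' @export
print.cross_sim <- function(x, ...) {
  cat(sprintf(
    "<cross_sim> %s: %d alba + %d orange offspring over %d sites (%d informative)\n",
    x$config$design, sum(x$morph == "alba"), sum(x$morph == "orange"),
    nrow(x$sites), sum(x$sites$informative)
  ))
  invisible(x)
}

#' Pool the haplotypes of a subset of simulated offspring
#'
#' @param cross a [simulate_cross()] result.
#' @param morph `"alba"` or `"orange"`.
#' @return A chromosome x site 0/1 matrix (two rows per individual).
#' @export
pool_haplotypes <- function(cross, morph = c("alba", "orange")) {
  morph <- match.arg(morph)
  keep <- cross$morph == morph
  rbind(cross$maternal[keep, , drop = FALSE], cross$paternal[keep, , drop = FALSE])
}
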