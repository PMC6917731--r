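#' Genome specification for the cross simulator
#'
#' Describes the simulated marker landscape: a set of contigs, marker sites
#' per contig, the causal locus, and the recombination fraction of every
#' site with the causal locus. The default landscape is deliberately
#' contig-grained: all sites on the causal contig are fully linked to the
#' causal locus (r = 0) and sites on all other contigs are unlinked
#' (r = 0.5), which is the resolution at which the contig intersection rule
#' operates. `informative_fraction` is the probability that a site is
#' polymorphic (heterozygous, in phase with the dominant allele) in the
#' segregating parent(s) of a given cross.
#'
#' @param n_contigs number of contigs.
#' @param sites_per_contig marker sites per contig.
#' @param causal_contig 1-based index of the contig carrying the causal
#'   locus (default 3, capped at `n_contigs`).
#' @param causal_site 1-based site index (within the causal contig) of the
#'   causal locus (default 20, capped at `sites_per_contig`).
#' @param informative_fraction probability in `[0, 1]` that a marker site
#'   segregates in a cross.
#' @param r_causal recombination fraction between sites on the causal
#'   contig and the causal locus (0 = complete linkage).
#' @param site_spacing distance in bp between consecutive marker sites.
#' @return An object of class `genome_spec`: a list with the scalar fields
#'   above plus `sites`, a data frame with one row per marker site
#'   (`contig`, `pos`, `r`, `on_causal_contig`).
#' @examples
#' gs <- genome_spec(n_contigs = 4, sites_per_contig = 10, causal_contig = 2)
#' table(gs$sites$r)
#' @export
genome_spec <- function(n_contigs = 10L, sites_per_contig = 40L,
                        causal_contig = min(3L, n_contigs),
                        causal_site = min(20L, sites_per_contig),
                        informative_fraction = 0.3, r_causal = 0,
                        site_spacing = 1000L) {
  stopifnot(
    n_contigs >= 1, sites_per_contig >= 1,
    causal_contig >= 1, causal_contig <= n_contigs,
    causal_site >= 1, causal_site <= sites_per_contig,
    informative_fraction >= 0, informative_fraction <= 1,
    r_causal >= 0, r_causal <= 0.5, site_spacing >= 1
  )
  contigs <- sprintf("contig_%02d", seq_len(n_contigs))
  sites <- data.frame(
    contig = rep(contigs, each = sites_per_contig),
    pos = rep.int(seq_len(sites_per_contig) * site_spacing, n_contigs),
    stringsAsFactors = FALSE
  )
  sites$on_causal_contig <- sites$contig == contigs[causal_contig]
  sites$r <- ifelse(sites$on_causal_contig, r_causal, 0.5)
  structure(
    list(
      n_contigs = as.integer(n_contigs),
      sites_per_contig = as.integer(sites_per_contig),
      contigs = contigs,
      causal_contig = contigs[causal_contig],
      causal_site_index = as.integer(causal_site),
      causal_pos = as.integer(causal_site) * as.integer(site_spacing),
      informative_fraction = informative_fraction,
      sites = sites
    ),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf(
    "<genome_spec> %d contigs x %d sites; causal locus %s:%d; informative fraction %.2f\n",
    x$n_contigs, x$sites_per_contig, x$causal_contig, x$causal_pos,
    x$informative_fraction
  ))
  invisible(x)
}

validate_genome_spec <- function(gs) {
  if (!inherits(gs, "genome_spec")) stop_("not a genome_spec")
  if (any(gs$sites$r < 0 | gs$sites$r > 0.5)) {
    stop_("recombination fractions must lie in [0, 0.5]")
  }
  if (any(gs$sites$r[!gs$sites$on_causal_contig] != 0.5)) {
    stop_("sites on non-causal contigs must be unlinked (r = 0.5)")
  }
  invisible(gs)
}

#' Cross configuration
#'
#' Describes one informative cross for the dominant allele `A`. Three
#' designs are supported, mirroring the three crosses of the mapping
#' design:
#'
#' * `female_informative`: Alba mother `Aa` x father `Aa`; the mother is
#'   sequenced alongside the two morph-sorted F1 female pools.
#' * `male_informative_I`: orange mother `aa` x father `Aa`; the mother is
#'   sequenced.
#' * `male_informative_II`: as above but no parental sample is available.
#'
#' Offspring pools contain females only; since the locus is autosomal all
#' simulated offspring are female. The dominant allele `A` confers the
#' Alba morph in one copy.
#'
#' @param design one of `"female_informative"`, `"male_informative_I"`,
#'   `"male_informative_II"`.
#' @param n_alba_offspring,n_orange_offspring pool sizes (individuals).
#'   Defaults are the design's study pool sizes: 21/21 for the female
#'   informative cross, 26/24 for male informative cross I and 26/28 for
#'   male informative cross II.
#' @param pool_depth_mean mean pooled read depth per site (reads/site).
#'   Defaults: 50 (female informative), 60 (male informative).
#' @param mother_depth_mean mean read depth for the sequenced mother, or
#'   `NULL` when no mother was sequenced (`male_informative_II`).
#' @param seq_error per-base sequencing error probability in `[0, 0.25)`.
#' @param mother_genotype,father_genotype causal-locus genotypes
#'   (`"AA"`, `"Aa"`, `"aa"`); defaults follow `design`. A design that
#'   cannot produce both morphs among offspring (e.g. `aa x aa`, or a
#'   homozygous `AA` parent, which cannot yield orange) is rejected.
#' @param seed integer seed for this cross's generator.
#' @return An object of class `cross_config`.
#' @examples
#' cross_config("female_informative")
#' cross_config("male_informative_II", seed = 7)
#' @export
cross_config <- function(design = c(
                           "female_informative",
                           "male_informative_I",
                           "male_informative_II"
                         ),
                         n_alba_offspring = NULL, n_orange_offspring = NULL,
                         pool_depth_mean = NULL, mother_depth_mean = NULL,
                         seq_error = 0, mother_genotype = NULL,
                         father_genotype = NULL, seed = 1L) {
  design <- match.arg(design)
  defaults <- switch(design,
    female_informative = list(
      n_alba = 21L, n_orange = 21L, depth = 50, mother = "Aa",
      father = "Aa", mother_depth = 40
    ),
    male_informative_I = list(
      n_alba = 26L, n_orange = 24L, depth = 60, mother = "aa",
      father = "Aa", mother_depth = 15
    ),
    male_informative_II = list(
      n_alba = 26L, n_orange = 28L, depth = 60, mother = "aa",
      father = "Aa", mother_depth = NULL
    )
  )
  n_alba <- as.integer(n_alba_offspring %||% defaults$n_alba)
  n_orange <- as.integer(n_orange_offspring %||% defaults$n_orange)
  depth <- pool_depth_mean %||% defaults$depth
  mother_genotype <- mother_genotype %||% defaults$mother
  father_genotype <- father_genotype %||% defaults$father
  mother_depth <- if (design == "male_informative_II") {
    NULL
  } else {
    mother_depth_mean %||% defaults$mother_depth
  }

  check_gt <- function(g, who) {
    if (!g %in% c("AA", "Aa", "aa")) stop_("invalid %s genotype '%s'", who, g)
  }
  check_gt(mother_genotype, "mother")
  check_gt(father_genotype, "father")
  n_A <- function(g) c(AA = 2L, Aa = 1L, aa = 0L)[[g]]
  if (n_A(mother_genotype) + n_A(father_genotype) == 0L) {
    stop_("impossible design: %s x %s cannot yield Alba offspring",
      mother_genotype, father_genotype)
  }
  if (mother_genotype == "AA" || father_genotype == "AA") {
    stop_("impossible design: a homozygous AA parent cannot yield orange offspring")
  }
  if (design == "female_informative" &&
      !(mother_genotype == "Aa" && father_genotype == "Aa")) {
    stop_("female informative design requires mother Aa and father Aa")
  }
  if (design != "female_informative" &&
      !(father_genotype == "Aa" && mother_genotype == "aa")) {
    stop_("male informative designs require father Aa and mother aa")
  }
  stopifnot(
    n_alba >= 1, n_orange >= 1, depth > 0,
    seq_error >= 0, seq_error < 0.25,
    is.null(mother_depth) || mother_depth > 0
  )
  structure(
    list(
      design = design,
      mother_genotype = mother_genotype,
      father_genotype = father_genotype,
      n_alba_offspring = n_alba,
      n_orange_offspring = n_orange,
      pool_depth_mean = depth,
      mother_depth_mean = mother_depth,
      seq_error = seq_error,
      seed = as.integer(seed)
    ),
    class = "cross_config"
  )
}

#' @export
print.cross_config <- function(x, ...) {
  cat(sprintf(
    "<cross_config> %s: mother %s x father %s; pools %d Alba / %d orange; depth %g%s; error %g\n",
    x$design, x$mother_genotype, x$father_genotype,
    x$n_alba_offspring, x$n_orange_offspring, x$pool_depth_mean,
    if (is.null(x$mother_depth_mean)) "" else sprintf(" (mother %g)", x$mother_depth_mean),
    x$seq_error
  ))
  invisible(x)
}
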