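#' Per-base allele frequencies from sync counts
#'
#' Frequencies over the four nucleotides after removing the `N` and `del`
#' fields (indel counts are retained in the sync format but treated as
#' non-allelic). A site with zero usable depth yields `NA` frequencies.
#'
#' @param counts numeric vector of counts named with at least
#'   `A, T, C, G` (sync order `A,T,C,G,N,del` accepted).
#' @return Named numeric vector of frequencies over `A, T, C, G`,
#'   summing to 1, or all-`NA` when no usable depth remains.
#' @examples
#' allele_frequencies(c(A = 10, T = 0, C = 10, G = 0, N = 0, del = 2))
#' @export
allele_frequencies <- function(counts) {
  x <- counts[BASES]
  names(x) <- BASES
  x[is.na(x)] <- 0
  d <- sum(x)
  if (d <= 0) {
    return(setNames(rep(NA_real_, 4L), BASES))
  }
  x / d
}

#' Allele-frequency difference between two pools
#'
#' The maximum over the four nucleotides of the absolute frequency
#' difference between the Alba and orange pools. For a bi-allelic site
#' this equals the major/minor allele-frequency difference reported by
#' Popoolation2, and it remains well defined when a third allele leaks
#' in. Symmetric, bounded in `[0, 1]`, zero iff the frequency vectors are
#' identical.
#'
#' @param alba,orange count vectors as in [allele_frequencies()].
#' @return A single number in `[0, 1]`, or `NA` if either pool has no
#'   usable depth.
#' @examples
#' pool_diff(c(A = 30, T = 0, C = 15, G = 0), c(A = 0, T = 0, C = 40, G = 0))
#' @export
pool_diff <- function(alba, orange) {
  fa <- allele_frequencies(alba)
  fo <- allele_frequencies(orange)
  if (anyNA(fa) || anyNA(fo)) {
    return(NA_real_)
  }
  max(abs(fa - fo))
}

#' Per-cross filter thresholds
#'
#' The printed filter windows of the three informative crosses:
#'
#' * `female_informative`: pool depth 20-90, mother depth 15-60, mother
#'   heterozygous (allele frequency between 0.4 and 0.6), orange pool
#'   homozygous, Alba/orange allele-frequency difference in
#'   `[0.4, 0.8]`, and the same nucleotide change in the Alba pool and
#'   the Alba mother.
#' * `male_informative_I`: pool depth 30-300, minimum minor-allele count
#'   3, mother depth 5-30, mother homozygous, orange pool homozygous,
#'   difference in `[0.45, 0.55]`.
#' * `male_informative_II`: pool depth 20-300, minimum minor-allele count
#'   3, no mother, orange pool homozygous, difference in `[0.45, 0.55]`.
#'
#' All intervals are closed (a difference of exactly 0.45 or 0.55
#' passes). "Homozygous" means a minor-allele frequency of at most
#' `hom_tol`; the default 0 demands the major allele at 100% frequency,
#' and a small positive value can be supplied where sequencing error
#' would make that brittle at high depth.
#'
#' @param design cross design name.
#' @param hom_tol homozygosity tolerance (minor-allele frequency).
#' @return A list of class `cross_thresholds`.
#' @export
cross_thresholds <- function(design = c(
                               "female_informative",
                               "male_informative_I",
                               "male_informative_II"
                             ), hom_tol = 0) {
  design <- match.arg(design)
  th <- switch(design,
    female_informative = list(
      pool_depth = c(20, 90), mother_depth = c(15, 60),
      mother_rule = "het", mother_het_band = c(0.4, 0.6),
      diff_band = c(0.4, 0.8), min_minor_count = 0L,
      require_same_change = TRUE
    ),
    male_informative_I = list(
      pool_depth = c(30, 300), mother_depth = c(5, 30),
      mother_rule = "hom", mother_het_band = c(0.4, 0.6),
      diff_band = c(0.45, 0.55), min_minor_count = 3L,
      require_same_change = FALSE
    ),
    male_informative_II = list(
      pool_depth = c(20, 300), mother_depth = NULL,
      mother_rule = "none", mother_het_band = c(0.4, 0.6),
      diff_band = c(0.45, 0.55), min_minor_count = 3L,
      require_same_change = FALSE
    )
  )
  th$design <- design
  th$hom_tol <- hom_tol
  stopifnot(
    th$pool_depth[1] < th$pool_depth[2],
    is.null(th$mother_depth) || th$mother_depth[1] < th$mother_depth[2],
    all(th$diff_band >= 0 & th$diff_band <= 1)
  )
  class(th) <- "cross_thresholds"
  th
}

# columns in deterministic tie-break order A < C < G < T
.usable <- function(m) {
  out <- m[, c("A", "C", "G", "T"), drop = FALSE]
  storage.mode(out) <- "double"
  out
}

.row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

# Vectorized criteria engine shared by bsa_verdicts() and the per-site
# filter_* wrappers. mother may be NULL.
.bsa_criteria <- function(sites, alba, orange, mother, th) {
  n <- nrow(sites)
  ua <- .usable(alba)
  uo <- .usable(orange)
  um <- if (!is.null(mother)) .usable(mother) else NULL

  d_alba <- rowSums(ua)
  d_orange <- rowSums(uo)
  d_mother <- if (!is.null(um)) rowSums(um) else rep(NA_real_, n)

  depth_ok <- d_alba >= th$pool_depth[1] & d_alba <= th$pool_depth[2] &
    d_orange >= th$pool_depth[1] & d_orange <= th$pool_depth[2]
  if (th$mother_rule != "none") {
    if (is.null(um)) stop_("the %s design requires a mother column", th$design)
    depth_ok <- depth_ok &
      d_mother >= th$mother_depth[1] & d_mother <= th$mother_depth[2]
  }

  joint <- ua + uo
  if (!is.null(um)) joint <- joint + um
  n_alleles <- rowSums(joint > 0)
  biallelic <- n_alleles == 2L

  pooled <- ua + uo
  minor_count <- rowSums(pooled) - .row_max(pooled)
  minor_ok <- minor_count >= th$min_minor_count

  safe_freq <- function(m, d) m / ifelse(d > 0, d, NA_real_)
  fa <- safe_freq(ua, d_alba)
  fo <- safe_freq(uo, d_orange)
  usable <- d_alba > 0 & d_orange > 0

  diff <- rep(NA_real_, n)
  diff[usable] <- do.call(pmax, lapply(1:4, function(j) {
    abs(fa[usable, j] - fo[usable, j])
  }))
  diff_in_band <- !is.na(diff) &
    diff >= th$diff_band[1] & diff <= th$diff_band[2]

  orange_major_f <- .row_max(fo)
  orange_hom <- !is.na(orange_major_f) & (1 - orange_major_f) <= th$hom_tol

  mother_het <- mother_hom <- rep(NA, n)
  if (!is.null(um)) {
    fm <- safe_freq(um, d_mother)
    m_major_f <- .row_max(fm)
    mother_het <- !is.na(m_major_f) &
      m_major_f >= th$mother_het_band[1] & m_major_f <= th$mother_het_band[2] |
      (!is.na(m_major_f) &
        (1 - m_major_f) >= th$mother_het_band[1] &
        (1 - m_major_f) <= th$mother_het_band[2])
    mother_hom <- !is.na(m_major_f) & (1 - m_major_f) <= th$hom_tol
  }
  # criteria not used by this design are reported as NA, not FALSE
  if (th$mother_rule != "het") mother_het <- rep(NA, n)
  if (th$mother_rule != "hom") mother_hom <- rep(NA, n)

  same_change <- rep(NA, n)
  if (isTRUE(th$require_same_change)) {
    if (is.null(um)) stop_("same-change criterion requires a mother column")
    o_major <- max.col(uo, ties.method = "first")
    first_al <- max.col(joint > 0, ties.method = "first")
    last_al <- max.col(joint > 0, ties.method = "last")
    other <- ifelse(first_al == o_major, last_al, first_al)
    idx <- cbind(seq_len(n), other)
    same_change <- ua[idx] > 0 & um[idx] > 0
  }

  verdict <- depth_ok & biallelic & minor_ok & orange_hom & diff_in_band
  if (th$mother_rule == "het") verdict <- verdict & mother_het
  if (th$mother_rule == "hom") verdict <- verdict & mother_hom
  if (isTRUE(th$require_same_change)) verdict <- verdict & same_change
  verdict[is.na(verdict)] <- FALSE

  out <- data.frame(
    contig = sites$contig, pos = sites$pos,
    depth_alba = d_alba, depth_orange = d_orange, depth_mother = d_mother,
    depth_ok = depth_ok, biallelic = biallelic,
    minor_count = minor_count, minor_count_ok = minor_ok,
    mother_het = mother_het, mother_hom = mother_hom,
    orange_hom = orange_hom, diff = diff, diff_in_band = diff_in_band,
    same_change = same_change,
    is_alba_snp = verdict,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Apply a cross's SNP criteria to a sync table
#'
#' Evaluates every per-site criterion of the given cross design on a sync
#' table and returns one row per site with the individual criterion
#' outcomes and the final verdict (`is_alba_snp` is the conjunction of
#' all criteria applicable to the design). Bi-allelic state is assessed
#' jointly on the pooled counts of all available columns (both pools,
#' plus the mother where present) after removing `N`/indel counts; sites
#' with zero usable depth in either pool are never called.
#'
#' @param sync a [sync_table()] whose columns include those named in
#'   `pools`.
#' @param design cross design, see [cross_thresholds()].
#' @param thresholds a [cross_thresholds()] object; defaults to the
#'   design's printed windows.
#' @param pools named character vector mapping the roles `alba`,
#'   `orange` (and `mother` when the design uses one) to sync column
#'   names.
#' @return Data frame of per-site verdicts.
#' @examples
#' gs <- genome_spec(n_contigs = 2, sites_per_contig = 5)
#' cs <- simulate_cross(cross_config("female_informative", seed = 3), gs)
#' v <- bsa_verdicts(simulate_cross_pools(cs), "female_informative")
#' table(v$is_alba_snp)
#' @export
bsa_verdicts <- function(sync, design, thresholds = cross_thresholds(design),
                         pools = c(
                           alba = "alba", orange = "orange",
                           mother = "mother"
                         )) {
  stopifnot(inherits(sync, "sync_table"), inherits(thresholds, "cross_thresholds"))
  get_pool <- function(role, required) {
    nm <- pools[[role]]
    if (is.null(nm) || !nm %in% names(sync$pools)) {
      if (required) stop_("sync table has no '%s' column for role '%s'", nm, role)
      return(NULL)
    }
    sync$pools[[nm]]
  }
  mother_required <- thresholds$mother_rule != "none"
  .bsa_criteria(
    sync$sites,
    get_pool("alba", TRUE),
    get_pool("orange", TRUE),
    get_pool("mother", mother_required),
    thresholds
  )
}

.single_site <- function(counts) {
  m <- matrix(0, nrow = 1L, ncol = 6L, dimnames = list(NULL, SYNC_FIELDS))
  common <- intersect(names(counts), SYNC_FIELDS)
  if (length(common) == 0L) stop_("counts must be named with sync fields (A,T,C,G,N,del)")
  m[1L, common] <- as.numeric(counts[common])
  m
}

.verdict_list <- function(v) {
  out <- as.list(v[1L, setdiff(names(v), c("contig", "pos"))])
  class(out) <- "snp_verdict"
  out
}

#' @export
print.snp_verdict <- function(x, ...) {
  crit <- vapply(x, function(e) {
    if (is.logical(e)) {
      if (is.na(e)) "n/a" else c("FAIL", "pass")[e + 1L]
    } else {
      format(e, digits = 4)
    }
  }, "")
  cat("<snp_verdict>", if (isTRUE(x$is_alba_snp)) "ALBA SNP" else "not an Alba SNP", "\n")
  for (nm in names(crit)) cat(sprintf("  %-15s %s\n", nm, crit[nm]))
  invisible(x)
}

#' Single-site filters for the three cross designs
#'
#' Convenience wrappers applying one cross's criteria to a single site
#' given named count vectors (sync field names). See [bsa_verdicts()]
#' for the vectorized form and [cross_thresholds()] for the criteria.
#'
#' @param mother,alba_pool,orange_pool named count vectors
#'   (`A`, `T`, `C`, `G`, optionally `N`, `del`).
#' @param th thresholds for the design.
#' @return A `snp_verdict` list: per-criterion logicals, the pool
#'   frequency difference, and `is_alba_snp`.
#' @examples
#' filter_female_informative(
#'   mother = c(A = 15, C = 15), alba_pool = c(A = 30, C = 15),
#'   orange_pool = c(C = 40)
#' )
#' @export
filter_female_informative <- function(mother, alba_pool, orange_pool,
                                      th = cross_thresholds("female_informative")) {
  sites <- data.frame(contig = "site", pos = 1L, stringsAsFactors = FALSE)
  .verdict_list(.bsa_criteria(
    sites, .single_site(alba_pool), .single_site(orange_pool),
    .single_site(mother), th
  ))
}

#' @rdname filter_female_informative
#' @export
filter_male_informative_I <- function(mother, alba_pool, orange_pool,
                                      th = cross_thresholds("male_informative_I")) {
  sites <- data.frame(contig = "site", pos = 1L, stringsAsFactors = FALSE)
  .verdict_list(.bsa_criteria(
    sites, .single_site(alba_pool), .single_site(orange_pool),
    .single_site(mother), th
  ))
}

#' @rdname filter_female_informative
#' @export
filter_male_informative_II <- function(alba_pool, orange_pool,
                                       th = cross_thresholds("male_informative_II")) {
  sites <- data.frame(contig = "site", pos = 1L, stringsAsFactors = FALSE)
  .verdict_list(.bsa_criteria(
    sites, .single_site(alba_pool), .single_site(orange_pool), NULL, th
  ))
}

#' Mask sites in the neighbourhood of indels
#'
#' Removes sites within `window` bp of any identified indel position
#' (on the same contig), the standard guard against alignment artefacts
#' around indels before SNP filtering.
#'
#' @param sites a [sync_table()] or a data frame with `contig`, `pos`.
#' @param indel_positions data frame with `contig`, `pos` of indels.
#' @param window non-negative mask radius in bp (0 masks only the indel
#'   site itself; default 5).
#' @return The input with masked sites removed (same class).
#' @export
mask_indel_neighborhood <- function(sites, indel_positions, window = 5L) {
  stopifnot(window >= 0)
  site_df <- if (inherits(sites, "sync_table")) sites$sites else sites
  masked <- rep(FALSE, nrow(site_df))
  for (i in seq_len(NROW(indel_positions))) {
    masked <- masked | (
      site_df$contig == indel_positions$contig[i] &
        abs(site_df$pos - indel_positions$pos[i]) <= window
    )
  }
  if (inherits(sites, "sync_table")) {
    sync_table(
      sites$sites[!masked, , drop = FALSE],
      lapply(sites$pools, function(m) m[!masked, , drop = FALSE])
    )
  } else {
    sites[!masked, , drop = FALSE]
  }
}

#' Contig-level intersection of per-cross SNP verdicts
#'
#' A contig is called trait-associated when it carries at least
#' `min_snps` passing SNPs in every cross independently.
#'
#' @param verdicts named list of verdict data frames (one per cross,
#'   from [bsa_verdicts()]), sharing a contig namespace.
#' @param min_snps minimum passing SNPs per cross (default 3).
#' @param contigs optional character vector of all contigs to report
#'   (defaults to the union observed across crosses).
#' @return Data frame with `contig`, one `n_<cross>` count column per
#'   cross, and `associated`.
#' @examples
#' v <- data.frame(contig = c("c1", "c1", "c1", "c2"),
#'                 is_alba_snp = c(TRUE, TRUE, TRUE, TRUE))
#' call_contigs(list(f = v, m1 = v, m2 = v))
#' @export
call_contigs <- function(verdicts, min_snps = 3L, contigs = NULL) {
  stopifnot(is.list(verdicts), length(verdicts) >= 1)
  if (is.null(names(verdicts)) || any(!nzchar(names(verdicts)))) {
    names(verdicts) <- sprintf("cross%d", seq_along(verdicts))
  }
  contigs <- contigs %||%
    sort(unique(unlist(lapply(verdicts, function(v) unique(v$contig)))))
  counts <- vapply(verdicts, function(v) {
    tab <- tapply(v$is_alba_snp, v$contig, sum)
    n <- tab[match(contigs, names(tab))]
    n[is.na(n)] <- 0
    as.integer(n)
  }, integer(length(contigs)))
  if (length(contigs) == 1L) counts <- matrix(counts, nrow = 1L)
  colnames(counts) <- paste0("n_", names(verdicts))
  out <- data.frame(contig = contigs, counts, stringsAsFactors = FALSE)
  out$associated <- apply(counts >= min_snps, 1L, all)
  out
}
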