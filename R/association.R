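#' Site filters for the re-sequencing panel
#'
#' Keeps sites with at most `max_missing` missing genotypes, a mean read
#' depth across individuals within `depth_range`, and a site quality of
#' at least `min_qual`. All bounds are inclusive.
#'
#' @param panel a `panel` object ([simulate_panel()] or
#'   [read_panel_vcf()]).
#' @param max_missing maximum fraction of missing genotypes (default
#'   0.5).
#' @param depth_range inclusive mean-depth window (default `c(15, 50)`).
#' @param min_qual minimum site quality (default 30).
#' @return The panel restricted to kept sites, with a logical attribute
#'   `kept` recording the per-site decision.
#' @export
filter_panel_sites <- function(panel, max_missing = 0.5,
                               depth_range = c(15, 50), min_qual = 30) {
  stopifnot(inherits(panel, "panel"))
  miss <- rowMeans(is.na(panel$gt))
  mean_dp <- rowMeans(panel$dp)
  keep <- miss <= max_missing &
    mean_dp >= depth_range[1] & mean_dp <= depth_range[2] &
    panel$sites$qual >= min_qual
  out <- panel
  out$sites <- panel$sites[keep, , drop = FALSE]
  out$gt <- panel$gt[keep, , drop = FALSE]
  out$dp <- panel$dp[keep, , drop = FALSE]
  attr(out, "kept") <- keep
  out
}

#' Allelic case/control association test at one site
#'
#' Builds the 2x2 allele-count table (case/control x alternate/reference
#' allele, two alleles per non-missing individual) and returns a
#' two-sided p-value. The default is Fisher's exact test (two-sided by
#' summation of table probabilities no larger than the observed one);
#' a 1-df allelic chi-square without continuity correction is available
#' via `method = "chisq"`. A site monomorphic across the non-missing
#' individuals returns p = 1 by convention.
#'
#' @param case_gt,control_gt integer vectors of alternate-allele copies
#'   (0/1/2, `NA` = missing) for case and control individuals.
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return List with `table` (2x2 allele counts) and `p`.
#' @examples
#' allelic_test(c(1L, 2L, 1L), c(0L, 0L, 0L))
#' @export
allelic_test <- function(case_gt, control_gt, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  case_gt <- case_gt[!is.na(case_gt)]
  control_gt <- control_gt[!is.na(control_gt)]
  if (length(case_gt) < 1L || length(control_gt) < 1L) {
    stop_("both groups need at least one non-missing genotype")
  }
  stopifnot(all(case_gt %in% 0:2), all(control_gt %in% 0:2))
  tab <- matrix(
    c(
      sum(case_gt), 2L * length(case_gt) - sum(case_gt),
      sum(control_gt), 2L * length(control_gt) - sum(control_gt)
    ),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("case", "control"), c("alt", "ref"))
  )
  p <- if (any(colSums(tab) == 0L)) {
    1
  } else if (method == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  list(table = tab, p = min(1, p))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q[i] = min over j with p[(j)] >= p[(i)] of m * p[(j)] / j`, mapped
#' back to input order. Monotone in p and invariant to input ordering.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) {
    return(numeric(0))
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Case/control association across a panel
#'
#' Applies [allelic_test()] to every site of a (filtered) panel, adjusts
#' the p-values with [bh_fdr()], and flags sites with q below
#' `fdr_level` as significant.
#'
#' @param panel a `panel` object with morph labels in `panel$samples`
#'   (`"alba"` = case, `"orange"` = control).
#' @param method test passed to [allelic_test()].
#' @param fdr_level FDR significance level (default 0.05).
#' @return Data frame sorted by q: `contig`, `pos`, allele counts
#'   (`case_alt`, `case_ref`, `control_alt`, `control_ref`), `p`, `q`,
#'   `significant`.
#' @examples
#' p <- simulate_panel(genome_spec(n_contigs = 2, sites_per_contig = 6),
#'                     n_alba = 8, n_orange = 8, seed = 5)
#' head(associate_panel(filter_panel_sites(p)))
#' @export
associate_panel <- function(panel, method = c("fisher", "chisq"),
                            fdr_level = 0.05) {
  stopifnot(inherits(panel, "panel"))
  method <- match.arg(method)
  morph <- panel$samples$morph
  if (anyNA(morph)) stop_("panel has samples without morph labels")
  case <- morph == "alba"
  if (!any(case) || !all(case | morph == "orange")) {
    stop_("morph labels must be 'alba' (case) or 'orange' (control), both present")
  }
  res <- lapply(seq_len(nrow(panel$gt)), function(i) {
    at <- allelic_test(panel$gt[i, case], panel$gt[i, !case], method)
    c(at$table["case", "alt"], at$table["case", "ref"],
      at$table["control", "alt"], at$table["control", "ref"], at$p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    contig = panel$sites$contig,
    pos = panel$sites$pos,
    case_alt = as.integer(res[, 1]), case_ref = as.integer(res[, 2]),
    control_alt = as.integer(res[, 3]), control_ref = as.integer(res[, 4]),
    p = res[, 5],
    stringsAsFactors = FALSE
  )
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr_level
  out[order(out$q, out$p, out$contig, out$pos), , drop = FALSE]
}
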