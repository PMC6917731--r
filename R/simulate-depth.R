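#' Default insertion/flanking window definitions
#'
#' Two equal-length windows on a single contig: the insertion itself and
#' a nearby conserved flanking region. Coordinates are 1-based inclusive
#' (the package-internal convention; see [read_bed()] for the BED
#' boundary conversion).
#'
#' @param contig contig name.
#' @param insertion_start 1-based first base of the insertion window.
#' @param insertion_length insertion length in bp.
#' @param gap distance between insertion end and flanking window start.
#' @return Data frame with `contig`, `start`, `end`, `label`.
#' @export
insertion_windows <- function(contig = "contig_03", insertion_start = 10001L,
                              insertion_length = 3000L, gap = 2000L) {
  stopifnot(insertion_length > 0, gap >= 0, insertion_start >= 1)
  data.frame(
    contig = contig,
    start = c(insertion_start, insertion_start + insertion_length + gap),
    end = c(
      insertion_start + insertion_length - 1L,
      insertion_start + 2L * insertion_length + gap - 1L
    ),
    label = c("insertion", "flanking"),
    stringsAsFactors = FALSE
  )
}

#' Simulate windowed read depth for insertion genotyping
#'
#' For each individual, mean read depth in the flanking conserved window
#' is Poisson around `baseline_depth`, while depth inside the insertion
#' window scales with the number of insertion-bearing chromosomes:
#' expected inside/flanking ratios of 1.0, 0.5 and 0 for `AA`, `Aa` and
#' `aa` (reads from an insertion-free chromosome cannot map inside the
#' insertion). Noise is Poisson at the per-base level, so longer windows
#' give tighter window means.
#'
#' @param genotypes character vector of insertion genotypes
#'   (`"AA"`, `"Aa"`, `"aa"`), optionally named by individual.
#' @param baseline_depth expected read depth in the flanking window.
#' @param window_defs window table as from [insertion_windows()]; must
#'   contain one `insertion` and one `flanking` row.
#' @param seed integer seed or `NULL`.
#' @return Data frame with one row per individual per window:
#'   `individual`, `contig`, `start`, `end`, `label`, `mean_depth`.
#' @examples
#' simulate_depth_windows(c(a = "AA", b = "Aa", c = "aa"), 30, seed = 1)
#' @export
simulate_depth_windows <- function(genotypes, baseline_depth = 30,
                                   window_defs = insertion_windows(),
                                   seed = NULL) {
  stopifnot(
    all(genotypes %in% c("AA", "Aa", "aa")),
    baseline_depth > 0,
    all(c("insertion", "flanking") %in% window_defs$label),
    all(window_defs$start <= window_defs$end)
  )
  ids <- names(genotypes) %||% sprintf("ind_%03d", seq_along(genotypes))
  mult <- c(AA = 1, Aa = 0.5, aa = 0)[genotypes]
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(window_defs)), function(w) {
      len <- window_defs$end[w] - window_defs$start[w] + 1L
      m <- if (window_defs$label[w] == "insertion") mult else rep(1, length(mult))
      data.frame(
        individual = ids,
        contig = window_defs$contig[w],
        start = window_defs$start[w],
        end = window_defs$end[w],
        label = window_defs$label[w],
        mean_depth = rpois(length(ids), len * baseline_depth * m) / len,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
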