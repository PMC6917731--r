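#' Within-insertion to flanking depth ratio
#'
#' The ratio of mean read depth inside a presence/absence insertion to
#' the mean depth of a nearby conserved flanking region. Individuals
#' homozygous for the insertion show a ratio near 1, heterozygotes near
#' 0.5 (about half the flanking depth) and insertion-free individuals
#' near 0.
#'
#' @param inside mean depth (or per-base depths) within the insertion.
#' @param flanking mean depth (or per-base depths) in the flanking
#'   conserved region; must be positive.
#' @return A single non-negative ratio.
#' @examples
#' depth_ratio(15, 30)
#' @export
depth_ratio <- function(inside, flanking) {
  fl <- mean(flanking)
  if (!is.finite(fl) || fl <= 0) {
    stop_("flanking depth must be positive; individual is unclassifiable")
  }
  mean(inside) / fl
}

#' Classify an insertion genotype from a depth ratio
#'
#' Thresholds default to 0.2 and 0.75, placed between the expected
#' ratios (0, 0.5, 1) with margin for Poisson depth noise:
#' `aa` if `r < t_low`, `Aa` if `t_low <= r < t_high`, `AA` if
#' `r >= t_high`.
#'
#' @param r depth ratio(s) from [depth_ratio()].
#' @param t_low,t_high class boundaries.
#' @return Character vector of genotype classes.
#' @examples
#' classify_insertion(c(0.02, 0.48, 0.97))
#' @export
classify_insertion <- function(r, t_low = 0.2, t_high = 0.75) {
  stopifnot(t_low >= 0, t_low < t_high)
  ifelse(r < t_low, "aa", ifelse(r < t_high, "Aa", "AA"))
}

#' Genotype individuals from a windowed depth table
#'
#' Joins each individual's insertion and flanking window depths,
#' computes the depth ratio and classifies the insertion genotype.
#' Individuals whose flanking depth is below `min_flanking_depth` are
#' reported as unclassifiable (`NA` class) rather than given an
#' unstable ratio.
#'
#' @param depth_table data frame from [simulate_depth_windows()] or
#'   [read_depth_table()] (`individual`, `label`, `mean_depth`).
#' @param t_low,t_high thresholds for [classify_insertion()].
#' @param min_flanking_depth minimum usable flanking depth (default 5).
#' @return Data frame with `individual`, `depth_insertion`,
#'   `depth_flanking`, `ratio`, `class`.
#' @export
genotype_insertions <- function(depth_table, t_low = 0.2, t_high = 0.75,
                                min_flanking_depth = 5) {
  stopifnot(all(c("individual", "label", "mean_depth") %in% names(depth_table)))
  ins <- depth_table[depth_table$label == "insertion", ]
  fl <- depth_table[depth_table$label == "flanking", ]
  ids <- sort(unique(depth_table$individual))
  di <- tapply(ins$mean_depth, ins$individual, mean)[ids]
  df <- tapply(fl$mean_depth, fl$individual, mean)[ids]
  if (anyNA(di) || anyNA(df)) {
    stop_("every individual needs both an insertion and a flanking window")
  }
  ratio <- ifelse(df > 0, di / df, NA_real_)
  usable <- df >= min_flanking_depth
  cls <- rep(NA_character_, length(ids))
  cls[usable] <- classify_insertion(ratio[usable], t_low, t_high)
  data.frame(
    individual = ids,
    depth_insertion = as.numeric(di),
    depth_flanking = as.numeric(df),
    ratio = as.numeric(ratio),
    class = cls,
    stringsAsFactors = FALSE
  )
}

#' Does a read pair map properly across an insertion junction?
#'
#' Models the proper-pair criterion of an aligner with a maximum
#' allowed insert size. A fragment that does not cross the junction is
#' always proper. A fragment crossing the junction has its apparent
#' length grown by `insertion_length` when its source haplotype and the
#' mapping haplotype disagree about the insertion (an insertion-free
#' fragment mapped onto the insertion-bearing haplotype, or vice versa);
#' it maps properly iff the apparent length is at most `max_insert`.
#'
#' @param fragment_start leftmost coordinate of the fragment on its
#'   source haplotype.
#' @param fragment_length true fragment length in bp.
#' @param junction junction coordinate (insertion point).
#' @param target_has_insertion does the mapping target carry the
#'   insertion where the source does not (or vice versa)? `TRUE` adds
#'   `insertion_length` to the apparent fragment length.
#' @param insertion_length insertion length in bp.
#' @param max_insert maximum proper insert size (default 1000 bp).
#' @return Logical: does the pair map as a proper pair?
#' @examples
#' spans_properly(100, 350, 300, target_has_insertion = FALSE)
#' spans_properly(100, 350, 300, target_has_insertion = TRUE,
#'                insertion_length = 3000) # 3350 > 1000 -> improper
#' @export
spans_properly <- function(fragment_start, fragment_length, junction,
                           target_has_insertion, insertion_length = 3000,
                           max_insert = 1000) {
  stopifnot(fragment_length > 0, max_insert > 0, insertion_length >= 0)
  crosses <- fragment_start < junction &
    (fragment_start + fragment_length) > junction
  apparent <- fragment_length +
    ifelse(crosses & target_has_insertion, insertion_length, 0)
  !crosses | apparent <= max_insert
}
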