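#' Read and write window definitions in BED format
#'
#' BED is 0-based, half-open; the package-internal convention is 1-based,
#' inclusive (matching sync/VCF positions). `read_bed` converts at the
#' boundary (`start + 1`, `end` unchanged); `write_bed` inverts the
#' conversion. The optional fourth BED column becomes the window `label`.
#'
#' @param path file path (gzip accepted on read).
#' @return `read_bed`: data frame with `contig`, `start`, `end` (1-based
#'   inclusive) and `label`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("ctg1\t0\t100\tinsertion", f)
#' read_bed(f) # start 1, end 100
#' @export
read_bed <- function(path) {
  df <- utils::read.table(gzfile(path), sep = "\t", header = FALSE,
    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop_("BED file must have at least 3 columns")
  out <- data.frame(
    contig = as.character(df[[1L]]),
    start = as.integer(df[[2L]]) + 1L,
    end = as.integer(df[[3L]]),
    label = if (ncol(df) >= 4L) as.character(df[[4L]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end)) {
    stop_("BED interval with start >= end at row %d", which(out$start > out$end)[1L])
  }
  out
}

#' @param windows window data frame (1-based inclusive coordinates).
#' @rdname read_bed
#' @export
write_bed <- function(windows, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(windows)))
  df <- data.frame(
    windows$contig, windows$start - 1L, windows$end,
    if (!is.null(windows$label)) windows$label else ".",
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a tab-separated table with a header
#'
#' Plain TSV with a header row, no quoting, no row names; the format used
#' for verdicts, measurement tables and reports.
#'
#' @param df data frame.
#' @param path file path (gzip accepted on read).
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(gzfile(path), sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Mean read depth per individual per window
#'
#' Accepts either a per-window table (columns `individual`, `label`,
#' `mean_depth`, as written by [simulate_depth_windows()]) which is
#' validated and returned, or a per-base depth table (columns `contig`,
#' `pos` 1-based, `individual`, `depth`) which is averaged over each
#' window. A window containing no bases is an error.
#'
#' @param path TSV path.
#' @param windows window definitions (1-based inclusive), e.g. from
#'   [read_bed()] or [insertion_windows()].
#' @return Data frame with `individual`, `contig`, `start`, `end`,
#'   `label`, `mean_depth`.
#' @export
read_depth_table <- function(path, windows) {
  df <- read_tsv(path)
  stopifnot(all(c("contig", "start", "end", "label") %in% names(windows)))
  if (all(c("individual", "label", "mean_depth") %in% names(df))) {
    keep <- df$label %in% windows$label
    return(df[keep, , drop = FALSE])
  }
  if (!all(c("contig", "pos", "individual", "depth") %in% names(df))) {
    stop_("depth table must have columns individual/label/mean_depth or contig/pos/individual/depth")
  }
  rows <- lapply(seq_len(nrow(windows)), function(w) {
    sel <- df$contig == windows$contig[w] &
      df$pos >= windows$start[w] & df$pos <= windows$end[w]
    if (!any(sel)) {
      stop_("window %s:%d-%d (%s) contains no bases in the depth table",
        windows$contig[w], windows$start[w], windows$end[w], windows$label[w])
    }
    agg <- tapply(df$depth[sel], df$individual[sel], mean)
    data.frame(
      individual = names(agg),
      contig = windows$contig[w],
      start = windows$start[w],
      end = windows$end[w],
      label = windows$label[w],
      mean_depth = as.numeric(agg),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a panel as VCF 4.2
#'
#' Emits the subset of VCF consumed by the association stage: CHROM, POS,
#' REF, ALT, QUAL and per-sample `GT:DP`. Genotypes are unphased
#' (`0/0`, `0/1`, `1/1`, `./.` for missing).
#'
#' @param panel a [simulate_panel()] result (or compatible list with
#'   `sites`, `gt`, `dp`, `samples`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  s <- panel$sites
  gt_code <- c("0/0", "0/1", "1/1")
  fmt <- matrix("./.", nrow = nrow(panel$gt), ncol = ncol(panel$gt))
  ok <- !is.na(panel$gt)
  fmt[ok] <- gt_code[panel$gt[ok] + 1L]
  fmt[] <- paste(fmt, ifelse(is.na(panel$dp), 0L, panel$dp), sep = ":")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=albamap",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", colnames(panel$gt)
    ), collapse = "\t")
  )
  body <- do.call(paste, c(
    list(
      s$contig, s$pos, ".", s$ref, s$alt, s$qual, "PASS", ".", "GT:DP"
    ),
    lapply(seq_len(ncol(fmt)), function(j) fmt[, j]),
    sep = "\t"
  ))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a VCF into a panel object
#'
#' Parses a VCF 4.2 file (via the vcfR package) keeping CHROM, POS, REF,
#' ALT, QUAL and the GT/DP fields; multi-allelic records are rejected.
#' Morph labels can be supplied as a data frame (`sample`, `morph`); when
#' absent they must be attached before association testing.
#'
#' @param path VCF path (gzip accepted).
#' @param phenotypes optional data frame with columns `sample`, `morph`
#'   (`"alba"` = case, `"orange"` = control).
#' @return A `panel` object (see [simulate_panel()]) with `truth = NULL`.
#' @export
read_panel_vcf <- function(path, phenotypes = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
    dimnames = dimnames(vcfR::getFIX(v)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop_("multi-allelic VCF records are not supported")
  }
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_integer_,
      vapply(strsplit(gsub("\\|", "/", g), "/", fixed = FALSE), function(p) {
        sum(p == "1")
      }, integer(1)))
  }
  gt <- apply(gt_chr, 2L, count_alt)
  gt <- matrix(as.integer(gt), nrow = nrow(gt_chr),
    dimnames = dimnames(gt_chr))
  samples <- colnames(gt)
  pheno <- phenotypes
  if (!is.null(pheno)) {
    stopifnot(all(c("sample", "morph") %in% names(pheno)))
    pheno <- pheno[match(samples, pheno$sample), , drop = FALSE]
    if (anyNA(pheno$sample)) stop_("phenotype table missing some VCF samples")
  }
  structure(
    list(
      sites = data.frame(
        contig = fix[, "CHROM"],
        pos = as.integer(fix[, "POS"]),
        ref = fix[, "REF"],
        alt = alt,
        qual = as.numeric(fix[, "QUAL"]),
        stringsAsFactors = FALSE
      ),
      gt = gt,
      dp = matrix(as.integer(dp), nrow = nrow(gt_chr), dimnames = dimnames(gt_chr)),
      samples = if (is.null(pheno)) {
        data.frame(sample = samples, morph = NA_character_,
          stringsAsFactors = FALSE)
      } else {
        data.frame(sample = samples, morph = pheno$morph,
          stringsAsFactors = FALSE)
      },
      truth = NULL
    ),
    class = "panel"
  )
}

#' Write / read the simulation truth file
#'
#' Ground truth (causal locus, phase, per-individual insertion genotypes)
#' recorded before sequencing noise; consumed only by reports and tests,
#' never by inference stages.
#'
#' @param truth a truth list.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
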