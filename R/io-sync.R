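#' Read a Popoolation2 sync file
#'
#' A sync file is tab-separated with columns contig, 1-based position,
#' reference base, then one `A:T:C:G:N:del` count column per sequenced
#' pool or parent. Malformed input (ragged columns, count fields without
#' exactly six values, negative or non-numeric counts, invalid positions)
#' is rejected with the offending line number. An empty file yields an
#' empty table, not an error. Plain and gzip-compressed files are both
#' accepted.
#'
#' @param path file path.
#' @param pool_names optional character vector naming the count columns;
#'   defaults to `pool1`, `pool2`, ...
#' @return A [sync_table()].
#' @examples
#' f <- tempfile(fileext = ".sync")
#' writeLines("ctg1\t5\tA\t10:0:0:0:0:0\t0:0:0:10:0:0", f)
#' read_sync(f, pool_names = c("alba", "orange"))
#' @export
read_sync <- function(path, pool_names = NULL) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(
      list(
        sites = data.frame(contig = character(), pos = integer(),
          ref = character(), stringsAsFactors = FALSE),
        pools = setNames(list(), character())
      ),
      class = "sync_table"
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_cols <- lengths(fields)
  if (length(unique(n_cols)) != 1L) {
    bad <- which(n_cols != n_cols[1L])[1L]
    stop_("sync parse error at line %d: %d columns where %d expected",
      bad, n_cols[bad], n_cols[1L])
  }
  if (n_cols[1L] < 4L) {
    stop_("sync parse error at line 1: need at least 4 columns, found %d", n_cols[1L])
  }
  n_pools <- n_cols[1L] - 3L
  m <- matrix(unlist(fields), ncol = n_cols[1L], byrow = TRUE)

  pos <- suppressWarnings(as.integer(m[, 2L]))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) {
    stop_("sync parse error at line %d: invalid position '%s'", bad[1L], m[bad[1L], 2L])
  }
  ref <- toupper(m[, 3L])
  bad <- which(!ref %in% c(BASES, "N"))
  if (length(bad)) {
    stop_("sync parse error at line %d: invalid reference base '%s'",
      bad[1L], m[bad[1L], 3L])
  }

  parse_counts <- function(col) {
    parts <- strsplit(m[, col + 3L], ":", fixed = TRUE)
    bad <- which(lengths(parts) != 6L)
    if (length(bad)) {
      stop_("sync parse error at line %d: count field '%s' has %d values, expected 6",
        bad[1L], m[bad[1L], col + 3L], lengths(parts)[bad[1L]])
    }
    v <- suppressWarnings(as.integer(unlist(parts)))
    cnt <- matrix(v, ncol = 6L, byrow = TRUE, dimnames = list(NULL, SYNC_FIELDS))
    bad <- which(apply(is.na(cnt) | cnt < 0L, 1L, any))
    if (length(bad)) {
      stop_("sync parse error at line %d: non-numeric or negative count in '%s'",
        bad[1L], m[bad[1L], col + 3L])
    }
    cnt
  }
  pools <- lapply(seq_len(n_pools), parse_counts)
  names(pools) <- pool_names %||% sprintf("pool%d", seq_len(n_pools))
  sync_table(
    data.frame(contig = m[, 1L], pos = pos, ref = ref, stringsAsFactors = FALSE),
    pools
  )
}

#' Write a sync table
#'
#' Emits pools in their stored column order, sites sorted by contig then
#' position, so that `read_sync(write_sync(x))` round-trips exactly for
#' sorted input. Paths ending in `.gz` are gzip-compressed.
#'
#' @param sync a [sync_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path) {
  stopifnot(inherits(sync, "sync_table"))
  ord <- order(sync$sites$contig, sync$sites$pos)
  cols <- vapply(sync$pools, function(m) {
    apply(m[ord, , drop = FALSE], 1L, paste, collapse = ":")
  }, character(length(ord)))
  if (length(ord) == 1L) cols <- matrix(cols, nrow = 1L)
  lines <- do.call(paste, c(
    list(sync$sites$contig[ord], sync$sites$pos[ord], sync$sites$ref[ord]),
    lapply(seq_along(sync$pools), function(i) cols[, i]),
    sep = "\t"
  ))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
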