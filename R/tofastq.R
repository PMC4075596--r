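# BAM/SAM to FastQ conversion on top of the collation engine.

.writeFastq <- function(id, seq, qual, path, gzip = FALSE) {
  con <- if (gzip) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(id)) {
    lines <- as.vector(rbind(paste0("@", id), seq, "+", qual))
    writeLines(lines, con)
  }
  invisible(length(id))
}

#' Convert an alignment file to FastQ
#'
#' Collates the input by read name and writes four FastQ streams: mate 1
#' and mate 2 of every recovered pair (index-aligned by name), orphan reads
#' (paired flag set, mate never seen) and single-end reads. Reverse-strand
#' records are restored to their original sequencing orientation
#' (reverse-complemented bases, reversed qualities). Records without stored
#' sequence are skipped with a warning. All four output files are created
#' even when empty. Qualities are emitted Phred+33.
#'
#' @param input Path to a SAM/BAM file, or an [AlignmentSet-class].
#' @param out1,out2,orphans,singles Output FastQ paths.
#' @param config A [CollationConfig-class].
#' @param gzip Write gzip-compressed output streams.
#' @param suffix Append `/1` and `/2` to paired read names.
#' @return Invisibly, a list with per-category counts (`pairs`, `orphans`,
#'   `singles`, `skipped`) and the collation stats.
#' @export
bamToFastq <- function(input, out1, out2, orphans, singles,
                       config = collationConfig(), gzip = FALSE,
                       suffix = FALSE) {
  res <- if (is(input, "CollationResult")) input else collate(input, config)
  x <- res@alignments
  rec <- x@records
  skipped <- 0L

  # drop a whole pair if either mate lacks sequence, keeping files aligned
  pkeep <- nzchar(rec$seq[res@pairs$first]) &
    nzchar(rec$seq[res@pairs$second])
  skipped <- skipped + 2L * sum(!pkeep)
  i1 <- res@pairs$first[pkeep]
  i2 <- res@pairs$second[pkeep]
  oIdx <- res@orphans$idx
  okO <- nzchar(rec$seq[oIdx]); skipped <- skipped + sum(!okO)
  oIdx <- oIdx[okO]
  sIdx <- res@singles$idx
  okS <- nzchar(rec$seq[sIdx]); skipped <- skipped + sum(!okS)
  sIdx <- sIdx[okS]

  emit <- function(idx, path, suff = "") {
    ori <- toOriginalOrientation(rec$seq[idx], rec$qual[idx],
                                 flagReverse(rec$flag[idx]))
    ids <- rec$qname[idx]
    if (nzchar(suff)) ids <- paste0(ids, suff)
    .writeFastq(ids, ori$seq, ori$qual, path, gzip)
  }
  emit(i1, out1, if (suffix) "/1" else "")
  emit(i2, out2, if (suffix) "/2" else "")
  emit(oIdx, orphans)
  emit(sIdx, singles)
  if (skipped > 0L)
    warning(sprintf("%d record(s) without stored sequence skipped", skipped))
  invisible(list(pairs = length(i1), orphans = length(oIdx),
                 singles = length(sIdx), skipped = skipped,
                 stats = res@stats))
}

#' Read a FastQ file into a data.frame
#'
#' Minimal 4-line FastQ reader used for round-trip validation; transparently
#' reads gzip-compressed files.
#'
#' @param path FastQ path (optionally gzipped).
#' @return `data.frame(id, seq, qual)`.
#' @export
readFastq <- function(path) {
  lines <- readLines(path)   # file()/readLines handle gzip transparently
  if (length(lines) %% 4L != 0L)
    stop("truncated FastQ file: ", path)
  n <- length(lines) / 4L
  if (n == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  i <- seq_len(n)
  data.frame(id = sub("^@", "", lines[4L * i - 3L]),
             seq = lines[4L * i - 2L], qual = lines[4L * i],
             stringsAsFactors = FALSE)
}
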