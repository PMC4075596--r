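# SAM/BAM input and output plus the compact serialized record form used by
# the collation buffers.

.isBamFile <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  # BGZF containers start with the gzip magic 1f 8b
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

.parseHeader <- function(headerLines) {
  sq <- grep("^@SQ\t", headerLines, value = TRUE)
  if (!length(sq))
    return(data.frame(refName = character(0), refLen = integer(0),
                      stringsAsFactors = FALSE))
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  data.frame(refName = sn, refLen = ln, stringsAsFactors = FALSE)
}

# Parse SAM body lines to the internal record table. refLookup maps
# reference name -> 0-based index.
.parseSamLines <- function(lines, refNames, offset = 0L) {
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(qname = character(0), flag = integer(0),
                      refId = integer(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      mateRefId = integer(0), matePos = integer(0),
                      tlen = integer(0), seq = character(0),
                      qual = character(0), tags = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  sp <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(sp)
  if (any(nf < 11L))
    stop(sprintf("malformed SAM record at index %d: fewer than 11 fields",
                 which(nf < 11L)[1] - 1L + offset))
  fld <- function(k) vapply(sp, `[[`, character(1), k)
  qname <- fld(1L)
  flag <- suppressWarnings(as.integer(fld(2L)))
  rname <- fld(3L)
  pos1 <- suppressWarnings(as.integer(fld(4L)))
  mapq <- suppressWarnings(as.integer(fld(5L)))
  cigar <- fld(6L)
  rnext <- fld(7L)
  pnext1 <- suppressWarnings(as.integer(fld(8L)))
  tlen <- suppressWarnings(as.integer(fld(9L)))
  seq <- fld(10L)
  qual <- fld(11L)
  bad <- is.na(flag) | is.na(pos1) | is.na(pnext1) | is.na(tlen)
  if (any(bad))
    stop(sprintf("malformed SAM record at index %d: non-numeric field",
                 which(bad)[1] - 1L + offset))
  tags <- character(n)
  extra <- which(nf > 11L)
  if (length(extra))
    tags[extra] <- vapply(sp[extra], function(x)
      paste(x[-(1:11)], collapse = "\t"), character(1))
  refId <- match(rname, refNames)
  refId[rname == "*"] <- 0L
  if (anyNA(refId))
    stop(sprintf("record at index %d refers to unknown reference '%s'",
                 which(is.na(refId))[1] - 1L + offset,
                 rname[which(is.na(refId))[1]]))
  refId <- refId - 1L          # 0-based; "*" -> -1
  mateRname <- rnext
  same <- mateRname == "="
  mateRname[same] <- rname[same]
  mateRefId <- match(mateRname, refNames)
  mateRefId[mateRname == "*"] <- 0L
  if (anyNA(mateRefId))
    stop(sprintf("record at index %d has unknown mate reference '%s'",
                 which(is.na(mateRefId))[1] - 1L + offset,
                 mateRname[which(is.na(mateRefId))[1]]))
  mateRefId <- mateRefId - 1L
  seq[seq == "*"] <- ""
  qual[qual == "*"] <- ""
  data.frame(qname = qname, flag = flag, refId = refId, pos = pos1 - 1L,
             mapq = mapq, cigar = cigar, mateRefId = mateRefId,
             matePos = pnext1 - 1L, tlen = tlen, seq = seq, qual = qual,
             tags = tags, rank = offset + seq_len(n) - 1L,
             stringsAsFactors = FALSE)
}

# Render internal records back to SAM text lines (1-based positions).
.samLines <- function(rec, refNames) {
  if (!nrow(rec)) return(character(0))
  rn <- c("*", refNames)[rec$refId + 2L]
  mrn <- c("*", refNames)[rec$mateRefId + 2L]
  seq <- ifelse(nzchar(rec$seq), rec$seq, "*")
  qual <- ifelse(nzchar(rec$qual), rec$qual, "*")
  base <- paste(rec$qname, rec$flag, rn, rec$pos + 1L, rec$mapq, rec$cigar,
                mrn, rec$matePos + 1L, rec$tlen, seq, qual, sep = "\t")
  ifelse(nzchar(rec$tags), paste(base, rec$tags, sep = "\t"), base)
}

# Read raw SAM text (header + body lines), converting BAM through Rsamtools.
.readSamText <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (.isBamFile(path)) {
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp))
    Rsamtools::asSam(path, sub("\\.sam$", "", tmp), overwrite = TRUE)
    lines <- readLines(tmp)
  } else {
    lines <- readLines(path)
  }
  is_header <- grepl("^@", lines)
  if (any(!is_header) && any(is_header & cumsum(!is_header) > 0))
    stop("malformed header: @-lines after first record in ", path)
  list(header = lines[is_header], body = lines[!is_header])
}

#' Read alignments from a SAM or BAM file
#'
#' The format is auto-detected from the file content (BGZF magic bytes mark
#' BAM; anything else is parsed as SAM text). BAM input is converted through
#' `Rsamtools::asSam()`. Records are returned in file order as an
#' [AlignmentSet-class]; ranks 0,1,2,... are assigned in encounter order.
#'
#' @param path Path to a readable SAM or BAM file.
#' @param assignRanks Assign 0-based ranks in encounter order (default);
#'   when `FALSE` ranks are still filled sequentially, which is the only
#'   supported numbering for a fresh read.
#' @return An [AlignmentSet-class].
#' @export
readAlignments <- function(path, assignRanks = TRUE) {
  txt <- .readSamText(path)
  refs <- .parseHeader(txt$header)
  rec <- .parseSamLines(txt$body, refs$refName)
  AlignmentSet(rec, refs,
               headerLines = if (length(txt$header)) txt$header
                             else character(0))
}

#' Write alignments to a SAM or BAM file
#'
#' Records are written in table order. The output parses back to a
#' field-for-field equal stream. The format is chosen from `format`, or from
#' the file extension when `format = "auto"`.
#'
#' @param x An [AlignmentSet-class].
#' @param path Output path.
#' @param format `"auto"`, `"sam"` or `"bam"`.
#' @return The number of records written, invisibly.
#' @export
writeAlignments <- function(x, path, format = c("auto", "sam", "bam")) {
  stopifnot(is(x, "AlignmentSet"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "sam"
  rec <- x@records
  mapped <- rec$refId >= 0L
  if (any(mapped & rec$refId >= nrow(x@refInfo)))
    stop("record refId out of range of the reference dictionary")
  lines <- c(x@headerLines, .samLines(rec, x@refInfo$refName))
  if (format == "sam") {
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("unwritable path: ", path)
  } else {
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp))
    writeLines(lines, tmp)
    dest <- sub("\\.bam$", "", path, ignore.case = TRUE)
    Rsamtools::asBam(tmp, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  invisible(nrow(rec))
}

# --- compact serialized form ------------------------------------------------

#' Serialize alignment records to their compact byte form
#'
#' The collation buffers store records as opaque byte strings. The
#' serialized form is the record's SAM text line; the read name occupies the
#' bytes up to the first tab, so it is extractable without deserializing the
#' whole record (see [serializedName()]). `serializeRecords()` returns a
#' character vector of serialized records, with byte lengths in attribute
#' `"len"`; [deserializeRecords()] is its inverse.
#'
#' @param x An [AlignmentSet-class], or for `deserializeRecords` a character
#'   vector of serialized records.
#' @return For `serializeRecords`, a character vector with a `"len"`
#'   attribute; for `deserializeRecords`, a record `data.frame` (ranks are
#'   taken from the `ranks` argument).
#' @export
serializeRecords <- function(x) {
  stopifnot(is(x, "AlignmentSet"))
  ser <- .samLines(x@records, x@refInfo$refName)
  attr(ser, "len") <- nchar(ser, type = "bytes")
  ser
}

#' @rdname serializeRecords
#' @param refNames Reference dictionary names resolving reference ids.
#' @param ranks Integer ranks to assign to the deserialized records.
#' @export
deserializeRecords <- function(x, refNames, ranks = seq_along(x) - 1L) {
  rec <- .parseSamLines(x, refNames)
  rec$rank <- as.integer(ranks)
  rec
}

#' @rdname serializeRecords
#' @export
serializedName <- function(x) {
  nm <- sub("\t.*$", "", x)
  attributes(nm) <- NULL
  nm
}
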