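# SAM FLAG bits
.FLAG_PAIRED      <- 0x1L
.FLAG_PROPER      <- 0x2L
.FLAG_UNMAPPED    <- 0x4L
.FLAG_MUNMAPPED   <- 0x8L
.FLAG_REVERSE     <- 0x10L
.FLAG_MREVERSE    <- 0x20L
.FLAG_READ1       <- 0x40L
.FLAG_READ2       <- 0x80L
.FLAG_SECONDARY   <- 0x100L
.FLAG_QCFAIL      <- 0x200L
.FLAG_DUP         <- 0x400L
.FLAG_SUPPLEMENTARY <- 0x800L

#' Test SAM flag bits
#'
#' Vectorized predicates over the SAM FLAG field.
#'
#' @param flag Integer vector of SAM flags.
#' @return Logical vector.
#' @name flagBits
NULL

#' @rdname flagBits
#' @export
flagPaired <- function(flag) bitwAnd(flag, .FLAG_PAIRED) != 0L

#' @rdname flagBits
#' @export
flagUnmapped <- function(flag) bitwAnd(flag, .FLAG_UNMAPPED) != 0L

#' @rdname flagBits
#' @export
flagMateUnmapped <- function(flag) bitwAnd(flag, .FLAG_MUNMAPPED) != 0L

#' @rdname flagBits
#' @export
flagReverse <- function(flag) bitwAnd(flag, .FLAG_REVERSE) != 0L

#' @rdname flagBits
#' @export
flagRead1 <- function(flag) bitwAnd(flag, .FLAG_READ1) != 0L

#' @rdname flagBits
#' @export
flagRead2 <- function(flag) bitwAnd(flag, .FLAG_READ2) != 0L

#' @rdname flagBits
#' @export
flagDuplicate <- function(flag) bitwAnd(flag, .FLAG_DUP) != 0L

# secondary or supplementary: excluded from pairing and duplicate candidacy
.flagNonPrimary <- function(flag) bitwAnd(flag, bitwOr(.FLAG_SECONDARY, .FLAG_SUPPLEMENTARY)) != 0L

# --- CIGAR arithmetic -------------------------------------------------------

# split a vector of CIGAR strings into lists of lengths and ops
.cigarParse <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)
  ops <- regmatches(cigar, m)
  lapply(ops, function(x) {
    if (length(x) == 0L || identical(x, "*")) {
      list(len = integer(0), op = character(0))
    } else {
      list(len = as.integer(sub("[MIDNSHP=X]$", "", x)),
           op  = sub("^\\d+", "", x))
    }
  })
}

# reference bases consumed by an alignment (M, D, N, =, X)
.cigarRefSpan <- function(cigar, seqlen = NULL) {
  parsed <- .cigarParse(cigar)
  span <- vapply(parsed, function(p) {
    sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
  # "*" CIGAR on a mapped record: fall back to the read length
  star <- cigar == "*" | cigar == ""
  if (any(star) && !is.null(seqlen)) span[star] <- seqlen[star]
  span
}

.cigarLeadClip <- function(cigar) {
  vapply(.cigarParse(cigar), function(p) {
    n <- 0L
    for (k in seq_along(p$op)) {
      if (p$op[k] %in% c("S", "H")) n <- n + p$len[k] else break
    }
    n
  }, integer(1))
}

.cigarTrailClip <- function(cigar) {
  vapply(.cigarParse(cigar), function(p) {
    n <- 0L
    for (k in rev(seq_along(p$op))) {
      if (p$op[k] %in% c("S", "H")) n <- n + p$len[k] else break
    }
    n
  }, integer(1))
}

# --- sequence orientation ---------------------------------------------------

#' Restore the original sequencing orientation of a read
#'
#' Alignment files store the bases of reverse-strand reads as the reverse
#' complement of what the sequencer produced. This helper undoes that:
#' for entries flagged as reverse-strand the sequence is reverse-complemented
#' (IUPAC codes mapped to their complements) and the quality string reversed;
#' forward-strand entries pass through unchanged.
#'
#' @param seq Character vector of base strings.
#' @param qual Character vector of quality strings (same lengths as `seq`).
#' @param reverse Logical vector: is the record reverse-strand (FLAG 0x10)?
#' @return A list with components `seq` and `qual`.
#' @examples
#' toOriginalOrientation("AAAC", "!!I!", TRUE)
#' @export
toOriginalOrientation <- function(seq, qual, reverse) {
  stopifnot(length(seq) == length(qual), length(reverse) == length(seq))
  seq <- as.character(seq); qual <- as.character(qual)
  rev_idx <- which(as.logical(reverse) & nchar(seq) > 0L)
  if (length(rev_idx)) {
    seq[rev_idx] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[rev_idx])))
    qual[rev_idx] <- as.character(
      Biostrings::reverse(Biostrings::BStringSet(qual[rev_idx])))
  }
  list(seq = seq, qual = qual)
}

# Phred values (integer) from a Phred+33 quality string
.phredValues <- function(qual) {
  if (is.na(qual) || qual == "" || qual == "*") return(integer(0))
  utf8ToInt(qual) - 33L
}
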