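# Duplicate marking: coordinate-keyed pair and fragment lists built from the
# collating reader, duplicate-rank deduction, and rewriting of the input
# with FLAG 0x400 set, with a hybrid in-memory/external spill strategy.

# FragCoord encoded as one exact double: refId * 2^33 + pos5 * 2 + strand
# (strand 0 = forward, 1 = reverse); total order (refId, pos5, strand).
.fragCode <- function(refId, pos5, strand) {
  refId * 2^33 + pos5 * 2 + strand
}

.decodeFrag <- function(code) {
  refId <- floor(code / 2^33)
  rest <- code - refId * 2^33
  pos5 <- floor(rest / 2)
  data.frame(refId = as.integer(refId), pos5 = as.integer(pos5),
             strand = as.integer(rest - pos5 * 2))
}

#' Unclipped 5' coordinate of mapped alignments
#'
#' The coordinate used for duplicate detection: the reference position of
#' the read's 5' sequencing end, extrapolated through soft/hard clipping.
#' Forward-strand reads: leftmost mapped position minus the leading clip
#' length. Reverse-strand reads: rightmost mapped position plus the
#' trailing clip length. Extrapolating through clips makes PCR copies with
#' slightly different alignments (hence different clipping) key to the same
#' coordinate.
#'
#' @param rec A record `data.frame` (rows must be mapped alignments) or an
#'   [AlignmentSet-class].
#' @return `data.frame(refId, pos5, strand)` with `strand` 0 (forward) or
#'   1 (reverse).
#' @export
fragCoord <- function(rec) {
  if (is(rec, "AlignmentSet")) rec <- rec@records
  if (any(flagUnmapped(rec$flag) | rec$refId < 0L))
    stop("fragCoord is undefined for unmapped records")
  rev <- flagReverse(rec$flag)
  span <- .cigarRefSpan(rec$cigar, nchar(rec$seq))
  lead <- .cigarLeadClip(rec$cigar)
  trail <- .cigarTrailClip(rec$cigar)
  pos5 <- ifelse(rev, rec$pos + span - 1L + trail, rec$pos - lead)
  data.frame(refId = rec$refId, pos5 = as.integer(pos5),
             strand = as.integer(rev))
}

#' Duplicate scores from base qualities
#'
#' The representant of a duplicate class is the member with the highest
#' score computed from base qualities: the sum of Phred values, where
#' values below 15 contribute nothing. A pair's score is the sum of its two
#' fragment scores; absent qualities score 0.
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @param qualA,qualB Quality strings of the two mates.
#' @return Integer score vector.
#' @export
fragScore <- function(qual) {
  vapply(qual, function(q) {
    v <- .phredValues(q)
    sum(v[v >= 15L])
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname fragScore
#' @export
pairScore <- function(qualA, qualB) {
  fragScore(qualA) + fragScore(qualB)
}

# ---------------------------------------------------------------------------
# list generation from a collation result

# Returns the fragment list L_S and pair list L_P in collation emission
# order (the order entries are "inserted" for the spill machinery):
#   LS: code, score, rank, isPair (end of a both-ends-mapped pair), seq
#   LP: code1, code2 (canonicalized left <= right), score, rank1, rank2, seq
.buildDupLists <- function(res) {
  x <- res@alignments
  rec <- x@records
  mapped <- !flagUnmapped(rec$flag) & rec$refId >= 0L

  p1 <- res@pairs$first; p2 <- res@pairs$second
  bothMapped <- if (length(p1)) mapped[p1] & mapped[p2] else logical(0)

  LP <- data.frame(code1 = numeric(0), code2 = numeric(0),
                   score = numeric(0), rank1 = integer(0),
                   rank2 = integer(0), seq = integer(0))
  if (any(bothMapped)) {
    a <- p1[bothMapped]; b <- p2[bothMapped]
    fa <- fragCoord(rec[a, , drop = FALSE])
    fb <- fragCoord(rec[b, , drop = FALSE])
    ca <- .fragCode(fa$refId, fa$pos5, fa$strand)
    cb <- .fragCode(fb$refId, fb$pos5, fb$strand)
    swap <- cb < ca
    left <- ifelse(swap, cb, ca)
    right <- ifelse(swap, ca, cb)
    LP <- data.frame(code1 = left, code2 = right,
                     score = pairScore(rec$qual[a], rec$qual[b]),
                     rank1 = rec$rank[a], rank2 = rec$rank[b],
                     seq = res@pairs$seq[bothMapped])
  }

  # fragment entries: every mapped end of every template; ends of mapped
  # pairs are flagged and protected from fragment-level marking
  fragIdx <- integer(0); fragIsPair <- logical(0); fragSeq <- integer(0)
  if (length(p1)) {
    fragIdx <- c(fragIdx, p1[bothMapped], p2[bothMapped])
    fragIsPair <- c(fragIsPair, rep(TRUE, 2L * sum(bothMapped)))
    fragSeq <- c(fragSeq, rep(res@pairs$seq[bothMapped], 2L))
    # half-mapped pairs: the mapped end is an orphan-like fragment
    half <- which(!bothMapped)
    for (k in half) {
      for (i in c(p1[k], p2[k])) {
        if (mapped[i]) {
          fragIdx <- c(fragIdx, i)
          fragIsPair <- c(fragIsPair, FALSE)
          fragSeq <- c(fragSeq, res@pairs$seq[k])
        }
      }
    }
  }
  oIdx <- res@orphans$idx
  okO <- mapped[oIdx]
  fragIdx <- c(fragIdx, oIdx[okO])
  fragIsPair <- c(fragIsPair, rep(FALSE, sum(okO)))
  fragSeq <- c(fragSeq, res@orphans$seq[okO])
  # secondary/supplementary records are routed through the singles channel;
  # they are not duplicate candidates
  sIdx <- res@singles$idx
  okS <- mapped[sIdx] & !.flagNonPrimary(rec$flag[sIdx])
  fragIdx <- c(fragIdx, sIdx[okS])
  fragIsPair <- c(fragIsPair, rep(FALSE, sum(okS)))
  fragSeq <- c(fragSeq, res@singles$seq[okS])

  LS <- if (length(fragIdx)) {
    fc <- fragCoord(rec[fragIdx, , drop = FALSE])
    data.frame(code = .fragCode(fc$refId, fc$pos5, fc$strand),
               score = fragScore(rec$qual[fragIdx]),
               rank = rec$rank[fragIdx], isPair = fragIsPair,
               seq = fragSeq)
  } else {
    data.frame(code = numeric(0), score = numeric(0), rank = integer(0),
               isPair = logical(0), seq = integer(0))
  }
  list(LS = LS, LP = LP)
}

# ---------------------------------------------------------------------------
# duplicate deduction over sorted lists

#' Deduce fragment-level duplicates
#'
#' Operates on the coordinate-sorted fragment list: a non-pair fragment
#' (single-end read or orphan) mapping to the same 5' coordinate as one end
#' of a mapped pair is marked unconditionally; within each coordinate class
#' containing only non-pair fragments, every entry but the single
#' highest-score one (ties: lowest rank) is marked. Reads belonging to
#' mapped pairs are never marked here.
#'
#' @param LS `data.frame(code, score, rank, isPair)` sorted by `code`.
#' @param pairEndCodes Coordinates occurring as ends of mapped pairs; when
#'   `NULL`, derived from the `isPair` entries of `LS`.
#' @return Integer vector of ranks to mark.
#' @export
markFragmentDuplicates <- function(LS, pairEndCodes = NULL) {
  if (!nrow(LS)) return(integer(0))
  if (is.unsorted(LS$code)) stop("fragment list is not coordinate-sorted")
  if (is.null(pairEndCodes)) pairEndCodes <- unique(LS$code[LS$isPair])
  frag <- !LS$isPair
  protectedClass <- LS$code %in% pairEndCodes
  marked <- LS$rank[frag & protectedClass]
  # pure-fragment classes: keep the best entry
  rest <- which(frag & !protectedClass)
  if (length(rest)) {
    o <- rest[order(LS$code[rest], -LS$score[rest], LS$rank[rest])]
    dupe <- duplicated(LS$code[o])
    marked <- c(marked, LS$rank[o][dupe])
  }
  sort(unique(marked))
}

#' Deduce pair-level duplicates
#'
#' Operates on the lexicographically sorted pair list: within each class of
#' pairs mapping to the same (left, right) 5' coordinates, the single
#' highest-score pair (ties: lowest rank) is the representant; both ranks
#' of every other pair are marked.
#'
#' @param LP `data.frame(code1, code2, score, rank1, rank2)` sorted by
#'   `(code1, code2)`.
#' @return Integer vector of ranks to mark.
#' @export
markPairDuplicates <- function(LP) {
  if (!nrow(LP)) return(integer(0))
  if (is.unsorted(LP$code1) ||
      any(diff(LP$code2)[diff(LP$code1) == 0] < 0))
    stop("pair list is not coordinate-sorted")
  key <- paste(LP$code1, LP$code2)
  o <- order(LP$code1, LP$code2, -LP$score, pmin(LP$rank1, LP$rank2))
  dupe <- duplicated(key[o])
  sort(unique(c(LP$rank1[o][dupe], LP$rank2[o][dupe])))
}

# ---------------------------------------------------------------------------
# hybrid in-memory / external spill

# Simulates streaming insertion of list entries (in collation emission
# order) under a cap on the number of in-memory entries. Whenever the cap
# is exceeded, every in-memory entry at the lowest coordinate (fragment
# coordinate, or a pair's left coordinate) is flushed to that coordinate's
# spill run on disk and the coordinate is marked for external handling;
# later entries at a spilled coordinate bypass memory and are appended to
# the run, which therefore stays internally coordinate-sorted. Returns the
# final LS/LP tables (memory + spill runs combined).
.spillProcess <- function(lists, threshold, tmpDir) {
  LS <- lists$LS; LP <- lists$LP
  if (!is.finite(threshold)) return(list(LS = LS, LP = LP, spilled = 0L))
  if (threshold < 1) stop("threshold must be >= 1")
  dir.create(tmpDir, recursive = TRUE, showWarnings = FALSE)
  ev <- rbind(
    if (nrow(LS)) data.frame(type = "F", key = LS$code, seq = LS$seq,
                             row = seq_len(nrow(LS)))
    else data.frame(type = character(0), key = numeric(0), seq = integer(0),
                    row = integer(0)),
    if (nrow(LP)) data.frame(type = "P", key = LP$code1, seq = LP$seq,
                             row = seq_len(nrow(LP)))
    else data.frame(type = character(0), key = numeric(0), seq = integer(0),
                    row = integer(0)))
  ev <- ev[order(ev$seq, ev$type, ev$row), , drop = FALSE]
  spillPath <- new.env(parent = emptyenv())
  memF <- integer(0); memP <- integer(0)

  entryLine <- function(type, row) {
    if (type == "F")
      sprintf("F\t%.0f\t%g\t%d\t%d", LS$code[row], LS$score[row],
              LS$rank[row], as.integer(LS$isPair[row]))
    else
      sprintf("P\t%.0f\t%.0f\t%g\t%d\t%d", LP$code1[row], LP$code2[row],
              LP$score[row], LP$rank1[row], LP$rank2[row])
  }
  spillLowest <- function() {
    cmin <- min(c(LS$code[memF], LP$code1[memP]))
    key <- sprintf("%.0f", cmin)
    path <- tempfile("bamcollate_spill_", tmpdir = tmpDir,
                     fileext = ".run")
    fF <- memF[LS$code[memF] == cmin]
    fP <- memP[LP$code1[memP] == cmin]
    lines <- c(vapply(fF, function(r) entryLine("F", r), character(1)),
               vapply(fP, function(r) entryLine("P", r), character(1)))
    writeLines(lines, path)
    assign(key, path, envir = spillPath)
    memF <<- setdiff(memF, fF)
    memP <<- setdiff(memP, fP)
  }
  for (k in seq_len(nrow(ev))) {
    key <- sprintf("%.0f", ev$key[k])
    if (exists(key, envir = spillPath, inherits = FALSE)) {
      cat(entryLine(ev$type[k], ev$row[k]), "\n", sep = "",
          file = get(key, envir = spillPath), append = TRUE)
    } else {
      if (ev$type[k] == "F") memF <- c(memF, ev$row[k])
      else memP <- c(memP, ev$row[k])
      while (length(memF) + length(memP) > threshold) spillLowest()
    }
  }
  # gather: in-memory remainder plus all spill runs
  outLS <- LS[memF, c("code", "score", "rank", "isPair"), drop = FALSE]
  outLP <- LP[memP, c("code1", "code2", "score", "rank1", "rank2"),
              drop = FALSE]
  paths <- unlist(mget(ls(spillPath), envir = spillPath),
                  use.names = FALSE)
  for (p in paths) {
    sp <- strsplit(readLines(p), "\t", fixed = TRUE)
    isF <- vapply(sp, `[[`, character(1), 1L) == "F"
    if (any(isF)) {
      m <- do.call(rbind, sp[isF])
      outLS <- rbind(outLS,
                     data.frame(code = as.numeric(m[, 2]),
                                score = as.numeric(m[, 3]),
                                rank = as.integer(m[, 4]),
                                isPair = m[, 5] == "1"))
    }
    if (any(!isF)) {
      m <- do.call(rbind, sp[!isF])
      outLP <- rbind(outLP,
                     data.frame(code1 = as.numeric(m[, 2]),
                                code2 = as.numeric(m[, 3]),
                                score = as.numeric(m[, 4]),
                                rank1 = as.integer(m[, 5]),
                                rank2 = as.integer(m[, 6])))
    }
  }
  unlink(paths)
  list(LS = outLS, LP = outLP, spilled = length(paths))
}

# ---------------------------------------------------------------------------

#' Deduce the set of duplicate ranks of an alignment set
#'
#' Collates `x` by read name, builds the coordinate-keyed pair and fragment
#' lists, and applies the pair- and fragment-level marking rules. With a
#' finite `threshold` the lists are held in memory only up to that many
#' entries; excess entries are flushed, lowest coordinate first, to
#' external spill runs (the marked set is invariant to `threshold`).
#'
#' @param x An [AlignmentSet-class].
#' @param config A [CollationConfig-class].
#' @param threshold Maximum in-memory list entries (default `Inf`).
#' @return A list: `ranks` (sorted 0-based ranks to mark), `templates`,
#'   `pairsExamined`, `dupReadsMarked`.
#' @export
computeDuplicateRanks <- function(x, config = collationConfig(),
                                  threshold = Inf) {
  res <- if (is(x, "CollationResult")) x else collate(x, config)
  lists <- .buildDupLists(res)
  got <- .spillProcess(lists, threshold,
                       file.path(config@tmpDir, "markdup_spill"))
  LS <- got$LS[order(got$LS$code, got$LS$rank), , drop = FALSE]
  LP <- got$LP[order(got$LP$code1, got$LP$code2,
                     pmin(got$LP$rank1, got$LP$rank2)), , drop = FALSE]
  pairEnds <- unique(LS$code[LS$isPair])
  marked <- sort(unique(c(markFragmentDuplicates(LS, pairEnds),
                          markPairDuplicates(LP))))
  rec <- res@alignments@records
  elig <- !.flagNonPrimary(rec$flag)
  list(ranks = marked,
       templates = length(unique(rec$qname[elig])),
       pairsExamined = nrow(got$LP),
       dupReadsMarked = length(marked))
}

#' Mark duplicate alignments in a SAM/BAM file
#'
#' Two-pass duplicate marking: the first pass collates the file by read
#' name and deduces the duplicate ranks from the 5'-coordinate pair and
#' fragment lists; the second pass rewrites the file with FLAG 0x400 set on
#' exactly those ranks and cleared everywhere else (pre-existing duplicate
#' flags are discarded, so marking is a pure function of content and
#' idempotent). All record bytes other than the FLAG field are preserved;
#' record order is unchanged. All reads are compared in a single namespace
#' (no library/read-group partitioning).
#'
#' @param input Path to a SAM/BAM file.
#' @param output Output path; the format follows the input dialect unless
#'   the extension says otherwise.
#' @param config A [CollationConfig-class].
#' @param threshold Maximum in-memory duplicate-list entries (see
#'   [computeDuplicateRanks()]).
#' @return Invisibly, a list of summary counts: `templates`,
#'   `pairsExamined`, `dupReadsMarked`.
#' @export
markDuplicates <- function(input, output, config = collationConfig(),
                           threshold = Inf) {
  txt <- .readSamText(input)
  refs <- .parseHeader(txt$header)
  rec <- .parseSamLines(txt$body, refs$refName)
  rec$flag <- bitwAnd(rec$flag, bitwNot(.FLAG_DUP))   # clear 0x400 first
  x <- AlignmentSet(rec, refs, headerLines = txt$header)
  ded <- computeDuplicateRanks(x, config, threshold)
  newFlag <- rec$flag
  if (length(ded$ranks)) {
    hit <- match(ded$ranks, rec$rank)
    newFlag[hit] <- bitwOr(newFlag[hit], .FLAG_DUP)
  }
  qn <- sub("\t.*$", "", txt$body)
  rest <- sub("^[^\t]*\t[^\t]*", "", txt$body)
  body <- paste0(qn, "\t", newFlag, rest)
  outBam <- grepl("\\.bam$", output, ignore.case = TRUE) ||
    (!grepl("\\.sam$", output, ignore.case = TRUE) && .isBamFile(input))
  if (outBam) {
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp))
    writeLines(c(txt$header, body), tmp)
    Rsamtools::asBam(tmp, sub("\\.bam$", "", output, ignore.case = TRUE),
                     overwrite = TRUE, indexDestination = FALSE)
  } else {
    writeLines(c(txt$header, body), output)
  }
  invisible(ded[c("templates", "pairsExamined", "dupReadsMarked")])
}
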