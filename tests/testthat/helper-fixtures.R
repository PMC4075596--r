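# Builders for in-code fixtures and independent oracles.

mkRec <- function(qname = "r1", flag = 0L, refId = 0L, pos = 0L,
                  mapq = 60L, cigar = "10M", mateRefId = -1L,
                  matePos = -1L, tlen = 0L, seq = "ACGTACGTAC",
                  qual = "IIIIIIIIII", tags = "", rank = 0L) {
  data.frame(qname = qname, flag = as.integer(flag),
             refId = as.integer(refId), pos = as.integer(pos),
             mapq = as.integer(mapq), cigar = cigar,
             mateRefId = as.integer(mateRefId),
             matePos = as.integer(matePos), tlen = as.integer(tlen),
             seq = seq, qual = qual, tags = tags, rank = as.integer(rank),
             stringsAsFactors = FALSE)
}

# a proper pair: read1 forward at pos1, read2 reverse at pos2 (10M each)
mkPair <- function(qname, pos1 = 100L, pos2 = 200L, refId = 0L,
                   qual1 = "IIIIIIIIII", qual2 = "IIIIIIIIII",
                   cigar1 = "10M", cigar2 = "10M") {
  rbind(
    mkRec(qname, flag = 0x1L + 0x2L + 0x20L + 0x40L, refId = refId,
          pos = pos1, cigar = cigar1, mateRefId = refId, matePos = pos2,
          tlen = pos2 + 10L - pos1, qual = qual1),
    mkRec(qname, flag = 0x1L + 0x2L + 0x10L + 0x80L, refId = refId,
          pos = pos2, cigar = cigar2, mateRefId = refId, matePos = pos1,
          tlen = -(pos2 + 10L - pos1), qual = qual2))
}

mkSingle <- function(qname, pos = 100L, refId = 0L, rev = FALSE,
                     qual = "IIIIIIIIII", cigar = "10M") {
  mkRec(qname, flag = if (rev) 0x10L else 0L, refId = refId, pos = pos,
        cigar = cigar, qual = qual)
}

mkOrphan <- function(qname, pos = 100L, refId = 0L, rev = FALSE,
                     qual = "IIIIIIIIII", cigar = "10M") {
  mkRec(qname, flag = 0x1L + 0x8L + 0x40L + (if (rev) 0x10L else 0L),
        refId = refId, pos = pos, cigar = cigar, mateRefId = refId,
        matePos = pos, qual = qual)
}

mkSet <- function(rows, nRefs = 1L, refLen = 100000L) {
  rows$rank <- seq_len(nrow(rows)) - 1L
  rownames(rows) <- NULL
  AlignmentSet(rows, data.frame(refName = sprintf("ref%d", seq_len(nRefs)),
                                refLen = as.integer(refLen),
                                stringsAsFactors = FALSE))
}

writeSamFixture <- function(x, path = tempfile(fileext = ".sam")) {
  writeAlignments(x, path, format = "sam")
  path
}

# --- collation oracle: stable name-sort, group, pair complementary mates ----

# Returns the PAIR/ORPHAN/SINGLE partition as three sorted name vectors
# (one entry per record for orphans/singles, one per pair for pairs).
oracleCollate <- function(rec) {
  nonprim <- bitwAnd(rec$flag, 0x900L) != 0L
  paired <- bitwAnd(rec$flag, 0x1L) != 0L
  isR1 <- bitwAnd(rec$flag, 0x40L) != 0L & bitwAnd(rec$flag, 0x80L) == 0L
  isR2 <- bitwAnd(rec$flag, 0x80L) != 0L & bitwAnd(rec$flag, 0x40L) == 0L
  pairs <- character(0); orphans <- character(0); singles <- character(0)
  singles <- c(singles, rec$qname[nonprim])
  elig <- which(!nonprim)
  singles <- c(singles, rec$qname[elig[!paired[elig]]])
  pr <- elig[paired[elig]]
  for (nm in unique(rec$qname[pr])) {
    g <- pr[rec$qname[pr] == nm]
    a <- g[isR1[g]][order(rec$rank[g[isR1[g]]])]
    b <- g[isR2[g]][order(rec$rank[g[isR2[g]]])]
    m <- min(length(a), length(b))
    pairs <- c(pairs, rep(nm, m))
    leftover <- length(g) - 2L * m
    orphans <- c(orphans, rep(nm, leftover))
  }
  list(pairs = sort(pairs), orphans = sort(orphans),
       singles = sort(singles))
}

resultPartition <- function(res) {
  rec <- alnRecords(res@alignments)
  list(pairs = sort(rec$qname[collatedPairs(res)$first]),
       orphans = sort(rec$qname[collatedOrphans(res)$idx]),
       singles = sort(rec$qname[collatedSingles(res)$idx]))
}

conservationHolds <- function(res) {
  n <- length(res@alignments)
  2L * nrow(collatedPairs(res)) + nrow(collatedOrphans(res)) +
    nrow(collatedSingles(res)) == n
}

# --- O(n^2) duplicate-marking oracle ----------------------------------------

# Independent all-pairs implementation of the marking rules; intentionally
# naive. Returns the sorted 0-based ranks to mark.
oracleMarkDup <- function(rec) {
  n <- nrow(rec)
  prim <- bitwAnd(rec$flag, 0x900L) == 0L
  mapped <- bitwAnd(rec$flag, 0x4L) == 0L & rec$refId >= 0L
  rev <- bitwAnd(rec$flag, 0x10L) != 0L
  score1 <- function(i) {
    q <- rec$qual[i]
    if (q == "") return(0)
    v <- utf8ToInt(q) - 33L
    sum(v[v >= 15L])
  }
  coord <- function(i) {
    cig <- rec$cigar[i]
    toks <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
    len <- as.integer(sub(".$", "", toks))
    op <- sub("^\\d+", "", toks)
    span <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    if (!length(toks)) span <- nchar(rec$seq[i])
    lead <- 0L
    for (k in seq_along(op)) {
      if (op[k] %in% c("S", "H")) lead <- lead + len[k] else break
    }
    trail <- 0L
    for (k in rev(seq_along(op))) {
      if (op[k] %in% c("S", "H")) trail <- trail + len[k] else break
    }
    if (rev[i]) c(rec$refId[i], rec$pos[i] + span - 1L + trail, 1L)
    else c(rec$refId[i], rec$pos[i] - lead, 0L)
  }
  # mapped pairs: exactly one read1 and one read2, both mapped
  pairFirst <- integer(0); pairSecond <- integer(0)
  for (nm in unique(rec$qname[prim & bitwAnd(rec$flag, 0x1L) != 0L])) {
    g <- which(rec$qname == nm & prim)
    a <- g[bitwAnd(rec$flag[g], 0x40L) != 0L & bitwAnd(rec$flag[g], 0x80L) == 0L]
    b <- g[bitwAnd(rec$flag[g], 0x80L) != 0L & bitwAnd(rec$flag[g], 0x40L) == 0L]
    if (length(a) == 1L && length(b) == 1L && mapped[a] && mapped[b]) {
      pairFirst <- c(pairFirst, a); pairSecond <- c(pairSecond, b)
    }
  }
  inPair <- c(pairFirst, pairSecond)
  marked <- integer(0)
  # pair duplicates
  if (length(pairFirst)) {
    keys <- vapply(seq_along(pairFirst), function(k) {
      ca <- coord(pairFirst[k]); cb <- coord(pairSecond[k])
      kk <- sort(c(paste(sprintf("%09d", ca), collapse = ","),
                   paste(sprintf("%09d", cb), collapse = ",")))
      paste(kk, collapse = "|")
    }, character(1))
    sc <- vapply(seq_along(pairFirst), function(k)
      score1(pairFirst[k]) + score1(pairSecond[k]), numeric(1))
    mr <- pmin(rec$rank[pairFirst], rec$rank[pairSecond])
    for (k in seq_along(pairFirst)) {
      beats <- which(keys == keys[k] &
                     (sc > sc[k] | (sc == sc[k] & mr < mr[k])))
      if (length(beats))
        marked <- c(marked, rec$rank[pairFirst[k]], rec$rank[pairSecond[k]])
    }
  }
  # fragments: primary mapped reads not part of a mapped pair
  frags <- setdiff(which(prim & mapped), inPair)
  if (length(frags)) {
    fc <- vapply(frags, function(i) paste(coord(i), collapse = ","),
                 character(1))
    fs <- vapply(frags, score1, numeric(1))
    pairEnd <- unique(vapply(inPair, function(i)
      paste(coord(i), collapse = ","), character(1)))
    for (k in seq_along(frags)) {
      if (fc[k] %in% pairEnd) {
        marked <- c(marked, rec$rank[frags[k]])
      } else {
        beats <- which(fc == fc[k] &
                       (fs > fs[k] |
                        (fs == fs[k] & rec$rank[frags] < rec$rank[frags[k]])))
        if (length(beats)) marked <- c(marked, rec$rank[frags[k]])
      }
    }
  }
  sort(unique(marked))
}

# expected duplicate set derived from the simulator truth table: for every
# coordinate-identical group of mapped pairs, all but the best-scoring
# template's reads; orphans/singles at a pair-end coordinate; and
# best-of-class among coordinate-identical orphans/singles.
truthExpectedDuplicates <- function(sim) {
  tr <- sim$truth
  rec <- alnRecords(sim$alignments)
  qscore <- function(q) {
    v <- utf8ToInt(q) - 33L
    sum(v[v >= 15L])
  }
  ranksOf <- function(nm) sort(rec$rank[rec$qname == nm])
  minRank <- vapply(tr$name, function(nm) min(ranksOf(nm)), numeric(1))
  ckey <- function(r, p, s) sprintf("%d:%d:%s", r, p, s)
  isPairT <- tr$category %in% c("normal", "split")
  marked <- integer(0)
  if (any(isPairT)) {
    pk <- vapply(which(isPairT), function(i) {
      paste(sort(c(ckey(tr$refId1[i], tr$pos5_1[i], tr$strand1[i]),
                   ckey(tr$refId2[i], tr$pos5_2[i], tr$strand2[i]))),
            collapse = "|")
    }, character(1))
    sc <- vapply(which(isPairT), function(i)
      qscore(tr$qual1[i]) + qscore(tr$qual2[i]), numeric(1))
    mr <- minRank[isPairT]
    nms <- tr$name[isPairT]
    for (key in unique(pk)) {
      g <- which(pk == key)
      if (length(g) < 2L) next
      best <- g[order(-sc[g], mr[g])][1L]
      for (k in setdiff(g, best)) marked <- c(marked, ranksOf(nms[k]))
    }
    pairEnds <- unique(c(
      ckey(tr$refId1[isPairT], tr$pos5_1[isPairT], tr$strand1[isPairT]),
      ckey(tr$refId2[isPairT], tr$pos5_2[isPairT], tr$strand2[isPairT])))
  } else {
    pairEnds <- character(0)
  }
  fragT <- which(tr$category %in% c("orphan", "single"))
  if (length(fragT)) {
    fk <- ckey(tr$refId1[fragT], tr$pos5_1[fragT], tr$strand1[fragT])
    fs <- vapply(fragT, function(i) qscore(tr$qual1[i]), numeric(1))
    fr <- minRank[fragT]
    atPair <- fk %in% pairEnds
    marked <- c(marked, fr[atPair])
    for (key in unique(fk[!atPair])) {
      g <- which(fk == key & !atPair)
      if (length(g) < 2L) next
      best <- g[order(-fs[g], fr[g])][1L]
      marked <- c(marked, fr[setdiff(g, best)])
    }
  }
  sort(unique(as.integer(marked)))
}
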