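# Synthetic-data generator: coordinate-sorted paired-end alignments with
# known ground truth (mate gaps, planted duplicate clusters, orphans, split
# pairs, single-end reads).

#' Simulate a coordinate-sorted paired-end alignment file
#'
#' Generates error-free reads as windows of synthetic reference sequences,
#' places templates uniformly, and emits one coordinate-sorted record table
#' together with a truth table listing, per template, its name, category,
#' duplicate-cluster id, the unclipped 5' coordinate and strand of each end,
#' and the sequencing-orientation bases and qualities of each read.
#' Planted duplicates are exact coordinate clones of their cluster seed with
#' independently drawn qualities (duplicate identity is coordinate-based,
#' not sequence-based). Qualities are windows of a pre-generated random
#' Phred 2-40 pool. All CIGARs are pure matches unless `clipRate > 0`, in
#' which case the affected reads are soft-clipped in a way that preserves
#' their unclipped 5' coordinate.
#'
#' @param profile A [SimProfile-class].
#' @return A list with components `alignments` (an [AlignmentSet-class],
#'   coordinate-sorted, ranks assigned) and `truth` (a `data.frame` with one
#'   row per template).
#' @examples
#' sim <- simulateAlignments(simProfile(genomeLen = 2e4, d = 6, seed = 42))
#' length(sim$alignments)
#' @export
simulateAlignments <- function(profile) {
  stopifnot(is(profile, "SimProfile"))
  validObject(profile)
  set.seed(profile@seed)
  G <- as.integer(profile@genomeLen)
  R <- as.integer(profile@nRefs)
  l <- as.integer(profile@l)
  refNames <- sprintf("ref%d", seq_len(R))
  bases <- c("A", "C", "G", "T")
  refSeq <- vapply(seq_len(R), function(i)
    paste(sample(bases, G, replace = TRUE), collapse = ""), character(1))
  qualChars <- strsplit(intToUtf8(35:73), "")[[1]]   # Phred 2..40
  poolLen <- max(4L * l, 2L * G)
  qualPool <- paste(sample(qualChars, poolLen, replace = TRUE),
                    collapse = "")

  nT <- as.integer(round(profile@d * G * R / (2 * l)))
  if (nT < 1L) stop("infeasible profile: zero templates")

  u <- runif(nT)
  cat <- rep("normal", nT)
  b1 <- profile@orphanRate
  b2 <- b1 + profile@splitRate
  b3 <- b2 + profile@singleRate
  cat[u < b1] <- "orphan"
  cat[u >= b1 & u < b2] <- "split"
  cat[u >= b2 & u < b3] <- "single"

  # per-template placement parameters
  ref <- sample.int(R, nT, replace = TRUE)              # 1-based
  tlenv <- pmin(pmax(as.integer(round(stats::rnorm(nT, profile@tMean,
                                                   profile@tSd))), l), G)
  p <- as.integer(floor(runif(nT) * (G - tlenv + 1)))   # template left end
  r1fwd <- runif(nT) < 0.5
  posSingle <- as.integer(floor(runif(nT) * (G - l + 1)))
  revSingle <- runif(nT) < 0.5
  refB <- (ref - 1L + sample.int(max(R - 1L, 1L), nT, replace = TRUE)) %%
    R + 1L                                              # split-pair mate ref
  posB <- as.integer(floor(runif(nT) * (G - l + 1)))
  revB <- runif(nT) < 0.5

  cluster <- seq_len(nT)
  # planted PCR-duplicate clusters: coordinate clones of normal templates
  normIdx <- which(cat == "normal")
  seeds <- normIdx[runif(length(normIdx)) < profile@dupRate]
  extra <- if (length(seeds)) stats::rpois(length(seeds),
                                           profile@lambdaDup) else integer(0)
  cloneOf <- rep(seeds, extra)
  if (length(cloneOf)) {
    m <- length(cloneOf)
    cat <- c(cat, rep("normal", m))
    ref <- c(ref, ref[cloneOf])
    tlenv <- c(tlenv, tlenv[cloneOf])
    p <- c(p, p[cloneOf])
    r1fwd <- c(r1fwd, r1fwd[cloneOf])
    posSingle <- c(posSingle, posSingle[cloneOf])
    revSingle <- c(revSingle, revSingle[cloneOf])
    refB <- c(refB, refB[cloneOf])
    posB <- c(posB, posB[cloneOf])
    revB <- c(revB, revB[cloneOf])
    cluster <- c(cluster, cluster[cloneOf])
  }
  nAll <- length(cat)
  name <- sprintf("sim%07d", seq_len(nAll))

  # --- expand templates to reads -------------------------------------------
  two <- cat %in% c("normal", "split")
  tmplId <- c(seq_len(nAll), which(two))
  readNo <- c(rep(1L, nAll), rep(2L, sum(two)))
  ord0 <- order(tmplId, readNo)
  tmplId <- tmplId[ord0]; readNo <- readNo[ord0]

  rcat <- cat[tmplId]
  rref <- integer(length(tmplId)); rpos <- integer(length(tmplId))
  rrev <- logical(length(tmplId)); rflag <- integer(length(tmplId))
  rtlen <- integer(length(tmplId))
  mref <- rep(-1L, length(tmplId)); mpos <- rep(-1L, length(tmplId))

  isNorm <- rcat == "normal"
  i1 <- isNorm & readNo == 1L; i2 <- isNorm & readNo == 2L
  t1 <- tmplId[i1]; t2 <- tmplId[i2]
  fwdPos <- p; revPos <- p + tlenv - l
  rref[i1] <- ref[t1] - 1L
  rref[i2] <- ref[t2] - 1L
  rpos[i1] <- ifelse(r1fwd[t1], fwdPos[t1], revPos[t1])
  rpos[i2] <- ifelse(r1fwd[t2], revPos[t2], fwdPos[t2])
  rrev[i1] <- !r1fwd[t1]
  rrev[i2] <- r1fwd[t2]
  rflag[i1] <- 0x1L + 0x2L + 0x40L +
    ifelse(r1fwd[t1], 0x20L, 0x10L)
  rflag[i2] <- 0x1L + 0x2L + 0x80L +
    ifelse(r1fwd[t2], 0x10L, 0x20L)
  rtlen[i1] <- ifelse(r1fwd[t1], tlenv[t1], -tlenv[t1])
  rtlen[i2] <- ifelse(r1fwd[t2], -tlenv[t2], tlenv[t2])
  mref[i1] <- ref[t1] - 1L; mref[i2] <- ref[t2] - 1L
  mpos[i1] <- ifelse(r1fwd[t1], revPos[t1], fwdPos[t1])
  mpos[i2] <- ifelse(r1fwd[t2], fwdPos[t2], revPos[t2])

  iS <- rcat == "split"
  s1 <- iS & readNo == 1L; s2 <- iS & readNo == 2L
  ts1 <- tmplId[s1]; ts2 <- tmplId[s2]
  rref[s1] <- ref[ts1] - 1L;  rpos[s1] <- p[ts1]
  rref[s2] <- refB[ts2] - 1L; rpos[s2] <- posB[ts2]
  rrev[s1] <- revSingle[ts1]; rrev[s2] <- revB[ts2]
  rflag[s1] <- 0x1L + 0x40L + ifelse(rrev[s1], 0x10L, 0L) +
    ifelse(revB[ts1], 0x20L, 0L)
  rflag[s2] <- 0x1L + 0x80L + ifelse(rrev[s2], 0x10L, 0L) +
    ifelse(revSingle[ts2], 0x20L, 0L)
  mref[s1] <- refB[ts1] - 1L; mpos[s1] <- posB[ts1]
  mref[s2] <- ref[ts2] - 1L;  mpos[s2] <- p[ts2]

  iO <- rcat == "orphan"
  tO <- tmplId[iO]
  rref[iO] <- ref[tO] - 1L; rpos[iO] <- posSingle[tO]
  rrev[iO] <- revSingle[tO]
  rflag[iO] <- 0x1L + 0x8L + 0x40L + ifelse(rrev[iO], 0x10L, 0L)
  mref[iO] <- rref[iO]; mpos[iO] <- rpos[iO]   # unmapped mate placed here

  iU <- rcat == "single"
  tU <- tmplId[iU]
  rref[iU] <- ref[tU] - 1L; rpos[iU] <- posSingle[tU]
  rrev[iU] <- revSingle[tU]
  rflag[iU] <- ifelse(rrev[iU], 0x10L, 0L)

  nReads <- length(tmplId)
  origPos <- rpos                       # left end of the full read window
  cigar <- rep(sprintf("%dM", l), nReads)

  # optional soft-clip mode, preserving the unclipped 5' coordinate
  if (profile@clipRate > 0) {
    clip <- which(runif(nReads) < profile@clipRate)
    if (length(clip)) {
      cl <- sample.int(min(10L, l - 1L), length(clip), replace = TRUE)
      fw <- clip[!rrev[clip]]; cf <- cl[!rrev[clip]]
      rv <- clip[rrev[clip]];  cr <- cl[rrev[clip]]
      cigar[fw] <- sprintf("%dS%dM", cf, l - cf)
      rpos[fw] <- rpos[fw] + cf
      cigar[rv] <- sprintf("%dM%dS", l - cr, cr)
    }
  }

  seq <- substring(refSeq[rref + 1L], origPos + 1L, origPos + l)
  qoff <- sample.int(poolLen - l + 1L, nReads, replace = TRUE)
  qual <- substring(qualPool, qoff, qoff + l - 1L)

  rec <- data.frame(qname = name[tmplId], flag = rflag, refId = rref,
                    pos = rpos, mapq = 60L, cigar = cigar,
                    mateRefId = mref, matePos = mpos, tlen = rtlen,
                    seq = seq, qual = qual, tags = "",
                    rank = 0L, stringsAsFactors = FALSE)
  ord <- order(rec$refId, rec$pos, rec$qname, method = "radix")
  rec <- rec[ord, , drop = FALSE]
  rec$rank <- seq_len(nrow(rec)) - 1L
  rownames(rec) <- NULL

  # --- truth table ----------------------------------------------------------
  ori <- toOriginalOrientation(seq, qual, rrev)
  p5 <- ifelse(rrev, origPos + l - 1L, origPos)
  strand <- ifelse(rrev, "-", "+")
  one <- which(readNo == 1L)
  truth <- data.frame(name = name, category = cat, cluster = cluster,
                      refId1 = rref[one], pos5_1 = p5[one],
                      strand1 = strand[one],
                      refId2 = NA_integer_, pos5_2 = NA_integer_,
                      strand2 = NA_character_,
                      seq1 = ori$seq[one], qual1 = ori$qual[one],
                      seq2 = NA_character_, qual2 = NA_character_,
                      stringsAsFactors = FALSE)
  second <- which(readNo == 2L)
  if (length(second)) {
    tid <- tmplId[second]
    truth$refId2[tid] <- rref[second]
    truth$pos5_2[tid] <- p5[second]
    truth$strand2[tid] <- strand[second]
    truth$seq2[tid] <- ori$seq[second]
    truth$qual2[tid] <- ori$qual[second]
  }

  refs <- data.frame(refName = refNames, refLen = G,
                     stringsAsFactors = FALSE)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", refNames, G))
  list(alignments = AlignmentSet(rec, refs, headerLines = hdr),
       truth = truth)
}

#' Empirical in-file gap between the mates of each template
#'
#' For every template whose two mates are both mapped to the same reference
#' (primary alignments, neither end unmapped), the gap is the number of
#' records lying strictly between the two mates in file order,
#' `|rank2 - rank1| - 1`.
#'
#' @param x An [AlignmentSet-class] (records must carry ranks).
#' @return A list with components `median`, `mean` and `gaps` (the
#'   per-template gap vector).
#' @examples
#' sim <- simulateAlignments(simProfile(genomeLen = 2e4, d = 8, seed = 3))
#' empiricalMateGap(sim$alignments)$median
#' @export
empiricalMateGap <- function(x) {
  stopifnot(is(x, "AlignmentSet"))
  rec <- x@records
  ok <- flagPaired(rec$flag) & !flagUnmapped(rec$flag) &
    !flagMateUnmapped(rec$flag) & rec$refId == rec$mateRefId &
    rec$refId >= 0L & !.flagNonPrimary(rec$flag)
  idx <- which(ok)
  if (!length(idx))
    return(list(median = NA_real_, mean = NA_real_, gaps = numeric(0)))
  nm <- rec$qname[idx]
  cnt <- table(nm)
  keep <- nm %in% names(cnt)[cnt == 2L]
  idx <- idx[keep]; nm <- nm[keep]
  o <- order(nm, rec$rank[idx], method = "radix")
  idx <- idx[o]
  r <- rec$rank[idx]
  first <- seq(1L, length(r), by = 2L)
  gaps <- abs(r[first + 1L] - r[first]) - 1L
  list(median = stats::median(gaps), mean = mean(gaps), gaps = gaps)
}
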