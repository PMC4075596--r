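# The collation engine: stream alignments in arbitrary order and emit
# name-matched pairs plus leftover orphans/singles, using a collisionless
# hash table H (pointer table P into a ring buffer R, with an ordered index
# B of live start offsets), a two-ended overflow list L, name-sorted
# temporary runs and a final multiway merge.

.RUN_MAGIC <- "BAMCOLLATE_RUN\t1"
.LIST_ENTRY_BYTES <- 8   # size of one start-pointer entry in the overflow list

#' Hash a read name to a slot index
#'
#' Deterministic polynomial rolling hash (base 131, modulus 2^31 - 1),
#' reduced modulo the slot count. Identical across platforms and runs.
#'
#' @param name Character vector of read names.
#' @param slots Number of hash slots.
#' @return Integer vector of slot indices in `[0, slots)`.
#' @export
hashName <- function(name, slots) {
  stopifnot(all(nzchar(name)), slots >= 1)
  p <- 2147483647
  maxlen <- max(nchar(name, type = "bytes"))
  codes <- matrix(0L, nrow = length(name), ncol = maxlen)
  ints <- lapply(name, utf8ToInt)
  for (i in seq_along(ints)) codes[i, seq_along(ints[[i]])] <- ints[[i]]
  h <- numeric(length(name))
  for (k in seq_len(maxlen)) h <- (h * 131 + codes[, k]) %% p
  as.integer(h %% slots)
}

# ---------------------------------------------------------------------------
# mutable collation state. The state is an environment built by a closure
# factory: the engine operations live inside it and update its bindings via
# superassignment, which keeps the large slot/offset/output vectors
# modified in place.

.newCollationState <- function(x, config) {
  stopifnot(is(x, "AlignmentSet"), is(config, "CollationConfig"))
  validObject(config)
  rec <- x@records
  serOut <- .samLines(rec, x@refInfo$refName)
  r1f <- flagRead1(rec$flag); r2f <- flagRead2(rec$flag)

  st <- local({
    aln <- x
    qn <- rec$qname
    flag <- rec$flag
    rank <- rec$rank
    ser <- serOut
    serLen <- nchar(serOut, type = "bytes")
    paired <- flagPaired(rec$flag)
    isR1 <- r1f & !r2f
    isR2 <- r2f & !r1f
    elig <- !.flagNonPrimary(rec$flag)
    n <- nrow(rec)
    h <- as.integer(config@hashSlots)
    cap <- config@ringBytes
    sL <- config@listBytes
    tmpDir <- config@tmpDir
    fanIn <- as.integer(config@mergeFanIn)
    slot <- if (n) hashName(qn, h) + 1L else integer(0)

    # hash table H: pointer table P (0 = EMPTY) plus per-slot ring offset
    P <- integer(h)
    Poff <- numeric(h)
    # ordered index B of live start offsets (sorted), with slot/record ids
    Boff <- numeric(0)
    Bslot <- integer(0)
    Bidx <- integer(0)
    r <- 0
    live <- 0
    maxLive <- 0
    # overflow list L
    Lidx <- integer(0)
    Lbytes <- 0
    maxLocc <- 0
    runs <- character(0)
    nL <- 0
    # outputs
    p1 <- integer(n); p2 <- integer(n); pSeq <- integer(n); np <- 0L
    oIdx <- integer(n); oSeq <- integer(n); no <- 0L
    sIdx <- integer(n); sSeq <- integer(n); ns <- 0L
    seqNo <- 0L

    emitPair <- function(i, j) {
      # order read1 first regardless of encounter order
      if (isR2[i]) { tmp <- i; i <- j; j <- tmp }
      np <<- np + 1L
      seqNo <<- seqNo + 1L
      p1[np] <<- i; p2[np] <<- j; pSeq[np] <<- seqNo
    }
    emitOrphan <- function(i) {
      no <<- no + 1L
      seqNo <<- seqNo + 1L
      oIdx[no] <<- i; oSeq[no] <<- seqNo
    }
    emitSingle <- function(i) {
      ns <<- ns + 1L
      seqNo <<- seqNo + 1L
      sIdx[ns] <<- i; sSeq[ns] <<- seqNo
    }

    # free bytes between the insert cursor r and the circular successor
    # offset in B (the whole ring when B is empty)
    ringFree <- function() {
      nb <- length(Boff)
      if (nb == 0L) return(cap)
      k <- findInterval(r, Boff)   # offsets <= r
      succ <- if (k < nb) Boff[k + 1L] else Boff[1L]
      d <- (succ - r) %% cap
      if (d == 0) 0 else d
    }
    bInsert <- function(off, s, idx) {
      k <- findInterval(off, Boff)
      Boff <<- append(Boff, off, after = k)
      Bslot <<- append(Bslot, s, after = k)
      Bidx <<- append(Bidx, idx, after = k)
    }
    bRemoveAt <- function(k) {
      Boff <<- Boff[-k]
      Bslot <<- Bslot[-k]
      Bidx <<- Bidx[-k]
    }
    # erase the record stored at slot s from H (P and B)
    hashErase <- function(s) {
      off <- Poff[s]
      k <- findInterval(off, Boff)
      stopifnot(k >= 1L, Boff[k] == off)
      live <<- live - serLen[Bidx[k]]
      bRemoveAt(k)
      P[s] <<- 0L
    }
    # evict the ring-order successor of r (the oldest live record) to L
    evictOldest <- function() {
      nb <- length(Boff)
      stopifnot(nb > 0L)
      k <- findInterval(r, Boff)
      k <- if (k < nb) k + 1L else 1L
      victim <- Bidx[k]
      P[Bslot[k]] <<- 0L
      live <<- live - serLen[victim]
      bRemoveAt(k)
      listInsert(victim)
    }
    # store record i at its (EMPTY) slot, evicting residents until the
    # circular free space suffices
    hashStore <- function(i) {
      len <- serLen[i]
      if (len > cap)
        stop(sprintf("record '%s' (%d bytes) exceeds ring buffer capacity %g",
                     qn[i], len, cap))
      while (ringFree() < len) evictOldest()
      s <- slot[i]
      P[s] <<- i
      Poff[s] <<- r
      bInsert(r, s, i)
      live <<- live + len
      if (live > maxLive) maxLive <<- live
      r <<- (r + len) %% cap
    }
    # hash-table insertion of record i: pair detection, collision eviction
    # to L, then storage of i
    hashInsert <- function(i) {
      s <- slot[i]
      j <- P[s]
      if (j != 0L) {
        if (qn[j] == qn[i] && paired[i] && paired[j] &&
            ((isR1[i] && isR2[j]) || (isR2[i] && isR1[j]))) {
          hashErase(s)
          emitPair(j, i)
          return(invisible(NULL))
        }
        hashErase(s)
        listInsert(j)
      }
      hashStore(i)
      invisible(NULL)
    }
    # insertion into the overflow list L; flushes first when the record
    # plus its pointer entry would no longer fit
    listInsert <- function(i) {
      len <- serLen[i]
      need <- Lbytes + len + .LIST_ENTRY_BYTES * (length(Lidx) + 1L)
      if (need > sL) {
        flushList()
        if (len + .LIST_ENTRY_BYTES > sL)
          stop(sprintf(
            "record '%s' (%d bytes) exceeds overflow list capacity %g",
            qn[i], len, sL))
      }
      Lidx <<- c(Lidx, i)
      Lbytes <<- Lbytes + len
      occ <- Lbytes + .LIST_ENTRY_BYTES * length(Lidx)
      if (occ > maxLocc) maxLocc <<- occ
      nL <<- nL + 1
      invisible(NULL)
    }
    # name-sort a batch (read1 before read2, then rank), emit newly matched
    # pairs, return the unmatched remainder
    pairExtractSorted <- function(ids) {
      if (!length(ids)) return(integer(0))
      nm <- qn[ids]
      ends <- c(which(nm[-1L] != nm[-length(nm)]), length(nm))
      start <- 1L
      rest <- integer(0)
      for (e in ends) {
        g <- ids[start:e]
        start <- e + 1L
        if (length(g) >= 2L) {
          pg <- g[paired[g]]
          a <- pg[isR1[pg]]
          b <- pg[isR2[pg]]
          m <- min(length(a), length(b))
          if (m > 0L) {
            for (k in seq_len(m)) emitPair(a[k], b[k])
            g <- setdiff(g, c(a[seq_len(m)], b[seq_len(m)]))
          }
        }
        rest <- c(rest, g)
      }
      rest
    }
    # flush the overflow list: sort by name, extract newly discovered
    # pairs, write the remainder (in name order) to a new temporary run
    flushList <- function() {
      if (!length(Lidx)) return(invisible(NULL))
      ids <- Lidx[order(qn[Lidx], isR2[Lidx], rank[Lidx],
                        method = "radix")]
      Lidx <<- integer(0)
      Lbytes <<- 0
      rest <- pairExtractSorted(ids)
      if (length(rest)) {
        if (!dir.exists(tmpDir))
          dir.create(tmpDir, recursive = TRUE, showWarnings = FALSE)
        path <- tempfile("bamcollate_run_", tmpdir = tmpDir,
                         fileext = ".run")
        writeLines(c(.RUN_MAGIC,
                     paste(serLen[rest], rank[rest], ser[rest],
                           sep = "\t")), path)
        runs <<- c(runs, path)
      }
      invisible(NULL)
    }
    # move every record still in H over to L (oldest-first in ring order)
    # and flush L one final time
    finalize <- function() {
      while (length(Boff) > 0L) evictOldest()
      flushList()
      invisible(NULL)
    }
    # final merge: k-way merge of the name-sorted runs (hierarchical passes
    # when their number exceeds the fan-in); same-name complementary mates
    # become pairs, paired leftovers orphans, unpaired ones singles
    mergeRuns <- function() {
      paths <- runs
      if (!length(paths)) return(invisible(NULL))
      while (length(paths) > fanIn) {
        grp <- split(paths, ceiling(seq_along(paths) / fanIn))
        paths <- unname(vapply(grp, function(g) {
          if (length(g) == 1L) g else .mergeRunFiles(g, tmpDir)
        }, character(1)))
      }
      readers <- lapply(paths, .runReader)
      group <- integer(0)
      groupName <- NA_character_
      flushGroup <- function() {
        if (!length(group)) return()
        for (i in pairExtractSorted(group)) {
          if (paired[i]) emitOrphan(i) else emitSingle(i)
        }
      }
      repeat {
        active <- which(vapply(readers, .runHasNext, logical(1)))
        if (!length(active)) break
        a <- .minHead(readers, active)
        rd <- readers[[a]]
        nm <- rd$names[rd$pos]
        idx <- rd$rank[rd$pos] + 1L
        if (idx < 1L || idx > n || qn[idx] != nm)
          stop("corrupt temp run (rank/name mismatch): ", rd$path)
        .runAdvance(rd)
        if (!identical(nm, groupName)) {
          flushGroup()
          group <- idx
          groupName <- nm
        } else {
          group <- c(group, idx)
        }
      }
      flushGroup()
      unlink(paths)
      runs <<- character(0)
      invisible(NULL)
    }
    environment()
  })
  st
}

# thin named entry points into the state closures (unit-testable surface)
.hashInsert <- function(st, i) st$hashInsert(i)
.hashStore <- function(st, i) st$hashStore(i)
.hashErase <- function(st, s) st$hashErase(s)
.listInsert <- function(st, i) st$listInsert(i)
.flushList <- function(st) st$flushList()
.finalizeCollation <- function(st) st$finalize()

.mergeRuns <- function(st) {
  st$nRunsTotal <- length(st$runs)
  st$mergeRuns()
  invisible(st)
}

# ---------------------------------------------------------------------------
# temporary runs and multiway merge plumbing

# chunk-buffered reader over one run file; yields (name, r2, rank) heads
.runReader <- function(path, chunk = 512L) {
  rd <- new.env(parent = emptyenv())
  rd$path <- path
  rd$con <- file(path, "r")
  magic <- readLines(rd$con, n = 1L)
  if (!identical(magic, .RUN_MAGIC)) {
    close(rd$con)
    stop("corrupt temp run (bad magic): ", path)
  }
  rd$chunk <- chunk
  rd$names <- character(0); rd$r2 <- logical(0); rd$rank <- integer(0)
  rd$lines <- character(0)
  rd$pos <- 0L
  rd$lastName <- NA_character_
  rd$done <- FALSE
  .runRefill(rd)
  rd
}

.runRefill <- function(rd) {
  lines <- readLines(rd$con, n = rd$chunk)
  if (!length(lines)) {
    rd$done <- TRUE
    close(rd$con)
    return(invisible(rd))
  }
  sp <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(sp) < 13L)) {
    close(rd$con); rd$done <- TRUE
    stop("corrupt temp run (truncated record): ", rd$path)
  }
  len <- as.integer(vapply(sp, `[[`, character(1), 1L))
  rank <- as.integer(vapply(sp, `[[`, character(1), 2L))
  nm <- vapply(sp, `[[`, character(1), 3L)
  fl <- as.integer(vapply(sp, `[[`, character(1), 4L))
  body_len <- nchar(lines, type = "bytes") -
    nchar(paste(len, rank, "", sep = "\t"), type = "bytes")
  if (any(body_len != len)) {
    close(rd$con); rd$done <- TRUE
    stop("corrupt temp run (length prefix mismatch): ", rd$path)
  }
  # per-run sortedness check (bytewise name order)
  full_nm <- c(rd$lastName, nm)
  if (is.na(full_nm[1L])) full_nm <- full_nm[-1L]
  if (!identical(order(full_nm, seq_along(full_nm), method = "radix"),
                 seq_along(full_nm))) {
    close(rd$con); rd$done <- TRUE
    stop("unsorted temp run detected during merge: ", rd$path)
  }
  rd$names <- nm
  rd$r2 <- bitwAnd(fl, .FLAG_READ2) != 0L & bitwAnd(fl, .FLAG_READ1) == 0L
  rd$rank <- rank
  rd$lines <- lines
  rd$pos <- 1L
  rd$lastName <- nm[length(nm)]
  invisible(rd)
}

.runHasNext <- function(rd) !rd$done && rd$pos <= length(rd$names)

.runAdvance <- function(rd) {
  rd$pos <- rd$pos + 1L
  if (rd$pos > length(rd$names) && !rd$done) .runRefill(rd)
  invisible(rd)
}

# pick the reader (index) holding the minimal (name, r2, rank) head
.minHead <- function(readers, active) {
  nm <- vapply(active, function(a) readers[[a]]$names[readers[[a]]$pos],
               character(1))
  r2 <- vapply(active, function(a) readers[[a]]$r2[readers[[a]]$pos],
               logical(1))
  rk <- vapply(active, function(a) readers[[a]]$rank[readers[[a]]$pos],
               integer(1))
  active[order(nm, r2, rk, method = "radix")[1L]]
}

# merge run files into one new run (no pair extraction); used for
# hierarchical passes when the run count exceeds the fan-in
.mergeRunFiles <- function(paths, tmpDir) {
  out <- tempfile("bamcollate_run_", tmpdir = tmpDir, fileext = ".run")
  con <- file(out, "w")
  writeLines(.RUN_MAGIC, con)
  readers <- lapply(paths, .runReader)
  repeat {
    active <- which(vapply(readers, .runHasNext, logical(1)))
    if (!length(active)) break
    a <- .minHead(readers, active)
    writeLines(readers[[a]]$lines[readers[[a]]$pos], con)
    .runAdvance(readers[[a]])
  }
  close(con)
  unlink(paths)
  out
}

# ---------------------------------------------------------------------------

#' Collate alignments by read name within a fixed memory budget
#'
#' Streams the records of `x` in order. Secondary and supplementary
#' alignments bypass the pairing structures and are emitted as singles.
#' Every other record is offered to the collisionless hash table; a slot
#' already holding the record's mate yields an immediate pair, a slot
#' holding an unrelated record evicts that resident to the overflow list.
#' When the overflow list fills it is sorted by name, newly matched pairs
#' are extracted, and the remainder is written to a name-sorted temporary
#' run. After the input is exhausted the hash-table residue is flushed the
#' same way and the runs are merged to recover the remaining pairs; paired
#' leftovers become orphans, unpaired ones singles. Temporary runs are
#' deleted on successful completion.
#'
#' @param x An [AlignmentSet-class] or the path of a SAM/BAM file.
#' @param config A [CollationConfig-class].
#' @return A [CollationResult-class].
#' @examples
#' sim <- simulateAlignments(simProfile(genomeLen = 2e4, d = 4, seed = 7))
#' res <- collate(sim$alignments)
#' collationStats(res)
#' @export
setGeneric("collate", function(x, config = collationConfig())
  standardGeneric("collate"))

#' @rdname collate
#' @export
setMethod("collate", "character", function(x, config = collationConfig()) {
  collate(readAlignments(x), config)
})

#' @rdname collate
#' @export
setMethod("collate", "AlignmentSet", function(x, config = collationConfig()) {
  st <- .newCollationState(x, config)
  hi <- st$hashInsert
  es <- st$emitSingle
  elig <- st$elig
  for (i in seq_len(st$n)) {
    if (elig[i]) hi(i) else es(i)
  }
  st$finalize()
  nRuns <- length(st$runs)
  st$mergeRuns()
  nElig <- sum(elig)
  stats <- new("CollationStats", n = st$n, nH = nElig - st$nL, nL = st$nL,
               runs = nRuns, maxRingBytes = st$maxLive,
               maxListBytes = st$maxLocc)
  new("CollationResult", alignments = x,
      pairs = data.frame(first = st$p1[seq_len(st$np)],
                         second = st$p2[seq_len(st$np)],
                         seq = st$pSeq[seq_len(st$np)]),
      orphans = data.frame(idx = st$oIdx[seq_len(st$no)],
                           seq = st$oSeq[seq_len(st$no)]),
      singles = data.frame(idx = st$sIdx[seq_len(st$ns)],
                           seq = st$sSeq[seq_len(st$ns)]),
      stats = stats)
})

#' Expected number of alignments between the mates of a template
#'
#' In a coordinate-sorted alignment file the two mates of a template are
#' separated, on average, by `(d / l) * (t - l)` other alignments: read
#' ends start at a mean rate of `d / l` per forward-strand position, and
#' the two start points of a template lie `t - l` positions apart.
#'
#' @param d Mean sequencing depth.
#' @param t Mean absolute template length.
#' @param l Mean read length.
#' @return The expected in-file mate gap (a count of alignments).
#' @examples
#' expectedPairGap(45, 324, 101)   # ~99.4
#' @export
expectedPairGap <- function(d, t, l) {
  if (!(d > 0) || !(l > 0)) stop("d and l must be positive")
  if (t < l) stop("template length t must be >= read length l")
  (d / l) * (t - l)
}
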