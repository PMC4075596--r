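#' @import methods
NULL

.ALN_COLUMNS <- c("qname", "flag", "refId", "pos", "mapq", "cigar",
                  "mateRefId", "matePos", "tlen", "seq", "qual", "tags",
                  "rank")

#' AlignmentSet: an in-memory table of alignment records
#'
#' Container for parsed SAM/BAM records. Coordinates are stored 0-based
#' (`pos = -1` for unplaced records, matching `refId = -1`); SAM text I/O
#' converts to and from the 1-based text convention. Sequences and qualities
#' of records carrying the absent marker `*` are stored as empty strings.
#' Optional tags are carried as one opaque tab-joined string per record and
#' never interpreted. `rank` is the 0-based line number of each record in
#' its source, unique and increasing in read order.
#'
#' @slot records A `data.frame` with columns `qname`, `flag`, `refId`,
#'   `pos`, `mapq`, `cigar`, `mateRefId`, `matePos`, `tlen`, `seq`, `qual`,
#'   `tags`, `rank`.
#' @slot refInfo A `data.frame` with columns `refName`, `refLen` describing
#'   the reference dictionary.
#' @slot headerLines Character vector of verbatim `@`-header lines.
#' @export
setClass("AlignmentSet",
         slots = c(records = "data.frame",
                   refInfo = "data.frame",
                   headerLines = "character"))

setValidity("AlignmentSet", function(object) {
  rec <- object@records
  miss <- setdiff(.ALN_COLUMNS, names(rec))
  if (length(miss))
    return(paste("missing record columns:", paste(miss, collapse = ", ")))
  if (!all(c("refName", "refLen") %in% names(object@refInfo)))
    return("refInfo must have columns refName, refLen")
  if (nrow(rec)) {
    has_seq <- nzchar(rec$seq)
    bad <- has_seq & nzchar(rec$qual) & nchar(rec$seq) != nchar(rec$qual)
    if (any(bad))
      return(sprintf("seq/qual length mismatch at rank %d",
                     rec$rank[which(bad)[1]]))
    if (any((rec$refId == -1L) != (rec$pos == -1L)))
      return("pos must be -1 exactly when refId is -1")
    if (anyDuplicated(rec$rank))
      return("ranks must be unique")
    if (is.unsorted(rec$rank, strictly = TRUE))
      return("ranks must be strictly increasing in record order")
    if (any(rec$refId >= nrow(object@refInfo)))
      return("refId out of range of reference dictionary")
  }
  TRUE
})

#' @describeIn AlignmentSet Construct an AlignmentSet from a record table.
#' @param records Record `data.frame` (see slots).
#' @param refInfo Reference dictionary `data.frame` (`refName`, `refLen`).
#' @param headerLines Verbatim header lines (optional; regenerated when
#'   empty).
#' @export
AlignmentSet <- function(records, refInfo, headerLines = character(0)) {
  rownames(records) <- NULL
  if (!length(headerLines))
    headerLines <- c("@HD\tVN:1.6",
                     sprintf("@SQ\tSN:%s\tLN:%d", refInfo$refName,
                             as.integer(refInfo$refLen)))
  new("AlignmentSet", records = records, refInfo = refInfo,
      headerLines = headerLines)
}

#' @rdname AlignmentSet
#' @param x,object An `AlignmentSet`.
#' @export
setGeneric("alnRecords", function(x) standardGeneric("alnRecords"))

#' @rdname AlignmentSet
#' @export
setMethod("alnRecords", "AlignmentSet", function(x) x@records)

#' @rdname AlignmentSet
#' @export
setGeneric("refInfo", function(x) standardGeneric("refInfo"))

#' @rdname AlignmentSet
#' @export
setMethod("refInfo", "AlignmentSet", function(x) x@refInfo)

#' @rdname AlignmentSet
#' @export
setMethod("length", "AlignmentSet", function(x) nrow(x@records))

setMethod("show", "AlignmentSet", function(object) {
  cat(sprintf("AlignmentSet with %d alignments over %d reference(s)\n",
              nrow(object@records), nrow(object@refInfo)))
  if (nrow(object@records)) {
    n <- min(5L, nrow(object@records))
    print(utils::head(object@records[, c("qname", "flag", "refId", "pos",
                                         "cigar", "rank")], n))
    if (nrow(object@records) > n) cat("...\n")
  }
})

#' CollationConfig: memory budget for the collation engine
#'
#' Fixed sizes of the collation data structures: `hashSlots` slots in the
#' pointer table of the collisionless hash table, `ringBytes` bytes of ring
#' buffer backing it, `listBytes` bytes of two-ended overflow list, the
#' directory used for name-sorted temporary runs, and the maximum number of
#' runs merged in one pass (larger run counts trigger hierarchical merge
#' passes).
#'
#' @slot hashSlots Number of hash slots (>= 1).
#' @slot ringBytes Ring buffer capacity in bytes.
#' @slot listBytes Overflow list capacity in bytes.
#' @slot tmpDir Directory for temporary runs.
#' @slot mergeFanIn Maximum runs merged per pass (>= 2).
#' @export
setClass("CollationConfig",
         slots = c(hashSlots = "numeric", ringBytes = "numeric",
                   listBytes = "numeric", tmpDir = "character",
                   mergeFanIn = "numeric"))

setValidity("CollationConfig", function(object) {
  if (object@hashSlots < 1) return("hashSlots must be >= 1")
  if (object@ringBytes < 1) return("ringBytes must be positive")
  if (object@listBytes < 1) return("listBytes must be positive")
  if (object@mergeFanIn < 2) return("mergeFanIn must be >= 2")
  TRUE
})

#' @describeIn CollationConfig Constructor. Defaults (2^16 slots, 16 MiB
#'   ring, 32 MiB list) comfortably hold the transient mate backlog of
#'   whole-genome coordinate-sorted input. `tmpDir` honours the
#'   `BAMCOLLATE_TMPDIR` environment variable when set.
#' @param hashSlots,ringBytes,listBytes,tmpDir,mergeFanIn See slots.
#' @export
collationConfig <- function(hashSlots = 2^16, ringBytes = 16 * 2^20,
                            listBytes = 32 * 2^20,
                            tmpDir = Sys.getenv("BAMCOLLATE_TMPDIR",
                                                tempdir()),
                            mergeFanIn = 64) {
  new("CollationConfig", hashSlots = hashSlots, ringBytes = ringBytes,
      listBytes = listBytes, tmpDir = tmpDir, mergeFanIn = mergeFanIn)
}

setMethod("show", "CollationConfig", function(object) {
  cat(sprintf(paste0("CollationConfig: %g hash slots, %g ring bytes, ",
                     "%g list bytes, fan-in %g\n  tmpDir: %s\n"),
              object@hashSlots, object@ringBytes, object@listBytes,
              object@mergeFanIn, object@tmpDir))
})

#' CollationStats: counters from a collation run
#'
#' `n` counts every record consumed; `nH` the records resolved entirely
#' inside the hash table (never touching the overflow list); `nL` the
#' records routed through the overflow list (including records moved there
#' when the input was exhausted); `runs` the number of name-sorted temporary
#' runs written. `maxRingBytes` and `maxListBytes` are instrumentation
#' high-water marks of live ring-buffer bytes and overflow-list occupancy.
#'
#' @slot n,nH,nL,runs,maxRingBytes,maxListBytes Numeric counters.
#' @export
setClass("CollationStats",
         slots = c(n = "numeric", nH = "numeric", nL = "numeric",
                   runs = "numeric", maxRingBytes = "numeric",
                   maxListBytes = "numeric"))

setValidity("CollationStats", function(object) {
  if (object@nH + object@nL > object@n) return("nH + nL must not exceed n")
  if (object@runs < 0) return("runs must be >= 0")
  TRUE
})

setMethod("show", "CollationStats", function(object) {
  cat(sprintf(paste0("CollationStats: n=%g, nH=%g, nL=%g, runs=%g, ",
                     "maxRingBytes=%g, maxListBytes=%g\n"),
              object@n, object@nH, object@nL, object@runs,
              object@maxRingBytes, object@maxListBytes))
})

#' CollationResult: name-collated partition of an alignment stream
#'
#' Every eligible input record appears in exactly one output category:
#' `pairs` (two mates with complementary read1/read2 flags, emitted
#' read1-first), `orphans` (paired-flag records whose mate never appeared)
#' or `singles` (unpaired records, plus secondary/supplementary records
#' passed through without entering the pairing structures). Rows reference
#' records of `alignments` by 1-based row index; `seq` is the global
#' emission order.
#'
#' @slot alignments The input `AlignmentSet`.
#' @slot pairs `data.frame(first, second, seq)`.
#' @slot orphans `data.frame(idx, seq)`.
#' @slot singles `data.frame(idx, seq)`.
#' @slot stats A [CollationStats-class] object.
#' @export
setClass("CollationResult",
         slots = c(alignments = "AlignmentSet", pairs = "data.frame",
                   orphans = "data.frame", singles = "data.frame",
                   stats = "CollationStats"))

#' @rdname CollationResult-class
#' @param x,object A `CollationResult`.
#' @export
setGeneric("collatedPairs", function(x) standardGeneric("collatedPairs"))

#' @rdname CollationResult-class
#' @export
setMethod("collatedPairs", "CollationResult", function(x) x@pairs)

#' @rdname CollationResult-class
#' @export
setGeneric("collatedOrphans", function(x) standardGeneric("collatedOrphans"))

#' @rdname CollationResult-class
#' @export
setMethod("collatedOrphans", "CollationResult", function(x) x@orphans)

#' @rdname CollationResult-class
#' @export
setGeneric("collatedSingles", function(x) standardGeneric("collatedSingles"))

#' @rdname CollationResult-class
#' @export
setMethod("collatedSingles", "CollationResult", function(x) x@singles)

#' @rdname CollationResult-class
#' @export
setGeneric("collationStats", function(x) standardGeneric("collationStats"))

#' @rdname CollationResult-class
#' @export
setMethod("collationStats", "CollationResult", function(x) x@stats)

setMethod("show", "CollationResult", function(object) {
  cat(sprintf("CollationResult: %d pairs, %d orphans, %d singles\n",
              nrow(object@pairs), nrow(object@orphans),
              nrow(object@singles)))
  show(object@stats)
})

#' SimProfile: parameters of the paired-end alignment simulator
#'
#' Describes a sequencing experiment over `nRefs` synthetic references of
#' `genomeLen` bases each: target mean depth `d`, read length `l` (bases)
#' and template length drawn from a normal distribution with mean `tMean`
#' and sd `tSd`, truncated below at `l`. `dupRate` is the fraction of
#' ordinary templates seeding a planted PCR-duplicate cluster whose size is
#' 1 + Poisson(`lambdaDup`) extra copies; `orphanRate`, `splitRate` and
#' `singleRate` are the fractions of templates emitted as mate-unmapped
#' orphans, split pairs (mates on different references) and unpaired
#' single-end reads. `clipRate` soft-clips that fraction of reads (preserving
#' the unclipped 5' coordinate). `seed` fixes the output exactly.
#'
#' @slot genomeLen,nRefs,d,tMean,tSd,l Numeric simulation parameters.
#' @slot dupRate,lambdaDup,orphanRate,splitRate,singleRate,clipRate Numeric
#'   rates.
#' @slot seed Integer RNG seed.
#' @export
setClass("SimProfile",
         slots = c(genomeLen = "numeric", nRefs = "numeric", d = "numeric",
                   tMean = "numeric", tSd = "numeric", l = "numeric",
                   dupRate = "numeric", lambdaDup = "numeric",
                   orphanRate = "numeric", splitRate = "numeric",
                   singleRate = "numeric", clipRate = "numeric",
                   seed = "numeric"))

setValidity("SimProfile", function(object) {
  rates <- c(object@dupRate, object@orphanRate, object@splitRate,
             object@singleRate, object@clipRate)
  if (any(rates < 0 | rates > 1)) return("rates must lie in [0, 1]")
  if (object@orphanRate + object@splitRate + object@singleRate > 1)
    return("special-case rates must sum to at most 1")
  if (object@tMean < object@l) return("tMean must be >= read length l")
  if (object@splitRate > 0 && object@nRefs < 2)
    return("split pairs require at least two references")
  if (object@genomeLen < object@tMean)
    return("genomeLen must be >= tMean")
  if (object@l < 1 || object@genomeLen < 1 || object@nRefs < 1 ||
      object@d <= 0)
    return("genomeLen, nRefs, l must be >= 1 and d > 0")
  TRUE
})

#' @describeIn SimProfile Constructor. Defaults mirror a whole-genome
#'   Illumina paired-end experiment (depth 45, template length 324 +- 25,
#'   read length 101) on a small synthetic reference.
#' @param genomeLen,nRefs,d,tMean,tSd,l,dupRate,lambdaDup,orphanRate
#'   See slots.
#' @param splitRate,singleRate,clipRate,seed See slots.
#' @export
simProfile <- function(genomeLen = 1e5, nRefs = 1, d = 45, tMean = 324,
                       tSd = 25, l = 101, dupRate = 0, lambdaDup = 1,
                       orphanRate = 0, splitRate = 0, singleRate = 0,
                       clipRate = 0, seed = 1) {
  new("SimProfile", genomeLen = genomeLen, nRefs = nRefs, d = d,
      tMean = tMean, tSd = tSd, l = l, dupRate = dupRate,
      lambdaDup = lambdaDup, orphanRate = orphanRate,
      splitRate = splitRate, singleRate = singleRate, clipRate = clipRate,
      seed = seed)
}

setMethod("show", "SimProfile", function(object) {
  cat(sprintf(paste0("SimProfile: %g ref(s) x %g bp, depth %g, template ",
                     "%g +- %g, read length %g\n  rates: dup=%g ",
                     "(lambda=%g), orphan=%g, split=%g, single=%g, ",
                     "clip=%g; seed=%g\n"),
              object@nRefs, object@genomeLen, object@d, object@tMean,
              object@tSd, object@l, object@dupRate, object@lambdaDup,
              object@orphanRate, object@splitRate, object@singleRate,
              object@clipRate, object@seed))
})
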