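q30 <- function(n) strrep(intToUtf8(63), n)   # Phred 30
q10 <- function(n) strrep(intToUtf8(43), n)   # Phred 10 (below cutoff)
qOf <- function(phred, n) strrep(intToUtf8(33 + phred), n)

test_that("the unclipped 5' coordinate extrapolates through clipping", {
  fwd <- mkRec("f", flag = 0L, pos = 100L, cigar = "50M",
               seq = strrep("A", 50), qual = q30(50))
  expect_equal(fragCoord(fwd)$pos5, 100L)
  rev <- mkRec("r", flag = 0x10L, pos = 100L, cigar = "50M",
               seq = strrep("A", 50), qual = q30(50))
  expect_equal(fragCoord(rev)$pos5, 149L)    # 100 + span 50 - 1
  clip <- mkRec("c", flag = 0L, pos = 100L, cigar = "5S45M",
                seq = strrep("A", 50), qual = q30(50))
  expect_equal(fragCoord(clip)$pos5, 95L)
  rclip <- mkRec("rc", flag = 0x10L, pos = 100L, cigar = "45M5S",
                 seq = strrep("A", 50), qual = q30(50))
  expect_equal(fragCoord(rclip)$pos5, 149L)  # 100 + 45 - 1 + 5
  expect_equal(fragCoord(rev)$strand, 1L)
  expect_error(fragCoord(mkRec("u", flag = 4L, refId = -1L, pos = -1L,
                               cigar = "*", seq = "", qual = "")),
               "unmapped")
})

test_that("scores sum base qualities at or above Phred 15", {
  expect_equal(fragScore(qOf(30, 10)), 300)
  expect_equal(fragScore(qOf(10, 10)), 0)
  expect_equal(fragScore(""), 0)
  expect_equal(fragScore(paste0(qOf(30, 3), qOf(14, 2), qOf(15, 1))), 105)
  expect_equal(pairScore(qOf(30, 10), qOf(20, 5)), 400)
})

test_that("list generation fills the pair and fragment lists per category", {
  x <- mkSet(rbind(mkPair("pp"), mkOrphan("oo", pos = 500L)))
  lists <- bamcollate:::.buildDupLists(collate(x))
  expect_equal(nrow(lists$LP), 1L)
  expect_equal(sum(lists$LS$isPair), 2L)
  expect_equal(sum(!lists$LS$isPair), 1L)
  # empty input
  e <- bamcollate:::.buildDupLists(collate(mkSet(mkRec()[0, ])))
  expect_equal(nrow(e$LP), 0L)
  expect_equal(nrow(e$LS), 0L)
})

test_that("fragment marking keeps the best entry and defers to pair ends", {
  LS <- data.frame(code = c(5, 5), score = c(300, 200), rank = c(0L, 1L),
                   isPair = FALSE)
  expect_equal(markFragmentDuplicates(LS), 1L)     # the score-200 single
  # a single at a mapped pair's end coordinate is marked unconditionally
  LS2 <- data.frame(code = c(5, 5), score = c(10, 9999), rank = c(0L, 7L),
                    isPair = c(TRUE, FALSE))
  expect_equal(markFragmentDuplicates(LS2), 7L)
  # a lone single at its own coordinate is kept
  LS3 <- data.frame(code = 9, score = 1, rank = 3L, isPair = FALSE)
  expect_equal(markFragmentDuplicates(LS3), integer(0))
  # ties resolved toward the lowest rank
  LS4 <- data.frame(code = c(2, 2), score = c(50, 50), rank = c(4L, 1L),
                    isPair = FALSE)
  expect_equal(markFragmentDuplicates(LS4), 4L)
  LSbad <- data.frame(code = c(9, 5), score = c(1, 1), rank = c(0L, 1L),
                      isPair = FALSE)
  expect_error(markFragmentDuplicates(LSbad), "not coordinate-sorted")
})

test_that("pair marking keeps one representant per coordinate class", {
  LP <- data.frame(code1 = c(1, 1, 1), code2 = c(9, 9, 9),
                   score = c(10, 20, 15),
                   rank1 = c(0L, 2L, 4L), rank2 = c(1L, 3L, 5L))
  expect_equal(markPairDuplicates(LP), c(0L, 1L, 4L, 5L))
  # different right coordinate -> distinct classes, nothing marked
  LP2 <- data.frame(code1 = c(1, 1), code2 = c(9, 11), score = c(5, 5),
                    rank1 = c(0L, 2L), rank2 = c(1L, 3L))
  expect_equal(markPairDuplicates(LP2), integer(0))
  # tied maxima: the lowest-rank pair is the representant
  LP3 <- data.frame(code1 = c(1, 1), code2 = c(9, 9), score = c(20, 20),
                    rank1 = c(6L, 2L), rank2 = c(7L, 3L))
  expect_equal(markPairDuplicates(LP3), c(6L, 7L))
  expect_error(markPairDuplicates(LP2[2:1, ]), "not coordinate-sorted")
})

test_that("spilling flushes the lowest coordinate and preserves results", {
  LS <- data.frame(code = c(5, 5, 9), score = c(1, 2, 3), rank = 0:2,
                   isPair = FALSE, seq = 1:3)
  LP <- data.frame(code1 = numeric(0), code2 = numeric(0),
                   score = numeric(0), rank1 = integer(0),
                   rank2 = integer(0), seq = integer(0))
  got <- bamcollate:::.spillProcess(list(LS = LS, LP = LP), threshold = 2,
                                    tmpDir = tempfile("spill"))
  expect_equal(got$spilled, 1L)                   # coordinate 5 went out
  expect_setequal(got$LS$rank, 0:2)               # nothing lost
  # threshold >= n: no spill at all
  got2 <- bamcollate:::.spillProcess(list(LS = LS, LP = LP),
                                     threshold = 10,
                                     tmpDir = tempfile("spill"))
  expect_equal(got2$spilled, 0L)
})

test_that("marked ranks equal the all-pairs oracle on small files", {
  mkCase <- function(seed) {
    simulateAlignments(simProfile(genomeLen = 1500, d = 3, l = 30,
                                  tMean = 100, tSd = 10, seed = seed,
                                  dupRate = 0.25, lambdaDup = 1.5,
                                  orphanRate = 0.1, singleRate = 0.1))
  }
  for (seed in c(71, 72, 73)) {
    sim <- mkCase(seed)
    rec <- alnRecords(sim$alignments)
    expect_lte(nrow(rec), 250)
    got <- computeDuplicateRanks(sim$alignments)
    expect_identical(got$ranks, oracleMarkDup(rec))
  }
  # clipped duplicates still collapse onto one coordinate
  simC <- simulateAlignments(simProfile(genomeLen = 3e3, d = 4, l = 30,
                                        tMean = 100, tSd = 10, seed = 74,
                                        dupRate = 0.3, clipRate = 0.3))
  gotC <- computeDuplicateRanks(simC$alignments)
  expect_identical(gotC$ranks, oracleMarkDup(alnRecords(simC$alignments)))
  expect_identical(gotC$ranks, truthExpectedDuplicates(simC))
})

test_that("marking recovers exactly the planted duplicates", {
  sim <- simulateAlignments(simProfile(genomeLen = 5e4, d = 8, l = 50,
                                       tMean = 200, seed = 81,
                                       dupRate = 0.15, lambdaDup = 1,
                                       orphanRate = 0.05,
                                       singleRate = 0.05))
  got <- computeDuplicateRanks(sim$alignments)
  expect_identical(got$ranks, truthExpectedDuplicates(sim))
  # exactly one unmarked representant per multi-member cluster
  rec <- alnRecords(sim$alignments)
  tr <- sim$truth
  markedNames <- unique(rec$qname[rec$rank %in% got$ranks])
  for (cl in names(which(table(tr$cluster) > 1L))) {
    g <- tr$name[tr$cluster == as.integer(cl)]
    expect_equal(sum(!g %in% markedNames), 1L)
  }
})

test_that("the marked set is invariant to the spill threshold", {
  sim <- simulateAlignments(simProfile(genomeLen = 1e4, d = 6, l = 40,
                                       tMean = 150, seed = 91,
                                       dupRate = 0.2, orphanRate = 0.1,
                                       singleRate = 0.1))
  ref <- computeDuplicateRanks(sim$alignments, threshold = Inf)
  for (th in c(1, 8)) {
    expect_identical(computeDuplicateRanks(sim$alignments,
                                           threshold = th)$ranks,
                     ref$ranks)
  }
})

test_that("markDuplicates rewrites only the FLAG field and is idempotent", {
  sim <- simulateAlignments(simProfile(genomeLen = 1e4, d = 6, l = 40,
                                       tMean = 150, seed = 95,
                                       dupRate = 0.2))
  rec <- alnRecords(sim$alignments)
  # plant stale duplicate flags: they must be cleared before marking
  rec$flag[1:5] <- bitwOr(rec$flag[1:5], 0x400L)
  x <- AlignmentSet(rec, refInfo(sim$alignments))
  inp <- writeSamFixture(x)
  out <- tempfile(fileext = ".sam")
  cnt <- markDuplicates(inp, out)
  expect_gt(cnt$dupReadsMarked, 0)
  inLines <- readLines(inp)
  outLines <- readLines(out)
  expect_equal(length(outLines), length(inLines))
  stripFlag <- function(l) sub("^([^\t]*)\t[^\t]*", "\\1\t", l)
  expect_identical(stripFlag(outLines), stripFlag(inLines))
  y <- readAlignments(out)
  marked <- alnRecords(y)$rank[flagDuplicate(alnRecords(y)$flag)]
  expect_identical(marked, computeDuplicateRanks(sim$alignments)$ranks)
  # idempotent: marking the marked file changes nothing
  out2 <- tempfile(fileext = ".sam")
  markDuplicates(out, out2)
  expect_identical(readLines(out2), outLines)
})

test_that("a duplicate-free file passes through with zero marks", {
  x <- mkSet(rbind(mkPair("a", pos1 = 10L, pos2 = 200L),
                   mkPair("b", pos1 = 50L, pos2 = 300L)))
  inp <- writeSamFixture(x)
  out <- tempfile(fileext = ".sam")
  cnt <- markDuplicates(inp, out)
  expect_equal(cnt$dupReadsMarked, 0)
  expect_identical(readLines(out), readLines(inp))
})

test_that("shuffling the input does not change the marked name set", {
  sim <- simulateAlignments(simProfile(genomeLen = 1e4, d = 6, l = 40,
                                       tMean = 150, seed = 97,
                                       dupRate = 0.2, singleRate = 0.1))
  rec <- alnRecords(sim$alignments)
  got <- computeDuplicateRanks(sim$alignments)
  set.seed(1)
  shuf <- rec[sample(nrow(rec)), ]
  shuf$rank <- seq_len(nrow(shuf)) - 1L
  y <- AlignmentSet(shuf, refInfo(sim$alignments))
  got2 <- computeDuplicateRanks(y)
  nameOf <- function(x, ranks) sort(unique(x$qname[x$rank %in% ranks]))
  expect_identical(nameOf(shuf, got2$ranks), nameOf(rec, got$ranks))
})
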