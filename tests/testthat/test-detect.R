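# fixture: contig with a planted repeat-spacer array and background margins
plantedContig <- function(repeatSeq, nCopies, spacerLen = c(28L, 38L),
                          pad = 300L, subRate = 0) {
  loc <- simLocus(repeatSeq, nCopies = nCopies, spacerLen = spacerLen,
                  subRate = subRate)
  list(seq = paste0(randSeq(pad), loc$seq, randSeq(pad)),
       loc = loc, offset = pad)
}

test_that("seed chains find planted periodic repeats and respect the gap window", {
  set.seed(201)
  r <- randSeq(30)
  ctg <- paste0(randSeq(100), r, randSeq(35), r, randSeq(35), r,
                randSeq(100))
  chains <- findSeedChains(ctg)
  expect_gt(length(chains), 0)
  expect_true(any(lengths(lapply(chains, `[[`, "starts")) == 3))
  # gaps of 200 bp exceed the repeat+spacer window: no chain
  far <- paste0(randSeq(50), r, randSeq(200), r, randSeq(200), r,
                randSeq(50))
  expect_length(findSeedChains(far), 0)
  # too-short contig: empty result with a notice
  expect_message(out <- findSeedChains(randSeq(40)), "shorter")
  expect_length(out, 0)
})

test_that("random sequence yields no persistent seed chains", {
  set.seed(202)
  nFalse <- 0L
  for (i in 1:20) {
    ctg <- randSeq(10000)
    arrays <- findCrisprs(ctg)
    nFalse <- nFalse + length(arrays)
  }
  expect_equal(nFalse, 0L)
})

test_that("boundary extension recovers planted repeat intervals exactly", {
  set.seed(203)
  r <- randSeq(32)
  p <- plantedContig(r, 5)
  chains <- findSeedChains(p$seq)
  lens <- lengths(lapply(chains, `[[`, "starts"))
  cand <- extendAndRefine(chains[[which.max(lens)]], p$seq)
  expect_equal(consensus(cand), r)
  truthStarts <- IRanges::start(p$loc$repeats) + p$offset
  expect_equal(IRanges::start(repeatRanges(cand)), truthStarts)
  # one substituted copy: consensus still the planted repeat, copy scored
  set.seed(204)
  loc <- simLocus(r, nCopies = 6)
  mut <- plantMismatches(substring(loc$seq, 1, 32), 1)
  ctg2 <- paste0(randSeq(200), mut, substring(loc$seq, 33), randSeq(200))
  arr <- findCrisprs(ctg2)[[1]]
  expect_equal(consensus(arr), r)
  expect_equal(S4Vectors::mcols(repeatRanges(arr))$mismatches[1], 1)
})

test_that("boundary error is within 1 bp on mutated arrays", {
  set.seed(205)
  within1 <- 0L
  for (i in 1:100) {
    r <- randSeq(32)
    loc <- simLocus(r, nCopies = sample(4:10, 1), subRate = 0.02)
    gen <- simGenome(list(loc), genomeLen = 3000)
    arrays <- findCrisprs(gen$seq)
    if (!length(arrays)) next
    a <- arrays[[1]]
    tl <- gen$truth$repeatStarts[[1]]
    errL <- abs(min(IRanges::start(repeatRanges(a))) - tl[1])
    errR <- abs(max(IRanges::end(repeatRanges(a))) - (tl[length(tl)] + 31))
    within1 <- within1 + (errL <= 1 && errR <= 1)
  }
  expect_gte(within1, 95)
})

test_that("array validation rejects for the stated enumerated reasons", {
  set.seed(206)
  r <- randSeq(30)
  sp <- randSeq(32)
  # two identical spacers
  ctg <- paste0(randSeq(50), r, sp, r, sp, r, randSeq(50))
  hits <- scanRepeat(ctg, r, maxMm = 0)
  rep <- IRanges::IRanges(hits$start, hits$end)
  S4Vectors::mcols(rep) <- S4Vectors::DataFrame(
    strand = hits$strand, mismatches = hits$mismatches,
    truncated = rep("none", nrow(hits)))
  gaps <- IRanges::IRanges(hits$end[-3] + 1, hits$start[-1] - 1)
  arr <- new("CrisprArray", contigId = "c", repeats = rep, spacers = gaps,
             consensus = r, avgMismatch = 0)
  v <- validateArray(arr, ctg)
  expect_false(v$accept)
  expect_equal(v$reason, "repeating_spacers")
  # dissimilar spacers of length 20 and 60 exceed the 2.5x size ratio
  ctg2 <- paste0(randSeq(50), r, randSeq(20), r, randSeq(60), r,
                 randSeq(50))
  hits2 <- scanRepeat(ctg2, r, maxMm = 0)
  rep2 <- IRanges::IRanges(hits2$start, hits2$end)
  S4Vectors::mcols(rep2) <- S4Vectors::DataFrame(
    strand = hits2$strand, mismatches = hits2$mismatches,
    truncated = rep("none", nrow(hits2)))
  gaps2 <- IRanges::IRanges(hits2$end[-3] + 1, hits2$start[-1] - 1)
  arr2 <- new("CrisprArray", contigId = "c", repeats = rep2,
              spacers = gaps2, consensus = r, avgMismatch = 0)
  v2 <- validateArray(arr2, ctg2)
  expect_false(v2$accept)
  expect_equal(v2$reason, "spacer_size")
  # planted valid arrays are all accepted
  set.seed(207)
  accepted <- 0L
  for (i in 1:50) {
    rr <- randSeq(sample(24:40, 1))
    gen <- simGenome(list(list(repeatSeq = rr, nCopies = sample(4:8, 1))),
                     genomeLen = 2500)
    arrays <- findCrisprs(gen$seq)
    accepted <- accepted +
      (length(arrays) == 1 && validateArray(arrays[[1]], gen$seq)$accept)
  }
  expect_equal(accepted, 50L)
})

test_that("incomplete repeats at contig ends are recovered and flagged", {
  set.seed(208)
  r <- randSeq(30)
  loc <- simLocus(r, nCopies = 5)
  # keep the last 12 bases of the first repeat copy at the contig start
  cut <- substring(loc$seq, 30 - 12 + 1)
  ctg <- paste0(cut, randSeq(300))
  arr <- findCrisprs(ctg)[[1]]
  expect_equal(nRepeats(arr), 5)
  tr <- S4Vectors::mcols(repeatRanges(arr))$truncated
  expect_equal(tr[1], "left")
  expect_equal(IRanges::width(repeatRanges(arr))[1], 12)
  expect_equal(nSpacers(arr), nRepeats(arr) - 1)
  # contig with full margins: no truncation flags
  gen <- simGenome(list(list(repeatSeq = r, nCopies = 5)),
                   genomeLen = 2000)
  arr2 <- findCrisprs(gen$seq)[[1]]
  expect_true(all(S4Vectors::mcols(repeatRanges(arr2))$truncated == "none"))
})

test_that("contigs cut mid-repeat recover the truncated element", {
  set.seed(209)
  recovered <- 0L
  for (i in 1:25) {
    r <- randSeq(30)
    loc <- simLocus(r, nCopies = 6)
    keep <- sample(5:25, 1)
    ctg <- paste0(substring(loc$seq, 30 - keep + 1), randSeq(300))
    arrays <- findCrisprs(ctg)
    if (length(arrays) == 1) {
      tr <- S4Vectors::mcols(repeatRanges(arrays[[1]]))$truncated
      recovered <- recovered +
        (tr[1] == "left" &&
           IRanges::width(repeatRanges(arrays[[1]]))[1] == keep)
    }
  }
  expect_gte(recovered, 23)
})

test_that("multiple planted arrays are found with exact coordinates", {
  set.seed(210)
  r1 <- randSeq(30); r2 <- randSeq(36)
  gen <- simGenome(list(list(repeatSeq = r1, nCopies = 5),
                        list(repeatSeq = r2, nCopies = 7)),
                   genomeLen = 8000)
  arrays <- findCrisprs(gen$seq, contigId = "g")
  expect_length(arrays, 2)
  cons <- vapply(arrays, consensus, character(1))
  expect_setequal(cons, c(r1, r2))
  for (i in 1:2) {
    a <- arrays[[i]]
    k <- which(gen$truth$consensus == consensus(a))
    expect_equal(IRanges::start(repeatRanges(a)),
                 gen$truth$repeatStarts[[k]])
  }
})

test_that("an array of 48 repeat copies is reported with 47 spacers", {
  set.seed(211)
  r <- randSeq(36)
  loc <- simLocus(r, nCopies = 48, spacerLen = c(30L, 30L))
  gen <- simGenome(list(loc), genomeLen = 5000)
  arrays <- findCrisprs(gen$seq)
  expect_length(arrays, 1)
  expect_equal(nRepeats(arrays[[1]]), 48)
  expect_equal(nSpacers(arrays[[1]]), 47)
  expect_equal(consensus(arrays[[1]]), r)
})

test_that("emitted arrays satisfy the structural invariants and GFF3 is deterministic", {
  set.seed(212)
  r <- randSeq(33)
  gen <- simGenome(list(list(repeatSeq = r, nCopies = 6, subRate = 0.01)),
                   genomeLen = 3000)
  arrays <- findCrisprs(gen$seq, contigId = "g1")
  a <- arrays[[1]]
  rep <- repeatRanges(a); sp <- spacerRanges(a)
  expect_equal(length(sp), length(rep) - 1)
  expect_true(all(IRanges::start(sp) == IRanges::end(rep)[-length(rep)] + 1))
  expect_true(all(IRanges::end(sp) == IRanges::start(rep)[-1] - 1))
  expect_true(all(S4Vectors::mcols(rep)$mismatches[
    S4Vectors::mcols(rep)$truncated == "none"] <= 3))
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  writeArraysGFF3(arrays, f1)
  writeArraysGFF3(findCrisprs(gen$seq, contigId = "g1"), f2)
  expect_identical(readLines(f1), readLines(f2))
  gff <- readLines(f1)
  expect_equal(gff[1], "##gff-version 3")
  expect_equal(sum(grepl("\tdirect_repeat\t", gff)), nRepeats(a))
  expect_equal(sum(grepl("\tspacer\t", gff)), nSpacers(a))
})
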