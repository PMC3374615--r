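mkRecords <- function(seqs, samples) {
  data.frame(spacerId = paste0("sp", seq_along(seqs)), seq = seqs,
             sampleId = samples, stringsAsFactors = FALSE)
}

test_that("deduplication is strand-canonical and conserves multiplicity", {
  set.seed(601)
  s <- randSeq(32)
  dd <- dedupeSpacers(mkRecords(c(s, revComp(s)), c("a", "b")))
  expect_equal(nrow(dd$unique), 1)
  expect_equal(dd$unique$multiplicity, 2)
  expect_equal(dd$unique$seq, canonicalSequence(s))
  # disjoint spacers map to themselves
  seqs <- vapply(1:5, function(i) randSeq(30), character(1))
  dd2 <- dedupeSpacers(mkRecords(seqs, rep("a", 5)))
  expect_equal(nrow(dd2$unique), 5)
  expect_equal(sum(dd2$unique$multiplicity), 5)
  # canonicalization is idempotent
  expect_identical(canonicalSequence(canonicalSequence(seqs)),
                   canonicalSequence(seqs))
  # multi-sample fixture: unique count equals planted distinct count
  set.seed(602)
  planted <- vapply(1:20, function(i) randSeq(32), character(1))
  obs <- sample(planted, 60, replace = TRUE)
  flip <- runif(60) < 0.5
  obs[flip] <- revComp(obs[flip])
  dd3 <- dedupeSpacers(mkRecords(obs, sample(c("s1", "s2", "s3"), 60,
                                             replace = TRUE)))
  expect_equal(nrow(dd3$unique), length(unique(canonicalSequence(obs))))
  expect_equal(sum(dd3$unique$multiplicity), 60)
})

test_that("spacer cluster counts are monotone in the identity threshold", {
  set.seed(603)
  fams <- vapply(1:30, function(i) randSeq(32), character(1))
  seqs <- unlist(lapply(fams, function(f)
    c(f, plantMismatches(f, 1), plantMismatches(f, 2))))
  names(seqs) <- paste0("s", seq_along(seqs))
  n98 <- length(representatives(clusterSpacers(seqs, 0.98)))
  n90 <- length(representatives(clusterSpacers(seqs, 0.90)))
  n80 <- length(representatives(clusterSpacers(seqs, 0.80)))
  expect_gte(n98, n90)
  expect_gte(n90, n80)
  # families with 1% internal and ~40%+ external divergence resolve at 90%
  expect_equal(n90, 30)
})

test_that("the sharing matrix counts samples and subjects correctly", {
  set.seed(604)
  s1 <- randSeq(32); s2 <- randSeq(32)
  rec <- mkRecords(c(s1, s1, s1, s2), c("a1", "a2", "b1", "b1"))
  meta <- data.frame(sample = c("a1", "a2", "b1"),
                     subject = c("A", "A", "B"),
                     site = c("tongue", "tongue", "stool"),
                     stringsAsFactors = FALSE)
  cl <- clusterSpacers(setNames(canonicalSequence(c(s1, s2)),
                                c("u1", "u2")), 0.98)
  sm <- sharingMatrix(rec, cl, meta)
  summ <- sharingSummary(sm)
  expect_equal(nrow(incidence(sm)), 2)
  i1 <- summ[summ$nSamples == 3, ]
  expect_equal(i1$nSubjects, 2)
  i2 <- summ[summ$nSamples == 1, ]
  expect_equal(i2$nSubjects, 1)
  # summary is sorted by subject count
  expect_true(!is.unsorted(rev(summ$nSubjects)))
  # unknown sample in the records is a hard error naming the offender
  recBad <- mkRecords(s1, "zz")
  expect_error(sharingMatrix(recBad, cl, meta), "zz")
  # empty records give an empty matrix
  sm0 <- sharingMatrix(rec[0, ], cl, meta)
  expect_equal(nrow(incidence(sm0)), 0)
})

test_that("proto-spacer search applies the 90 percent over 30 bp rule exactly", {
  set.seed(605)
  sp <- randSeq(30)
  g <- paste0(randSeq(400), sp, randSeq(400))
  hits <- findProtospacers(c(q = sp), c(g1 = g))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$start, 401)
  expect_equal(hits$alignedLen, 30)
  # 3 mismatches over 30 bp (identity 0.90) hits; 4 (0.867) does not
  g3 <- paste0(randSeq(100), plantMismatches(sp, 3), randSeq(100))
  expect_equal(nrow(findProtospacers(c(q = sp), c(g = g3))), 1)
  g4 <- paste0(randSeq(100), plantMismatches(sp, 4), randSeq(100))
  expect_equal(nrow(findProtospacers(c(q = sp), c(g = g4))), 0)
  # spacers shorter than the minimum aligned length are skipped
  expect_equal(nrow(findProtospacers(c(q = randSeq(25)), c(g = g))), 0)
})

test_that("proto-spacer search equals the brute-force window oracle", {
  set.seed(606)
  for (i in 1:200) {
    sp <- randSeq(sample(30:36, 1))
    g <- randSeq(300)
    if (i %% 2 == 0) {
      ins <- plantMismatches(sp, sample(0:4, 1))
      if (runif(1) < 0.5) ins <- revComp(ins)
      pos <- sample(300 - nchar(sp), 1)
      g <- paste0(substr(g, 1, pos), ins,
                  substr(g, pos + nchar(sp) + 1, 300))
    }
    got <- findProtospacers(c(q = sp), c(g = g))
    want <- oracleProtospacers(sp, g)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("start", "end", "strand", "mismatches")], want)
    }
  }
})

test_that("flanks are reported in proto-spacer orientation and padded at genome ends", {
  set.seed(607)
  sp <- randSeq(30)
  up <- randSeq(10); down <- randSeq(10)
  g <- paste0(randSeq(50), up, sp, down, randSeq(50))
  h <- findProtospacers(c(q = sp), c(g = g), flank = 10)
  expect_equal(h$flankUp, up)
  expect_equal(h$flankDown, down)
  # minus-strand plant: flanks are reverse-complemented accordingly
  gm <- paste0(randSeq(50), revComp(paste0(up, sp, down)), randSeq(50))
  hm <- findProtospacers(c(q = sp), c(g = gm), flank = 10)
  expect_equal(hm$strand, "-")
  expect_equal(hm$flankUp, up)
  expect_equal(hm$flankDown, down)
  # a proto-spacer at the genome edge gets N-padded flanks
  ge <- paste0(sp, randSeq(60))
  he <- findProtospacers(c(q = sp), c(g = ge), flank = 10)
  expect_equal(he$flankUp, strrep("N", 10))
})

test_that("PAM profiling recovers a planted downstream GG at frequency 1", {
  set.seed(608)
  spacers <- vapply(1:8, function(i) randSeq(32), character(1))
  names(spacers) <- paste0("s", 1:8)
  ph <- simPhage(spacers, pam = "GG", genomeLen = 3000)
  hits <- findProtospacers(spacers, c(phage = ph$seq))
  expect_equal(nrow(hits), 8)
  prof <- pamProfile(hits)
  expect_equal(prof$topDown$dinuc, "GG")
  expect_equal(prof$topDown$freq, 1.0)
  expect_equal(prof$topDown$pos, 1)
  # frequency columns sum to one
  expect_true(all(abs(colSums(prof$down) - 1) < 1e-9))
  # a single hit gives one-hot matrices
  prof1 <- pamProfile(hits[1, ])
  expect_true(all(prof1$up %in% c(0, 1)))
})

test_that("uniform random flanks show no dominant dinucleotide", {
  set.seed(609)
  n <- 1000
  fake <- data.frame(
    spacerId = paste0("s", 1:n), genomeId = "g", start = 1L, end = 30L,
    strand = "+", identity = 1, alignedLen = 30L, mismatches = 0L,
    flankUp = vapply(1:n, function(i) randSeq(10), character(1)),
    flankDown = vapply(1:n, function(i) randSeq(10), character(1)),
    stringsAsFactors = FALSE)
  prof <- pamProfile(fake)
  expect_lt(prof$topDown$freq, 0.2)
  expect_lt(prof$topUp$freq, 0.2)
})
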