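# build a CrisprArray by planting and detecting, for filter boundary tests
detectPlanted <- function(repeatLen, nCopies, subRate = 0) {
  r <- randSeq(repeatLen)
  gen <- simGenome(list(list(repeatSeq = r, nCopies = nCopies,
                             subRate = subRate)), genomeLen = 3000)
  arrays <- findCrisprs(gen$seq)
  stopifnot(length(arrays) == 1)
  arrays[[1]]
}

test_that("catalog selection enforces copy, length and mismatch bounds inclusively", {
  set.seed(501)
  a5 <- detectPlanted(30, 5)
  sel <- selectCrisprs(list(a5))
  expect_length(sel$accepted, 1)
  expect_equal(sel$reasons, "ok")
  # smallest accepted copy number is 4
  byCopies <- lapply(3:5, function(k) detectPlanted(30, k))
  reasons <- selectCrisprs(byCopies)$reasons
  expect_equal(reasons, c("too_few_copies", "ok", "ok"))
  # largest accepted repeat length is 40, smallest 24
  byLen <- lapply(c(23, 24, 40, 41), function(l) detectPlanted(l, 5))
  reasonsLen <- selectCrisprs(byLen)$reasons
  expect_equal(reasonsLen, c("repeat_length", "ok", "ok", "repeat_length"))
  # truncated copies do not count toward the copy minimum
  r <- randSeq(30)
  loc <- simLocus(r, nCopies = 4)
  ctg <- paste0(substring(loc$seq, 30 - 12 + 1), randSeq(300))
  arr <- findCrisprs(ctg)[[1]]
  expect_equal(nRepeats(arr), 4)  # 3 complete + 1 truncated
  expect_equal(selectCrisprs(list(arr))$reasons, "too_few_copies")
})

test_that("average mismatch at exactly 1.0 is accepted, above is rejected", {
  set.seed(502)
  r <- randSeq(30)
  spacers <- vapply(1:4, function(i) randSeq(32), character(1))
  mkArray <- function(mmPerCopy) {
    copies <- vapply(mmPerCopy, function(k) plantMismatches(r, k),
                     character(1))
    ctg <- paste0(randSeq(60),
                  paste0(paste0(copies[-5], spacers, collapse = ""),
                         copies[5]),
                  randSeq(60))
    arrays <- hitsToArrays(scanRepeat(ctg, r, maxMm = 3), ctg,
                           queryLen = 30)
    arrays[[1]]
  }
  atOne <- mkArray(c(1, 1, 1, 1, 1))      # avg exactly 1.0
  expect_equal(avgMismatch(atOne), 1.0)
  expect_equal(selectCrisprs(list(atOne))$reasons, "ok")
  above <- mkArray(c(2, 2, 1, 1, 1))      # avg 1.4
  expect_equal(selectCrisprs(list(above))$reasons, "avg_mismatch")
})

test_that("greedy clustering is orientation-aware and collapses a repeat with its reverse complement", {
  set.seed(503)
  s <- randSeq(36)
  cs <- clusterRepeats(c(a = s, b = revComp(s)), identity = 0.90)
  expect_length(representatives(cs), 1)
  expect_equal(length(unique(clusterMembers(cs)$cluster)), 1)
  # 1 difference in 36 positions (~0.97 identity) joins at 0.90
  s2 <- plantMismatches(s, 1)
  cs2 <- clusterRepeats(c(a = s, b = s2), identity = 0.90)
  expect_length(representatives(cs2), 1)
  # dissimilar sequences stay apart
  cs3 <- clusterRepeats(c(a = s, b = randSeq(36)), identity = 0.90)
  expect_length(representatives(cs3), 2)
})

test_that("variants within 12% divergence cluster to one consensus at 88% identity", {
  set.seed(504)
  base <- randSeq(36)
  # each variant within 2 substitutions of the base, so every pair is
  # within 4 of 36 positions (~11% divergence)
  variants <- c(base, vapply(1:13, function(i)
    plantMismatches(base, sample(1:2, 1)), character(1)))
  names(variants) <- paste0("v", 1:14)
  cs <- clusterRepeats(variants, identity = 0.88)
  expect_length(representatives(cs), 1)
})

test_that("every cluster member satisfies the identity constraint; representatives re-cluster to singletons", {
  set.seed(505)
  seqs <- vapply(1:25, function(i) {
    if (i <= 15) plantMismatches(randSeq(30), 0) else randSeq(34)
  }, character(1))
  names(seqs) <- paste0("s", 1:25)
  cs <- clusterRepeats(seqs, identity = 0.85)
  m <- clusterMembers(cs)
  for (i in seq_len(nrow(m))) {
    repSeq <- m$seq[match(m$cluster[i], m$id)]
    idt <- 1 - orientedDist(m$seq[i], repSeq)$oriented /
      max(nchar(m$seq[i]), nchar(repSeq))
    expect_gte(idt, 0.85 - 1e-9)
  }
  reps <- setNames(m$seq[match(representatives(cs), m$id)],
                   representatives(cs))
  cs2 <- clusterRepeats(reps, identity = 0.85)
  expect_length(representatives(cs2), length(reps))
})

test_that("the repeat network matches the all-pairs DP oracle on the printed consensuses", {
  reps <- knownRepeats()
  net <- buildNetwork(reps, maxDist = 10)
  ids <- names(reps)
  edges <- networkEdges(net)
  got <- paste(edges$idA, edges$idB)
  want <- character(0)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      d <- min(levDP(reps[[i]], reps[[j]]),
               levDP(reps[[i]], oracleRevComp(reps[[j]])))
      if (d <= 10) {
        pair <- sort(c(ids[i], ids[j]))
        want <- c(want, paste(pair[1], pair[2]))
      }
    }
  }
  expect_setequal(got, sort(want))
  # edge weights agree with the oracle distance
  for (k in seq_len(nrow(edges))) {
    a <- reps[[edges$idA[k]]]; b <- reps[[edges$idB[k]]]
    expect_equal(edges$distance[k],
                 min(levDP(a, b), levDP(a, oracleRevComp(b))))
  }
})

test_that("duplicate repeats give a distance-0 edge; distance 11 gives none", {
  set.seed(506)
  s <- randSeq(30)
  net <- buildNetwork(c(x = s, y = s), maxDist = 10)
  expect_equal(nrow(networkEdges(net)), 1)
  expect_equal(networkEdges(net)$distance, 0)
  # engineer a pair at oriented distance 11
  repeat {
    t <- plantMismatches(s, 11)
    if (min(levDP(s, t), levDP(s, oracleRevComp(t))) == 11) break
  }
  net2 <- buildNetwork(c(x = s, y = t), maxDist = 10)
  expect_equal(nrow(networkEdges(net2)), 0)
  # network export is readable
  tsv <- tempfile(fileext = ".tsv"); gml <- tempfile(fileext = ".graphml")
  writeNetwork(net, tsv = tsv, graphml = gml)
  expect_equal(nrow(utils::read.delim(tsv)), 1)
  expect_true(file.exists(gml))
})

test_that("body-site classification applies the rare and 10 percent rules", {
  totals <- c(plaque = 128, stool = 148, skin = 27)
  counts <- matrix(
    c(2, 1, 1,     # 4 samples in total: rare
      20, 3, 0,    # 15.6% plaque, 2% stool
      0, 16, 3,    # 10.8% stool, 11.1% skin
      5, 10, 1),   # 3.9%, 6.8%, 3.7%: unassigned
    nrow = 4, byrow = TRUE,
    dimnames = list(c("rare4", "plaqueOnly", "stoolSkin", "none"),
                    names(totals)))
  cls <- classifyBySite(counts, totals)
  expect_equal(unname(cls),
               c("rare", "plaque", "skin+stool", "unassigned"))
  expect_error(classifyBySite(counts, c(plaque = 128, stool = 0,
                                        skin = 27)),
               "positive")
})
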