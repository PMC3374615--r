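# Synthetic-data generator: plants CRISPR loci into mock genomes, simulates
# single-end shotgun reads, builds multi-sample communities with tiered
# spacer sharing, and plants proto-spacers with a PAM into mock phage
# genomes. Every generator returns the ground truth needed to score the
# detection, assembly and analytics modules.

.randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate <- function(seq, nSub) {
  if (nSub < 1L) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  pos <- sample(length(ch), nSub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# random spacers, mutually dissimilar and unlike the repeat
.randSpacers <- function(n, lenRange, repeatSeq, maxIdentity = 0.8,
                         maxTries = 200L) {
  out <- character(0)
  lens <- lenRange[1L]:lenRange[2L]
  for (i in seq_len(n)) {
    for (try in seq_len(maxTries)) {
      s <- .randSeq(lens[sample.int(length(lens), 1L)])
      okRep <- .seqIdentity(s, repeatSeq) < maxIdentity
      okPrev <- !length(out) ||
        all(.seqIdentity(s, out) < maxIdentity &
              .seqIdentity(revComp(s), out) < maxIdentity)
      if (okRep && okPrev) break
      if (try == maxTries) stop("could not draw a dissimilar spacer")
    }
    out <- c(out, s)
  }
  out
}

#' Simulate a CRISPR locus
#'
#' Builds a repeat-spacer-repeat... locus: \code{nCopies} copies of the
#' repeat (each copy independently substituted at \code{subRate} per base)
#' separated by random spacers whose pairwise identity is kept below 0.8 by
#' rejection.
#'
#' @param repeatSeq the planted repeat consensus.
#' @param nCopies number of repeat copies (>= 2).
#' @param spacerLen integer range \code{c(min, max)} of spacer lengths.
#' @param subRate per-copy, per-base substitution rate.
#' @param seed optional RNG seed (calls \code{set.seed}).
#' @return list with \code{seq}, \code{repeats} (\code{IRanges} of the
#'   copies within the locus), \code{spacers} (character vector),
#'   \code{consensus}.
#' @export
simLocus <- function(repeatSeq, nCopies = 6L, spacerLen = c(28L, 38L),
                     subRate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeatSeq <- normalizeSeq(repeatSeq)
  if (nCopies < 2L) stop("nCopies must be >= 2")
  if (spacerLen[1L] > spacerLen[2L]) stop("empty spacer length range")
  spacers <- .randSpacers(nCopies - 1L, spacerLen, repeatSeq)
  copies <- vapply(seq_len(nCopies), function(i)
    .mutate(repeatSeq, rbinom(1L, nchar(repeatSeq), subRate)),
    character(1))
  parts <- character(2L * nCopies - 1L)
  parts[seq(1L, by = 2L, length.out = nCopies)] <- copies
  if (nCopies > 1L)
    parts[seq(2L, by = 2L, length.out = nCopies - 1L)] <- spacers
  seq <- paste(parts, collapse = "")
  w <- nchar(parts)
  ends <- cumsum(w)
  starts <- ends - w + 1L
  ri <- seq(1L, by = 2L, length.out = nCopies)
  list(seq = seq, repeats = IRanges(starts[ri], ends[ri]),
       spacers = spacers, consensus = repeatSeq)
}

#' Simulate a genome with planted CRISPR loci
#'
#' An i.i.d. uniform background with loci inserted at non-overlapping
#' random positions (with a margin from the genome ends).
#'
#' @param loci list of locus specs; each a list of arguments for
#'   \code{\link{simLocus}} (or a ready-made \code{simLocus} result).
#' @param genomeLen background genome length before insertion.
#' @param margin minimum distance of a locus from either genome end.
#' @param seed optional RNG seed.
#' @return list with \code{seq} and \code{truth}, a data.frame with one row
#'   per locus (\code{start}, \code{end}, \code{consensus},
#'   \code{nCopies}) plus list-columns \code{spacers} and
#'   \code{repeatStarts}.
#' @export
simGenome <- function(loci, genomeLen = 10000L, margin = 200L,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  built <- lapply(loci, function(l) {
    if (is.list(l) && !is.null(l$seq)) l else do.call(simLocus, l)
  })
  bg <- .randSeq(genomeLen)
  lens <- vapply(built, function(l) nchar(l$seq), integer(1))
  # pick non-overlapping insertion points in the background
  for (try in seq_len(200L)) {
    pts <- sort(sample(seq(margin, genomeLen - margin), length(built)))
    if (length(pts) < 2L || all(diff(pts) > 2L * margin)) break
    if (try == 200L) stop("could not place loci without overlap; ",
                          "increase genomeLen or reduce loci")
  }
  pieces <- character(0)
  truthRows <- list()
  cursor <- 1L
  offset <- 0L
  for (i in seq_along(built)) {
    pieces <- c(pieces, substr(bg, cursor, pts[i] - 1L), built[[i]]$seq)
    lstart <- pts[i] + offset
    truthRows[[i]] <- list(start = lstart,
                           end = lstart + lens[i] - 1L,
                           consensus = built[[i]]$consensus,
                           nCopies = length(built[[i]]$repeats),
                           spacers = built[[i]]$spacers,
                           repeatStarts = start(built[[i]]$repeats) +
                             lstart - 1L)
    offset <- offset + lens[i]
    cursor <- pts[i]
  }
  pieces <- c(pieces, substr(bg, cursor, genomeLen))
  truth <- data.frame(
    start = vapply(truthRows, `[[`, numeric(1), "start"),
    end = vapply(truthRows, `[[`, numeric(1), "end"),
    consensus = vapply(truthRows, `[[`, character(1), "consensus"),
    nCopies = vapply(truthRows, `[[`, numeric(1), "nCopies"),
    stringsAsFactors = FALSE)
  truth$spacers <- lapply(truthRows, `[[`, "spacers")
  truth$repeatStarts <- lapply(truthRows, `[[`, "repeatStarts")
  list(seq = paste(pieces, collapse = ""), truth = truth)
}

#' Simulate single-end shotgun reads
#'
#' Uniform start positions, both strands equiprobable, substitution errors
#' only. The read count is \code{round(coverage * genomeLen / readLen)}.
#'
#' @param genome genome sequence (single string).
#' @param readLen read length.
#' @param coverage target fold coverage.
#' @param errorRate per-base substitution error rate.
#' @param seed optional RNG seed.
#' @param prefix read-name prefix.
#' @return \code{DNAStringSet} of reads named \code{<prefix>_<i>}.
#' @export
simReads <- function(genome, readLen = 100L, coverage = 50,
                     errorRate = 0, seed = NULL, prefix = "read") {
  if (!is.null(seed)) set.seed(seed)
  genome <- .asSingleSeq(genome)
  n <- nchar(genome)
  if (readLen > n) stop("readLen exceeds genome length")
  nReads <- round(coverage * n / readLen)
  if (nReads < 1L) return(DNAStringSet())
  starts <- sample(n - readLen + 1L, nReads, replace = TRUE)
  seqs <- substring(genome, starts, starts + readLen - 1L)
  rev <- runif(nReads) < 0.5
  seqs[rev] <- revComp(seqs[rev])
  if (errorRate > 0) {
    nErr <- rbinom(nReads, readLen, errorRate)
    for (i in which(nErr > 0L)) seqs[i] <- .mutate(seqs[i], nErr[i])
  }
  out <- DNAStringSet(seqs)
  names(out) <- paste0(prefix, "_", seq_len(nReads))
  out
}

#' Simulate a multi-sample community with tiered spacer sharing
#'
#' Each subject carries per-site CRISPR loci (one shared repeat consensus
#' across the community, as for a conserved streptococcal-type repeat);
#' spacer inventories are constructed so that re-samples of the same
#' subject and site share fraction \code{tiers[1]} of their spacers,
#' different sites of the same subject share \code{tiers[2]}, and different
#' subjects share \code{tiers[3]} (the fractions must be strictly
#' decreasing). Reads are then simulated per sample.
#'
#' @param nSubjects number of subjects.
#' @param sites character vector of body sites sampled per subject.
#' @param visits number of visits (re-samples) per subject and site.
#' @param tiers numeric vector \code{c(sameSite, crossSite, crossSubject)}
#'   of sharing fractions, strictly decreasing.
#' @param spacersPerSample spacers per CRISPR locus (array has one more
#'   repeat copy than spacers).
#' @param repeatSeq community repeat consensus (default: a random 36-mer).
#' @param spacerLen spacer length range.
#' @param genomePad background sequence added around each locus.
#' @param readLen,coverage,errorRate read simulation parameters.
#' @param seed optional RNG seed.
#' @return list with \code{reads} (named list of \code{DNAStringSet}, one
#'   per sample), \code{metadata} (data.frame: sample, subject, site,
#'   visit), \code{inventories} (named list of per-sample spacer vectors),
#'   \code{repeatSeq}.
#' @export
simCommunity <- function(nSubjects = 6L, sites = c("plaque", "tongue"),
                         visits = 2L, tiers = c(0.8, 0.2, 0.0),
                         spacersPerSample = 12L, repeatSeq = NULL,
                         spacerLen = c(30L, 36L), genomePad = 600L,
                         readLen = 100L, coverage = 30, errorRate = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!(tiers[1L] > tiers[2L] && tiers[2L] > tiers[3L]))
    stop("sharing tiers must be strictly decreasing")
  if (is.null(repeatSeq)) repeatSeq <- .randSeq(36L)
  S <- spacersPerSample
  # one pool of mutually dissimilar spacers for the whole community
  poolSize <- nSubjects * length(sites) * visits * S * 2L
  pool <- .randSpacers(poolSize, spacerLen, repeatSeq)
  cursor <- 0L
  draw <- function(n) {
    if (cursor + n > length(pool)) stop("spacer pool exhausted")
    out <- pool[(cursor + 1L):(cursor + n)]
    cursor <<- cursor + n
    out
  }
  nShared <- round(tiers[3L] * S)
  globalShared <- if (nShared > 0L) draw(nShared) else character(0)
  reads <- list(); meta <- list(); inv <- list()
  for (p in seq_len(nSubjects)) {
    base <- list()
    for (si in seq_along(sites)) {
      if (si == 1L) {
        base[[si]] <- c(globalShared, draw(S - length(globalShared)))
      } else {
        nCross <- round(tiers[2L] * S)
        kept <- sample(base[[1L]], nCross)
        base[[si]] <- c(kept, draw(S - nCross))
      }
    }
    for (si in seq_along(sites)) {
      current <- base[[si]]
      for (v in seq_len(visits)) {
        if (v > 1L) {
          nKeep <- round(tiers[1L] * S)
          current <- c(sample(current, nKeep), draw(S - nKeep))
        }
        sampleId <- sprintf("%s_v%d_p%d", sites[si], v, p)
        shuffled <- sample(current)
        locus <- .assembleLocusFromSpacers(repeatSeq, shuffled)
        genome <- paste0(.randSeq(genomePad), locus, .randSeq(genomePad))
        reads[[sampleId]] <- simReads(genome, readLen = readLen,
                                      coverage = coverage,
                                      errorRate = errorRate,
                                      prefix = sampleId)
        meta[[sampleId]] <- data.frame(
          sample = sampleId, subject = paste0("subject", p),
          site = sites[si], visit = v, stringsAsFactors = FALSE)
        inv[[sampleId]] <- shuffled
      }
    }
  }
  list(reads = reads, metadata = do.call(rbind, c(meta,
         list(make.row.names = FALSE))),
       inventories = inv, repeatSeq = repeatSeq)
}

.assembleLocusFromSpacers <- function(repeatSeq, spacers) {
  paste0(paste0(repeatSeq, spacers, collapse = ""), repeatSeq)
}

#' Simulate a phage genome with planted proto-spacers
#'
#' Spacers are embedded at non-overlapping random positions of a random
#' genome, each (optionally mutated) with the PAM placed immediately
#' adjacent on the downstream flank, on a random strand.
#'
#' @param spacers named character vector of spacer sequences to plant.
#' @param pam PAM motif placed immediately downstream of each proto-spacer
#'   (default "GG").
#' @param genomeLen genome length (must accommodate the spacers).
#' @param mismatches integer vector (recycled) of substitutions applied to
#'   each planted copy.
#' @param strands strand per planted spacer (\code{"+"}/\code{"-"});
#'   default random.
#' @param margin minimum distance between planted features and from ends.
#' @param seed optional RNG seed.
#' @return list with \code{seq} and \code{truth} (data.frame: spacerId,
#'   start, end, strand, mismatches -- coordinates of the proto-spacer
#'   itself, excluding the PAM).
#' @export
simPhage <- function(spacers, pam = "GG", genomeLen = 3000L,
                     mismatches = 0L, strands = NULL, margin = 20L,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spacers <- normalizeSeq(spacers)
  if (is.null(names(spacers)))
    names(spacers) <- paste0("spacer", seq_along(spacers))
  mismatches <- rep_len(as.integer(mismatches), length(spacers))
  if (is.null(strands))
    strands <- sample(c("+", "-"), length(spacers), replace = TRUE)
  inserts <- vapply(seq_along(spacers), function(i) {
    s <- .mutate(spacers[[i]], mismatches[i])
    block <- paste0(s, pam)  # PAM immediately downstream
    if (strands[i] == "+") block else revComp(block)
  }, character(1))
  need <- sum(nchar(inserts)) + (length(inserts) + 1L) * margin
  if (need > genomeLen)
    stop("genomeLen too small for the requested spacers")
  bgLen <- genomeLen - sum(nchar(inserts))
  bg <- .randSeq(bgLen)
  # place inserts left to right with random gaps
  slack <- bgLen - (length(inserts) + 1L) * margin
  gaps <- margin + diff(c(0L, sort(sample(0:slack, length(inserts),
                                          replace = TRUE))))
  pieces <- character(0)
  truth <- list()
  cursor <- 0L
  for (i in seq_along(inserts)) {
    pieces <- c(pieces, substr(bg, cursor + 1L, cursor + gaps[i]))
    cursor <- cursor + gaps[i]
    istart <- sum(nchar(pieces)) + 1L
    pieces <- c(pieces, inserts[i])
    L <- nchar(spacers[[i]])
    if (strands[i] == "+") {
      pstart <- istart; pend <- istart + L - 1L
    } else {
      pstart <- istart + nchar(pam); pend <- istart + nchar(pam) + L - 1L
    }
    truth[[i]] <- data.frame(spacerId = names(spacers)[i], start = pstart,
                             end = pend, strand = strands[i],
                             mismatches = mismatches[i],
                             stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, substr(bg, cursor + 1L, bgLen))
  list(seq = paste(pieces, collapse = ""),
       truth = do.call(rbind, truth))
}
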