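# Spacer-level analytics: strand canonicalization and deduplication,
# identity clustering, cross-sample sharing, proto-spacer search against
# phage/plasmid genomes and PAM flank profiling.

#' Canonical spacer orientation
#'
#' Because the strand of an assembled spacer is arbitrary, uniqueness is
#' defined on the lexicographic minimum of a sequence and its reverse
#' complement.
#'
#' @param x character vector of sequences.
#' @return character vector of canonical sequences.
#' @export
canonicalSequence <- function(x) {
  if (!length(x)) return(character(0))
  rc <- revComp(x)
  ifelse(x <= rc, x, rc)
}

#' Deduplicate spacer records
#'
#' Collapses spacer records to unique canonical sequences, preserving total
#' multiplicity and per-sample counts.
#'
#' @param records data.frame with at least \code{spacerId}, \code{seq} and
#'   \code{sampleId} columns (see \code{\link{sharingMatrix}} for the full
#'   record layout).
#' @return list with \code{unique} (data.frame: \code{id} -- the first
#'   spacerId seen, \code{seq} -- canonical sequence, \code{multiplicity})
#'   and \code{bySample} (data.frame: \code{seq}, \code{sampleId},
#'   \code{count}).
#' @export
dedupeSpacers <- function(records) {
  stopifnot(all(c("spacerId", "seq", "sampleId") %in% colnames(records)))
  canon <- canonicalSequence(normalizeSeq(records$seq))
  first <- !duplicated(canon)
  uniq <- data.frame(id = records$spacerId[first], seq = canon[first],
                     multiplicity = as.integer(table(canon)[canon[first]]),
                     stringsAsFactors = FALSE)
  bySample <- as.data.frame(table(seq = canon, sampleId = records$sampleId),
                            stringsAsFactors = FALSE)
  bySample <- bySample[bySample$Freq > 0L, , drop = FALSE]
  names(bySample)[3L] <- "count"
  rownames(bySample) <- NULL
  list(unique = uniq, bySample = bySample)
}

#' Cluster spacers by identity
#'
#' Greedy orientation-aware identity clustering of (unique) spacers; the
#' same algorithm as \code{\link{clusterRepeats}}. Typical thresholds are
#' 0.98, 0.90 and 0.80; cluster counts are monotone non-increasing as the
#' threshold is lowered.
#'
#' @param seqs named character vector of spacer sequences.
#' @param identity identity threshold (default 0.90).
#' @return a \code{\link{ClusterSet}}.
#' @export
clusterSpacers <- function(seqs, identity = 0.90) {
  clusterRepeats(seqs, identity = identity)
}

#' Build the spacer sharing matrix
#'
#' Binary incidence of spacer clusters across samples, with per-cluster
#' sample and subject counts. Every sample appearing in the records must be
#' present in the metadata.
#'
#' @param records data.frame of spacer records with columns \code{spacerId},
#'   \code{seq}, \code{sampleId}.
#' @param clusters a \code{\link{ClusterSet}} over the canonical unique
#'   spacer sequences (member ids or seqs must cover the records'
#'   canonical sequences).
#' @param metadata data.frame with columns \code{sample}, \code{subject},
#'   \code{site}.
#' @return a \code{\link{SharingMatrix}}; its summary is sorted by
#'   decreasing subject count, then sample count.
#' @export
sharingMatrix <- function(records, clusters, metadata) {
  stopifnot(all(c("sample", "subject", "site") %in% colnames(metadata)))
  missing <- setdiff(unique(records$sampleId), metadata$sample)
  if (length(missing))
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  samples <- sort(unique(metadata$sample))
  members <- clusterMembers(clusters)
  if (!nrow(records)) {
    inc <- matrix(0L, 0L, length(samples),
                  dimnames = list(NULL, samples))
    return(new("SharingMatrix", incidence = inc,
               summary = data.frame(cluster = character(0),
                                    nSamples = integer(0),
                                    nSubjects = integer(0)),
               metadata = metadata))
  }
  canon <- canonicalSequence(normalizeSeq(records$seq))
  cl <- members$cluster[match(canon, members$seq)]
  if (anyNA(cl))
    stop("records contain spacers absent from the cluster set")
  clusterIds <- unique(members$cluster)
  inc <- matrix(0L, length(clusterIds), length(samples),
                dimnames = list(clusterIds, samples))
  inc[cbind(match(cl, clusterIds), match(records$sampleId, samples))] <- 1L
  inc <- inc[rowSums(inc) > 0L, , drop = FALSE]
  subj <- metadata$subject[match(colnames(inc), metadata$sample)]
  summ <- data.frame(
    cluster = rownames(inc),
    nSamples = as.integer(rowSums(inc)),
    nSubjects = apply(inc, 1L, function(r) length(unique(subj[r > 0L]))),
    stringsAsFactors = FALSE)
  summ <- summ[order(-summ$nSubjects, -summ$nSamples, summ$cluster), ,
               drop = FALSE]
  rownames(summ) <- NULL
  new("SharingMatrix", incidence = inc, summary = summ, metadata = metadata)
}

#' Search spacers against phage/plasmid genomes for proto-spacers
#'
#' Gapless similarity search of each spacer against each genome on both
#' strands: every full-length window with identity at or above
#' \code{minIdentity} over an aligned block of at least \code{minLen} bases
#' is a candidate proto-spacer; overlapping candidates from one spacer and
#' genome are reduced to the best (highest identity, ties leftmost).
#' Computed as an exact all-window mismatch scan, so the output is the
#' brute-force hit set by construction.
#'
#' @param spacers named character vector of spacer sequences.
#' @param genomes named character vector or \code{DNAStringSet} of
#'   phage/plasmid genomes.
#' @param minIdentity minimum identity over the aligned block (default
#'   0.90).
#' @param minLen minimum aligned length (default 30; shorter spacers are
#'   skipped).
#' @param flank length of the flanking sequence reported on each side, in
#'   proto-spacer orientation (default 10); flanks beyond genome ends are
#'   padded with N.
#' @return data.frame with columns \code{spacerId}, \code{genomeId},
#'   \code{start}, \code{end} (1-based inclusive), \code{strand},
#'   \code{identity}, \code{alignedLen}, \code{mismatches},
#'   \code{flankUp}, \code{flankDown}.
#' @export
findProtospacers <- function(spacers, genomes, minIdentity = 0.90,
                             minLen = 30L, flank = 10L) {
  if (is(genomes, "DNAStringSet"))
    genomes <- setNames(as.character(genomes), names(genomes))
  if (!length(genomes)) stop("genomes must be non-empty")
  if (is.null(names(genomes)))
    names(genomes) <- paste0("genome", seq_along(genomes))
  spacers <- normalizeSeq(spacers)
  if (is.null(names(spacers)))
    names(spacers) <- paste0("spacer", seq_along(spacers))
  rows <- list()
  padFlank <- function(g, from, to) {
    n <- nchar(g)
    lo <- max(1L, from); hi <- min(n, to)
    core <- if (lo > hi) "" else substr(g, lo, hi)
    paste0(strrep("N", max(0L, 1L - from)), core,
           strrep("N", max(0L, to - n)))
  }
  for (sid in names(spacers)) {
    sp <- spacers[[sid]]
    L <- nchar(sp)
    if (L < minLen) next
    for (gid in names(genomes)) {
      g <- normalizeSeq(genomes[[gid]])
      cand <- NULL
      for (strand in c("+", "-")) {
        q <- if (strand == "+") sp else revComp(sp)
        mm <- mismatchScan(g, q)
        ok <- which((L - mm) / L >= minIdentity - 1e-9)
        if (length(ok))
          cand <- rbind(cand, data.frame(
            start = ok, end = ok + L - 1L, strand = strand,
            mismatches = mm[ok], stringsAsFactors = FALSE))
      }
      if (is.null(cand) || !nrow(cand)) next
      # reduce overlapping candidates to the best (max identity, leftmost)
      cand <- cand[order(cand$start, cand$mismatches), , drop = FALSE]
      grp <- cumsum(c(1L, as.integer(
        cand$start[-1L] > cummax(cand$end)[-nrow(cand)])))
      keep <- vapply(split(seq_len(nrow(cand)), grp), function(ix) {
        ix[which.min(cand$mismatches[ix])]
      }, integer(1))
      cand <- cand[sort(keep), , drop = FALSE]
      up <- ifelse(cand$strand == "+",
                   vapply(seq_len(nrow(cand)), function(i)
                     padFlank(g, cand$start[i] - flank, cand$start[i] - 1L),
                     character(1)),
                   vapply(seq_len(nrow(cand)), function(i)
                     revComp(padFlank(g, cand$end[i] + 1L,
                                      cand$end[i] + flank)), character(1)))
      down <- ifelse(cand$strand == "+",
                     vapply(seq_len(nrow(cand)), function(i)
                       padFlank(g, cand$end[i] + 1L, cand$end[i] + flank),
                       character(1)),
                     vapply(seq_len(nrow(cand)), function(i)
                       revComp(padFlank(g, cand$start[i] - flank,
                                        cand$start[i] - 1L)), character(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        spacerId = sid, genomeId = gid, start = cand$start, end = cand$end,
        strand = cand$strand,
        identity = (L - cand$mismatches) / L, alignedLen = L,
        mismatches = cand$mismatches, flankUp = up, flankDown = down,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(spacerId = character(0), genomeId = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0),
                      alignedLen = integer(0), mismatches = integer(0),
                      flankUp = character(0), flankDown = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PAM profile of proto-spacer flanks
#'
#' Per-position base frequency matrices of the upstream and downstream
#' flanks of a proto-spacer hit set (in proto-spacer orientation), plus the
#' top dinucleotide per flank: the dinucleotide with the highest frequency
#' at any adjacent position pair (N-containing pairs are excluded from the
#' denominator; excluded N mass is reported per position).
#'
#' @param hits data.frame from \code{\link{findProtospacers}}.
#' @return list with \code{up} and \code{down} (4 x flank frequency
#'   matrices over A,C,G,T; columns sum to 1 where any non-N base was
#'   observed), \code{nMassUp}/\code{nMassDown} (fraction of N per
#'   position) and \code{topUp}/\code{topDown} (list: \code{dinuc},
#'   \code{freq}, \code{pos}).
#' @export
pamProfile <- function(hits) {
  if (!nrow(hits)) stop("need at least one proto-spacer hit")
  profile <- function(flanks) {
    flanks <- flanks[nchar(flanks) > 0L]
    w <- max(nchar(flanks))
    mat <- matrix(0, 4L, w, dimnames = list(c("A", "C", "G", "T"), NULL))
    nMass <- numeric(w)
    chars <- do.call(rbind, strsplit(format(flanks, width = w), ""))
    chars[chars == " "] <- "N"
    for (p in seq_len(w)) {
      col <- chars[, p]
      nMass[p] <- mean(col == "N")
      tab <- table(factor(col[col != "N"], levels = c("A", "C", "G", "T")))
      if (sum(tab) > 0L) mat[, p] <- as.numeric(tab) / sum(tab)
    }
    # dinucleotide frequencies at each adjacent position pair
    top <- list(dinuc = NA_character_, freq = 0, pos = NA_integer_)
    if (w >= 2L) {
      for (p in seq_len(w - 1L)) {
        d <- paste0(chars[, p], chars[, p + 1L])
        d <- d[!grepl("N", d, fixed = TRUE)]
        if (!length(d)) next
        tab <- sort(table(d), decreasing = TRUE) / length(d)
        if (tab[1L] > top$freq)
          top <- list(dinuc = names(tab)[1L], freq = as.numeric(tab[1L]),
                      pos = p)
      }
    }
    if (all(nMass == 1)) stop("all flank bases are N")
    list(freq = mat, nMass = nMass, top = top)
  }
  up <- profile(hits$flankUp)
  down <- profile(hits$flankDown)
  list(up = up$freq, down = down$freq,
       nMassUp = up$nMass, nMassDown = down$nMass,
       topUp = up$top, topDown = down$top)
}
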