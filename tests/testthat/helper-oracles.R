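# Independent oracles and fixture builders. Everything here is written
# against the stated contracts with its own code paths (character-vector
# arithmetic, full DP matrices, explicit window loops) so that it never
# shares logic with the implementations it checks.

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracleRevComp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# hamming with the N-mismatches-everything policy
oracleHamming <- function(x, y) {
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  sum(xs != ys | xs == "N" | ys == "N")
}

# full O(nm) dynamic-programming edit distance (N matches nothing)
levDP <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n; D[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- D[i, j] + as.integer(A[i] != B[j] || A[i] == "N" || B[j] == "N")
    D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1L, D[i + 1L, j] + 1L, sub)
  }
  D[n + 1L, m + 1L]
}

# brute-force repeat scan: every window on both strands, then the stated
# same-strand overlap reduction (transitive clusters of starts closer than
# half a query length; keep min mismatches, ties leftmost)
oracleScan <- function(target, query, maxMm) {
  m <- nchar(query)
  hits <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else oracleRevComp(query)
    for (i in seq_len(nchar(target) - m + 1L)) {
      mm <- oracleHamming(substr(target, i, i + m - 1L), q)
      if (mm <= maxMm)
        hits <- rbind(hits, data.frame(start = i, end = i + m - 1L,
                                       strand = strand, mismatches = mm,
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(hits)) return(hits)
  out <- NULL
  for (strand in unique(hits$strand)) {
    h <- hits[hits$strand == strand, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    cluster <- list(h[1L, ])
    flush <- function(cl) {
      cl <- do.call(rbind, cl)
      cl[which.min(cl$mismatches), , drop = FALSE]
    }
    if (nrow(h) > 1L) {
      for (i in 2L:nrow(h)) {
        if (h$start[i] - h$start[i - 1L] < m / 2) {
          cluster[[length(cluster) + 1L]] <- h[i, ]
        } else {
          out <- rbind(out, flush(cluster))
          cluster <- list(h[i, ])
        }
      }
    }
    out <- rbind(out, flush(cluster))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force recruitment decision for one read
oracleRecruited <- function(read, query, maxMm) {
  m <- nchar(query)
  if (nchar(read) < m) return(FALSE)
  for (q in c(query, oracleRevComp(query))) {
    for (i in seq_len(nchar(read) - m + 1L)) {
      if (oracleHamming(substr(read, i, i + m - 1L), q) <= maxMm)
        return(TRUE)
    }
  }
  FALSE
}

# brute-force proto-spacer search for one spacer and genome: all windows on
# both strands above the identity floor, reduced per overlap cluster
oracleProtospacers <- function(spacer, genome, minIdentity = 0.90,
                               minLen = 30L) {
  L <- nchar(spacer)
  if (L < minLen) return(NULL)
  cand <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") spacer else oracleRevComp(spacer)
    for (i in seq_len(nchar(genome) - L + 1L)) {
      mm <- oracleHamming(substr(genome, i, i + L - 1L), q)
      if ((L - mm) / L >= minIdentity - 1e-9)
        cand <- rbind(cand, data.frame(start = i, end = i + L - 1L,
                                       strand = strand, mismatches = mm,
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(cand)) return(NULL)
  cand <- cand[order(cand$start, cand$mismatches), , drop = FALSE]
  out <- NULL
  cluster <- cand[1L, , drop = FALSE]
  hi <- cand$end[1L]
  if (nrow(cand) > 1L) {
    for (i in 2L:nrow(cand)) {
      if (cand$start[i] <= hi) {
        cluster <- rbind(cluster, cand[i, ])
        hi <- max(hi, cand$end[i])
      } else {
        out <- rbind(out, cluster[which.min(cluster$mismatches), ])
        cluster <- cand[i, , drop = FALSE]
        hi <- cand$end[i]
      }
    }
  }
  out <- rbind(out, cluster[which.min(cluster$mismatches), ])
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# plant a given number of substitutions at distinct random positions
plantMismatches <- function(seq, n) {
  ch <- strsplit(seq, "")[[1]]
  for (p in sample(length(ch), n))
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# the repeat consensuses printed for the selected known and novel CRISPRs
knownRepeats <- function() {
  fa <- readFasta(system.file("extdata", "known_repeats.fasta",
                              package = "mcrispr"))
  setNames(as.character(fa), names(fa))
}
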