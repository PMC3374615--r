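#' @import methods
#' @importFrom stats setNames runif rbinom
#' @importFrom utils adist head tail
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges start end width
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   readDNAStringSet writeXStringSet vcountPattern consensusMatrix
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.checkDna <- function(x, what = "sequence") {
  if (!is.character(x)) stop(what, " must be a character vector")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    s <- x[bad][1L]
    pos <- regexpr("[^ACGTN]", s)
    stop(sprintf("%s contains non-ACGTN character '%s' at position %d",
                 what, substr(s, pos, pos), pos))
  }
  invisible(x)
}

#' Normalize raw sequence strings
#'
#' Uppercases input and rejects characters outside \code{A,C,G,T,N}. IUPAC
#' ambiguity codes other than N are not accepted.
#'
#' @param x character vector of nucleotide sequences.
#' @return uppercased character vector.
#' @export
normalizeSeq <- function(x) {
  x <- toupper(x)
  .checkDna(x)
  x
}

#' Reverse complement
#'
#' Character-vector reverse complement with \code{N -> N}. For large sequence
#' sets \code{\link[Biostrings]{reverseComplement}} is used under the hood.
#'
#' @param x character vector of sequences over \code{A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @examples
#' revComp("AAAC")  # "GTTT"
#' @export
revComp <- function(x) {
  .checkDna(x)
  if (length(x) == 0L) return(character(0))
  as.character(reverseComplement(DNAStringSet(x)))
}

# integer encoding used by the window scanners; N in the subject and N in the
# query are mapped to distinct codes so that N never matches anything
.encodeSubject <- function(s) {
  v <- utf8ToInt(s)
  v[v == 78L] <- -1L
  v
}
.encodeQuery <- function(q) {
  v <- utf8ToInt(q)
  v[v == 78L] <- -2L
  v
}

#' Hamming distance
#'
#' Ungapped mismatch count between two equal-length sequences. Any comparison
#' involving N counts as a mismatch (including N vs N).
#'
#' @param a,b equal-length sequences (single strings).
#' @return integer mismatch count.
#' @export
hammingDist <- function(a, b) {
  .checkDna(a, "a"); .checkDna(b, "b")
  if (nchar(a) != nchar(b))
    stop("hammingDist requires equal-length sequences (got ",
         nchar(a), " and ", nchar(b), ")")
  sum(.encodeSubject(a) != .encodeQuery(b))
}

#' Levenshtein edit distance
#'
#' Unit-cost edit distance (substitution, insertion, deletion each cost 1).
#' N matches nothing, including another N.
#'
#' @param a,b non-empty sequences; either may be a vector (distances are
#'   computed elementwise after recycling).
#' @return integer vector of edit distances.
#' @export
editDist <- function(a, b) {
  .checkDna(a, "a"); .checkDna(b, "b")
  if (any(nchar(a) == 0L) || any(nchar(b) == 0L))
    stop("editDist requires non-empty sequences")
  # sentinel-substitute N so it can never match
  a <- gsub("N", "!", a, fixed = TRUE)
  b <- gsub("N", "?", b, fixed = TRUE)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[i], b[i])), integer(1))
}

#' Orientation-aware edit distance
#'
#' Because the orientation of a CRISPR repeat is generally unknowable without
#' cas-gene context, the distance between two repeats is taken as the smaller
#' of the forward-forward edit distance and the distance between one repeat
#' and the reverse complement of the other.
#'
#' @param a,b non-empty sequences (single strings).
#' @return a list with elements \code{rawForward}, \code{rawRevcomp} and
#'   \code{oriented} (the minimum of the two).
#' @export
orientedDist <- function(a, b) {
  fw <- editDist(a, b)
  rc <- editDist(a, revComp(b))
  list(rawForward = fw, rawRevcomp = rc, oriented = pmin(fw, rc))
}

#' Column-majority consensus
#'
#' Majority base per column among \code{A,C,G,T}; N is excluded from voting,
#' ties break alphabetically, and an all-N column yields N.
#'
#' @param seqs character vector of equal-length sequences.
#' @return single consensus string.
#' @export
columnConsensus <- function(seqs) {
  .checkDna(seqs)
  if (length(seqs) < 1L) stop("columnConsensus needs at least one sequence")
  if (length(unique(nchar(seqs))) != 1L)
    stop("columnConsensus requires equal-length sequences")
  cm <- consensusMatrix(DNAStringSet(seqs), baseOnly = TRUE)
  acgt <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  tot <- colSums(acgt)
  # which.max over rows ordered A,C,G,T gives the alphabetical tie-break
  idx <- apply(acgt, 2, which.max)
  out <- c("A", "C", "G", "T")[idx]
  out[tot == 0L] <- "N"
  paste(out, collapse = "")
}

#' Sliding-window mismatch scan
#'
#' Mismatch counts of a query against every full-length window of a subject
#' (forward orientation only). The workhorse behind repeat scanning and read
#' recruitment; equivalent by construction to a per-window hamming count.
#'
#' @param subject subject sequence (single string).
#' @param query query sequence (single string), no longer than the subject.
#' @return integer vector of length \code{nchar(subject) - nchar(query) + 1}
#'   with the mismatch count of each window start.
#' @export
mismatchScan <- function(subject, query) {
  s <- .encodeSubject(subject)
  q <- .encodeQuery(query)
  n <- length(s); m <- length(q)
  if (n < m) return(integer(0))
  nw <- n - m + 1L
  mm <- integer(nw)
  for (j in seq_len(m)) mm <- mm + (s[j:(j + nw - 1L)] != q[j])
  mm
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrappers over \code{\link[Biostrings]{readDNAStringSet}} that
#' uppercase the sequences and validate the alphabet. Gzipped files are read
#' transparently.
#'
#' @param path file path.
#' @return \code{DNAStringSet}; for FASTQ, qualities are carried in
#'   \code{mcols(x)$qual} as character strings.
#' @export
readFasta <- function(path) {
  x <- readDNAStringSet(path, format = "fasta")
  y <- DNAStringSet(normalizeSeq(as.character(x)))
  names(y) <- sub("\\s.*$", "", names(x))
  y
}

#' @rdname readFasta
#' @export
readFastq <- function(path) {
  x <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  y <- DNAStringSet(normalizeSeq(as.character(x)))
  names(y) <- sub("\\s.*$", "", names(x))
  mcols(y)$qual <- as.character(mcols(x)$qualities)
  y
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x \code{DNAStringSet} or named character vector.
#' @param path output file path.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- DNAStringSet(x)
  writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' @rdname writeFasta
#' @export
writeFastq <- function(x, path) {
  if (is.character(x)) x <- DNAStringSet(x)
  qual <- mcols(x)$qual
  if (is.null(qual)) qual <- strrep("I", width(x))
  writeXStringSet(x, path, format = "fastq",
                  qualities = Biostrings::BStringSet(qual))
  invisible(path)
}
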