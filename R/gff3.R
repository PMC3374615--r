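# GFF3 emission for CRISPR arrays: one repeat_region feature per array with
# direct_repeat and spacer children. Coordinates are 1-based inclusive as
# required by GFF3; output is deterministic for identical input.

.gffEscape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x
}

#' Write CRISPR arrays as GFF3
#'
#' @param arrays list of \code{\link{CrisprArray}} objects.
#' @param path output file path.
#' @param source value for the GFF3 source column.
#' @return invisibly, the path written.
#' @export
writeArraysGFF3 <- function(arrays, path, source = "mcrispr") {
  lines <- "##gff-version 3"
  for (i in seq_along(arrays)) {
    a <- arrays[[i]]
    rep <- repeatRanges(a)
    sp <- spacerRanges(a)
    aid <- sprintf("crispr%d", i)
    tr <- mcols(rep)$truncated
    lines <- c(lines, paste(
      contigId(a), source, "repeat_region",
      min(start(rep)), max(end(rep)), ".",
      mcols(rep)$strand[1L], ".",
      sprintf("ID=%s;consensus=%s;n_repeats=%d;avg_mismatch=%.4f;truncated=%s",
              aid, .gffEscape(consensus(a)), length(rep), avgMismatch(a),
              paste(tr[tr != "none"], collapse = "%2C")),
      sep = "\t"))
    for (j in seq_along(rep)) {
      lines <- c(lines, paste(
        contigId(a), source, "direct_repeat",
        start(rep)[j], end(rep)[j], mcols(rep)$mismatches[j],
        mcols(rep)$strand[j], ".",
        sprintf("ID=%s.r%d;Parent=%s;truncated=%s", aid, j, aid, tr[j]),
        sep = "\t"))
    }
    for (j in seq_along(sp)) {
      lines <- c(lines, paste(
        contigId(a), source, "spacer",
        start(sp)[j], end(sp)[j], ".",
        mcols(rep)$strand[1L], ".",
        sprintf("ID=%s.s%d;Parent=%s", aid, j, aid),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
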