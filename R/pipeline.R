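# End-to-end orchestration on synthetic data: simulate a community and a
# phage, run de novo detection, targeted assembly per sample, catalog and
# spacer analytics, and write every artifact with a checksum manifest.

#' Run the full pipeline end to end on synthetic data
#'
#' Simulates a multi-sample community carrying one CRISPR plus a mock phage
#' containing planted proto-spacers, then runs the complete toolchain:
#' de novo detection on a planted genome, per-sample targeted assembly,
#' spacer deduplication/clustering/sharing, proto-spacer search with PAM
#' profiling, and a repeat network over the detected consensuses. All
#' artifacts are written under \code{outDir} and listed in a checksum
#' manifest. Reruns with the same seed produce identical checksums.
#'
#' @param outDir output directory (created if needed).
#' @param seed RNG seed driving every simulation.
#' @param nSubjects,sites,visits,tiers community design, see
#'   \code{\link{simCommunity}}.
#' @param spacersPerSample spacers per planted locus.
#' @param coverage read coverage per sample.
#' @param k assembler k-mer length.
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
runEndToEnd <- function(outDir, seed = 1L, nSubjects = 3L,
                        sites = c("plaque", "tongue"), visits = 2L,
                        tiers = c(0.8, 0.2, 0.0), spacersPerSample = 8L,
                        coverage = 30, k = 45L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  comm <- simCommunity(nSubjects = nSubjects, sites = sites,
                       visits = visits, tiers = tiers,
                       spacersPerSample = spacersPerSample,
                       coverage = coverage)
  utils::write.table(comm$metadata, file.path(outDir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # de novo detection on one planted genome
  gen <- simGenome(list(list(repeatSeq = comm$repeatSeq, nCopies = 6L)),
                   genomeLen = 8000L)
  writeFasta(setNames(gen$seq, "genome1"), file.path(outDir, "genome.fasta"))
  arrays <- findCrisprs(gen$seq, contigId = "genome1")
  writeArraysGFF3(arrays, file.path(outDir, "denovo_arrays.gff3"))

  # targeted assembly per sample
  records <- list(); summaries <- list(); allSpacers <- DNAStringSet()
  for (s in names(comm$reads)) {
    res <- targetedAssembly(comm$reads[[s]], comm$repeatSeq, k = k,
                            queryId = "rep1", sampleId = s)
    summaries[[s]] <- res$summary
    if (length(res$spacers)) {
      allSpacers <- c(allSpacers, res$spacers)
      records[[s]] <- data.frame(spacerId = names(res$spacers),
                                 seq = as.character(res$spacers),
                                 sampleId = s, stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  utils::write.table(summary, file.path(outDir, "assembly_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(allSpacers))
    writeFasta(allSpacers, file.path(outDir, "spacers.fasta"))

  # spacer analytics
  recdf <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  sharingPath <- file.path(outDir, "sharing_matrix.tsv")
  if (!is.null(recdf) && nrow(recdf)) {
    dd <- dedupeSpacers(recdf)
    cl <- clusterSpacers(setNames(dd$unique$seq, dd$unique$id),
                         identity = 0.98)
    meta <- comm$metadata
    names(meta)[names(meta) == "sample"] <- "sample"
    sm <- sharingMatrix(recdf, cl, meta)
    utils::write.table(cbind(cluster = rownames(incidence(sm)),
                             as.data.frame(incidence(sm))),
                       sharingPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  # proto-spacer search against a mock phage carrying planted spacers
  planted <- unique(unlist(comm$inventories))[1:5]
  names(planted) <- paste0("planted", seq_along(planted))
  phage <- simPhage(planted, pam = "GG", genomeLen = 3000L)
  writeFasta(setNames(phage$seq, "phage1"), file.path(outDir, "phage.fasta"))
  hits <- findProtospacers(planted, c(phage1 = phage$seq))
  utils::write.table(hits[, setdiff(colnames(hits),
                                    c("flankUp", "flankDown"))],
                     file.path(outDir, "protospacers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(hits)) {
    pam <- pamProfile(hits)
    utils::write.table(
      data.frame(position = seq_len(ncol(pam$down)), t(pam$down)),
      file.path(outDir, "pam_downstream_pfm.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # repeat network over detected consensuses plus the community repeat
  reps <- c(community = comm$repeatSeq,
            setNames(vapply(arrays, consensus, character(1)),
                     paste0("denovo", seq_along(arrays))))
  if (length(reps) >= 2L)
    writeNetwork(buildNetwork(reps),
                 tsv = file.path(outDir, "repeat_network.tsv"))

  files <- sort(list.files(outDir, full.names = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outDir, "MANIFEST.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
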