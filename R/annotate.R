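# One-call transcript annotation: ORF/UTRs, poly(A) signals, protein
# statistics, IRE stem-loops and (optionally) exon-intron structure.

#' Annotate a transcript
#'
#' Runs the sequence-feature battery on a cDNA: longest-ORF/UTR
#' partition, polyadenylation-signal scan, protein mass and pI, IRE
#' stem-loop detection, and — when a genomic sequence is supplied —
#' exon-intron mapping.
#'
#' @param cdna A [nt_sequence()] or character scalar.
#' @param genomic Optional genomic [nt_sequence()]/character for
#'   exon-intron mapping.
#' @param polya_motifs Poly(A)-signal motifs to scan for.
#' @param ... Further arguments passed to [detect_ire()].
#' @return An object of class `transcript_annotation`: a list with `orf`,
#'   `protein`, `polya`, `ire` and (optionally) `gene_model`.
#' @examples
#' ann <- annotate_transcript(simulate_cdna(seed = 1))
#' ann$orf
#' @export
annotate_transcript <- function(cdna, genomic = NULL,
                                polya_motifs = c("ATTAAA", "AATAAA"), ...) {
  if (!inherits(cdna, "nt_sequence")) cdna <- nt_sequence("cdna", cdna)
  orf <- find_orf(cdna)
  out <- list(id = cdna$id,
              length_nt = nchar(cdna$residues),
              orf = orf,
              protein = protein_stats(orf$protein),
              polya = scan_polya_signal(cdna, polya_motifs),
              ire = detect_ire(cdna, ...))
  if (!is.null(genomic))
    out$gene_model <- map_exons(cdna, genomic)
  structure(out, class = "transcript_annotation")
}

#' @export
print.transcript_annotation <- function(x, ...) {
  cat(sprintf("Transcript annotation: %s (%d nt)\n", x$id, x$length_nt))
  print(x$orf)
  print(x$protein)
  if (nrow(x$polya)) {
    cat("Poly(A) signals:\n")
    print(x$polya, row.names = FALSE)
  } else cat("Poly(A) signals: none\n")
  if (nrow(x$ire)) {
    cat("IRE stem-loops:\n")
    print(x$ire, row.names = FALSE)
  } else cat("IRE stem-loops: none\n")
  if (!is.null(x$gene_model)) print(x$gene_model)
  invisible(x)
}

#' Flatten a transcript annotation to a GFF3-style table
#'
#' @param annotation A `transcript_annotation` from
#'   [annotate_transcript()].
#' @return A data.frame with columns `seqid`, `feature`, `start`, `end`,
#'   `attributes` (coordinates are 1-based inclusive; ORF/UTR/poly(A)/IRE
#'   on the cDNA, exons/introns on the genomic sequence).
#' @export
annotation_table <- function(annotation) {
  stopifnot(inherits(annotation, "transcript_annotation"))
  rows <- list()
  add <- function(feature, start, end, attributes) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = annotation$id, feature = feature,
      start = as.integer(start), end = as.integer(end),
      attributes = attributes, stringsAsFactors = FALSE)
  }
  orf <- annotation$orf
  if (orf$utr5_length > 0L)
    add("five_prime_UTR", 1L, orf$utr5_length, "")
  add("CDS", orf$start, orf$end,
      sprintf("protein_length=%d;mass_da=%.2f;pi=%.2f",
              annotation$protein$length_aa,
              annotation$protein$molecular_mass,
              annotation$protein$isoelectric_point))
  if (orf$utr3_length > 0L)
    add("three_prime_UTR", orf$end + 1L, annotation$length_nt, "")
  p <- annotation$polya
  for (i in seq_len(nrow(p)))
    add("polyA_signal_sequence", p$start[i], p$end[i],
        sprintf("motif=%s", p$motif[i]))
  ire <- annotation$ire
  for (i in seq_len(nrow(ire)))
    add("iron_responsive_element", ire$start[i], ire$end[i],
        sprintf("loop=%s;loop_start=%d;bulge_pos=%d;upper_pairs=%d;lower_pairs=%d",
                ire$loop_seq[i], ire$loop_start[i], ire$bulge_pos[i],
                ire$upper_stem_pairs[i], ire$lower_stem_pairs[i]))
  gm <- annotation$gene_model
  if (!is.null(gm)) {
    for (i in seq_len(nrow(gm$exons)))
      add("exon", gm$exons$start[i], gm$exons$end[i],
          sprintf("number=%d", i))
    for (i in seq_len(nrow(gm$introns)))
      add("intron", gm$introns$start[i], gm$introns$end[i],
          sprintf("number=%d;donor=%s;acceptor=%s;canonical=%s", i,
                  gm$introns$donor[i], gm$introns$acceptor[i],
                  tolower(gm$introns$canonical[i])))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an annotation table as GFF3-style TSV
#'
#' @param annotation A `transcript_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation_table(annotation), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
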