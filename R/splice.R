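# Exon-intron structure from cDNA-vs-genomic comparison: ordered greedy
# exact anchoring constrained to canonical GT...AG introns.

new_gene_model <- function(exons, introns, cdna_length) {
  structure(list(exons = exons, introns = introns,
                 cdna_length = cdna_length,
                 total_genomic_length = exons$end[nrow(exons)] -
                   exons$start[1L] + 1L),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model: %d exon(s), %d intron(s), spans %d nt of genomic\n",
              nrow(x$exons), nrow(x$introns), x$total_genomic_length))
  for (i in seq_len(nrow(x$exons)))
    cat(sprintf("  exon %d: %d-%d (%d nt)\n", i, x$exons$start[i],
                x$exons$end[i], x$exons$end[i] - x$exons$start[i] + 1L))
  for (i in seq_len(nrow(x$introns)))
    cat(sprintf("  intron %d: %d-%d (%d nt) %s..%s%s\n", i,
                x$introns$start[i], x$introns$end[i],
                x$introns$end[i] - x$introns$start[i] + 1L,
                x$introns$donor[i], x$introns$acceptor[i],
                if (x$introns$canonical[i]) "" else " [non-canonical]"))
  invisible(x)
}

# Longest common prefix length of cdna[c..] and genomic[g..].
lcp_length <- function(cd, gn, c0, g0) {
  max_len <- min(length(cd) - c0, length(gn) - g0) + 1L
  if (max_len <= 0L) return(0L)
  diff <- which(cd[c0:(c0 + max_len - 1L)] != gn[g0:(g0 + max_len - 1L)])
  if (!length(diff)) max_len else diff[1L] - 1L
}

#' Map exon-intron structure by spliced cDNA-to-genomic comparison
#'
#' Reconstructs the gene model that splices the genomic sequence into the
#' cDNA, assuming both derive from the same individual (exact exon
#' matches, no mismatch tolerance by default).  The algorithm anchors the
#' cDNA 5' end in the genomic sequence, then repeatedly extends the
#' longest exact match; at each mismatch boundary it takes the largest
#' exon extension whose following dinucleotide is the canonical donor GT
#' and for which a downstream acceptor AG is followed by genomic sequence
#' resuming the cDNA (nearest such acceptor, introns at least
#' `min_intron` nt).  The concatenated exons are verified to reconstruct
#' the cDNA exactly.
#'
#' @param cdna,genomic [nt_sequence()] objects or character scalars (DNA).
#' @param min_intron Minimum intron length (GT + AG bounds this at 4).
#' @param seed_length Length of the exact seed used to anchor the first
#'   exon and to confirm each acceptor site.
#' @return An object of class `gene_model` with `$exons` (genomic
#'   `start`/`end`, 1-based inclusive), `$introns` (`start`, `end`,
#'   `donor`, `acceptor`, `canonical`), `$cdna_length`,
#'   `$total_genomic_length`.
#' @examples
#' g <- paste0("ATGGCCATTGTAATGGGCCG", "GT", "TTTTTTTTCCCCCCCCAG",
#'             "CTCGAGCATGCATCTAGAGG")
#' map_exons(paste0("ATGGCCATTGTAATGGGCCG", "CTCGAGCATGCATCTAGAGG"), g)
#' @export
map_exons <- function(cdna, genomic, min_intron = 4L, seed_length = 12L) {
  cd_s <- as_dna_string(cdna, "cdna")
  gn_s <- as_dna_string(genomic, "genomic")
  if (nchar(cd_s) > nchar(gn_s))
    stop("cDNA is longer than the genomic sequence")
  cd <- strsplit(cd_s, "")[[1L]]
  gn <- strsplit(gn_s, "")[[1L]]
  nc <- length(cd); ng <- length(gn)
  seed <- min(seed_length, nc)
  # anchor the first exon at the first genomic occurrence of the cDNA
  # 5' seed
  g0 <- regexpr(substr(cd_s, 1L, seed), gn_s, fixed = TRUE)[1L]
  if (g0 == -1L)
    stop("cDNA 5' end not found in genomic sequence (reached cDNA position 0)")
  exons <- list(); introns <- list()
  c_pos <- 1L; g_pos <- as.integer(g0)
  repeat {
    m <- lcp_length(cd, gn, c_pos, g_pos)
    if (c_pos + m - 1L == nc) {
      exons[[length(exons) + 1L]] <- c(g_pos, g_pos + m - 1L)
      break
    }
    placed <- FALSE
    for (e in rev(seq_len(m))) {        # largest exon extension first
      don_at <- g_pos + e
      if (don_at + 1L > ng) next
      if (!(gn[don_at] == "G" && gn[don_at + 1L] == "T")) next
      # scan forward for the nearest acceptor AG followed by sequence
      # resuming the cDNA
      c_next <- c_pos + e
      sub_seed <- min(seed, nc - c_next + 1L)
      target <- substr(cd_s, c_next, c_next + sub_seed - 1L)
      i <- don_at + min_intron               # earliest next-exon start
      found <- FALSE
      while (i + sub_seed - 1L <= ng) {
        hit <- regexpr(target, substr(gn_s, i, ng), fixed = TRUE)[1L]
        if (hit == -1L) break
        cand <- i + as.integer(hit) - 1L
        if (cand >= don_at + min_intron &&
            gn[cand - 2L] == "A" && gn[cand - 1L] == "G") {
          found <- TRUE; i <- cand; break
        }
        i <- cand + 1L
      }
      if (!found) next
      exons[[length(exons) + 1L]] <- c(g_pos, g_pos + e - 1L)
      introns[[length(introns) + 1L]] <-
        list(start = don_at, end = i - 1L,
             donor = paste0(gn[don_at], gn[don_at + 1L]),
             acceptor = paste0(gn[i - 2L], gn[i - 1L]))
      c_pos <- c_next; g_pos <- i
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(paste0("cDNA not fully reconstructable from genomic ",
                          "sequence (reached cDNA position %d of %d)"),
                   c_pos + m - 1L, nc))
  }
  ex <- data.frame(start = vapply(exons, `[`, integer(1), 1L),
                   end = vapply(exons, `[`, integer(1), 2L))
  if (length(introns)) {
    it <- data.frame(
      start = vapply(introns, function(x) x$start, integer(1)),
      end = vapply(introns, function(x) x$end, integer(1)),
      donor = vapply(introns, function(x) x$donor, character(1)),
      acceptor = vapply(introns, function(x) x$acceptor, character(1)),
      stringsAsFactors = FALSE)
  } else {
    it <- data.frame(start = integer(), end = integer(),
                     donor = character(), acceptor = character(),
                     stringsAsFactors = FALSE)
  }
  it$canonical <- it$donor == "GT" & it$acceptor == "AG"
  model <- new_gene_model(ex, it, nc)
  spliced <- splice_gene_model(gn_s, model)
  if (!identical(spliced, cd_s))
    stop("internal error: spliced exons do not reconstruct the cDNA")
  model
}

#' Splice a gene model out of a genomic sequence
#'
#' Concatenates the exon substrings of `model` taken from `genomic`,
#' yielding the mature cDNA.
#'
#' @param genomic [nt_sequence()] or character scalar (DNA).
#' @param model A `gene_model` (from [map_exons()] or
#'   [simulate_gene_model()]).
#' @return Character scalar: the spliced cDNA.
#' @export
splice_gene_model <- function(genomic, model) {
  s <- as_dna_string(genomic, "genomic")
  paste(substring(s, model$exons$start, model$exons$end), collapse = "")
}
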