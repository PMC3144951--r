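# ORF finding and polyadenylation-signal scanning on the forward strand.

#' Find the longest open reading frame
#'
#' Scans the forward strand (all three frames) for ATG-initiated reading
#' frames terminated by an in-frame stop codon (standard genetic code) and
#' returns the longest; ties break to the 5'-most start.  The ORF length
#' includes the stop codon, so a 525-nt ORF encodes 174 residues.  UTR
#' lengths are derived from the ORF placement and always satisfy
#' `utr5_length + length_nt + utr3_length == nchar(seq)`.
#'
#' @param seq A [nt_sequence()] or character scalar (DNA or RNA; RNA is
#'   mapped U -> T before scanning).
#' @return An object of class `orf_annotation` with fields `start`, `end`
#'   (1-based inclusive), `length_nt`, `protein`, `utr5_length`,
#'   `utr3_length`.
#' @examples
#' find_orf("ATGAAATAA")     # protein "MK", no UTRs
#' @export
find_orf <- function(seq) {
  s <- as_dna_string(seq)
  n <- nchar(s)
  atg <- gregexpr("ATG", s, fixed = TRUE)[[1L]]
  if (atg[1L] == -1L) stop("no ORF found")
  stops <- sort(unique(c(
    unlist(gregexpr("TAA", s, fixed = TRUE)),
    unlist(gregexpr("TAG", s, fixed = TRUE)),
    unlist(gregexpr("TGA", s, fixed = TRUE)))))
  stops <- stops[stops > 0L]
  best_start <- NA_integer_; best_len <- -1L; best_stop <- NA_integer_
  for (a in as.integer(atg)) {
    cand <- stops[stops > a & (stops - a) %% 3L == 0L & stops + 2L <= n]
    if (!length(cand)) next
    st <- cand[1L]
    len <- st + 2L - a + 1L
    if (len > best_len) {            # ties keep the earlier (5'-most) start
      best_len <- len; best_start <- a; best_stop <- st
    }
  }
  if (is.na(best_start)) stop("no ORF found")
  coding <- substr(s, best_start, best_stop - 1L)
  protein <- as.character(Biostrings::translate(Biostrings::DNAString(coding)))
  structure(
    list(start = best_start, end = best_stop + 2L,
         length_nt = best_len, protein = protein,
         utr5_length = best_start - 1L,
         utr3_length = n - (best_stop + 2L)),
    class = "orf_annotation")
}

#' @export
print.orf_annotation <- function(x, ...) {
  cat(sprintf("ORF %d-%d (%d nt incl. stop), protein %d aa\n",
              x$start, x$end, x$length_nt, nchar(x$protein)))
  cat(sprintf("  5' UTR %d nt | ORF %d nt | 3' UTR %d nt\n",
              x$utr5_length, x$length_nt, x$utr3_length))
  invisible(x)
}

#' Scan for polyadenylation signal motifs
#'
#' Reports every (possibly overlapping) occurrence of each motif, with
#' 1-based inclusive coordinates.
#'
#' @param seq A [nt_sequence()] or character scalar (DNA alphabet).
#' @param motifs Character vector of motifs; defaults to the canonical
#'   AATAAA and the common ATTAAA variant.
#' @return A data.frame with columns `motif`, `start`, `end`, ordered by
#'   `start` (zero rows when nothing matches).
#' @examples
#' scan_polya_signal("GGATTAAAGG")
#' @export
scan_polya_signal <- function(seq, motifs = c("ATTAAA", "AATAAA")) {
  s <- as_dna_string(seq)
  hits <- lapply(motifs, function(m) {
    m <- toupper(m)
    # zero-width lookahead so overlapping occurrences are all reported
    starts <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1L]]
    if (starts[1L] == -1L) return(NULL)
    starts <- as.integer(starts)
    data.frame(motif = m, start = starts,
               end = starts + nchar(m) - 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(motif = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}
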