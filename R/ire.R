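# Consensus matcher for the iron-responsive element (IRE) stem-loop.
#
# The canonical ferritin IRE comprises (5' to 3') a lower stem, an
# unpaired bulged C on the 5' arm, an upper stem of five base pairs, and
# the apical six-nucleotide loop CAGUGA (CAGUGH more generally).  This is
# a deterministic consensus/base-pairing matcher, not a thermodynamic
# folder: it anchors on the loop motif and verifies pairing outward.

IRE_PAIRS_WC <- c("AU", "UA", "GC", "CG")
IRE_PAIRS_WOBBLE <- c("GU", "UG")

ire_paired <- function(a, b, allow_wobble) {
  p <- paste0(a, b)
  p %in% IRE_PAIRS_WC || (allow_wobble && p %in% IRE_PAIRS_WOBBLE)
}

#' Detect iron-responsive element stem-loops
#'
#' Scans a sequence (T and U equivalent, case-insensitive) for the IRE
#' consensus: the apical loop motif, an upper stem of `upper_stem_pairs`
#' complementary pairs enclosing the loop (Watson-Crick, plus G·U wobble
#' unless disabled), exactly one unpaired bulged C on the 5' arm
#' immediately below the upper stem, and at least `lower_stem_min`
#' further contiguous pairs of lower stem.  Overlapping candidates are
#' resolved greedily 5' to 3'.
#'
#' @param seq A [nt_sequence()] or character scalar.
#' @param loop_motif Apical loop sequence required exactly (RNA alphabet;
#'   default the conserved `CAGUGA`).
#' @param upper_stem_pairs Required pairs in the upper (proximal) stem.
#' @param lower_stem_min Minimum pairs in the lower (bottom) stem.
#' @param allow_wobble Accept G·U wobble pairs in the stems?
#' @param require_bulge_c Require the bulged residue to be C?
#' @return A data.frame with one row per match: `start`, `end` (1-based,
#'   spanning the paired element), `loop_start`, `loop_end`, `loop_seq`,
#'   `bulge_pos`, `upper_stem_pairs`, `lower_stem_pairs`.  Zero rows when
#'   nothing matches.
#' @examples
#' detect_ire("ctttgctgcgtcagtgaacgtacgagc")
#' @export
detect_ire <- function(seq, loop_motif = "CAGUGA", upper_stem_pairs = 5L,
                       lower_stem_min = 3L, allow_wobble = TRUE,
                       require_bulge_c = TRUE) {
  s <- as_rna_string(seq)
  n <- nchar(s)
  motif <- chartr("T", "U", toupper(loop_motif))
  k <- nchar(motif)
  empty <- data.frame(start = integer(), end = integer(),
                      loop_start = integer(), loop_end = integer(),
                      loop_seq = character(), bulge_pos = integer(),
                      upper_stem_pairs = integer(),
                      lower_stem_pairs = integer(),
                      stringsAsFactors = FALSE)
  if (n < k) return(empty)
  ch <- strsplit(s, "")[[1L]]
  starts <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1L]]
  if (starts[1L] == -1L) return(empty)
  rows <- list()
  last_end <- 0L
  for (p in as.integer(starts)) {
    # upper stem: positions (p - i) pair with (p + k - 1 + i)
    if (p - upper_stem_pairs - 1L < 1L ||
        p + k - 1L + upper_stem_pairs > n) next
    if (p <= last_end) next                      # enforce non-overlap
    ok <- TRUE
    for (i in seq_len(upper_stem_pairs))
      if (!ire_paired(ch[p - i], ch[p + k - 1L + i], allow_wobble)) {
        ok <- FALSE; break
      }
    if (!ok) next
    bulge <- p - upper_stem_pairs - 1L
    if (require_bulge_c && ch[bulge] != "C") next
    # lower stem: (bulge - j) pairs with (p + k - 1 + upper_stem_pairs + j)
    lower <- 0L
    repeat {
      i5 <- bulge - lower - 1L
      i3 <- p + k - 1L + upper_stem_pairs + lower + 1L
      if (i5 < 1L || i3 > n) break
      if (!ire_paired(ch[i5], ch[i3], allow_wobble)) break
      lower <- lower + 1L
    }
    if (lower < lower_stem_min) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = bulge - lower, end = p + k - 1L + upper_stem_pairs + lower,
      loop_start = p, loop_end = p + k - 1L,
      loop_seq = motif, bulge_pos = bulge,
      upper_stem_pairs = as.integer(upper_stem_pairs),
      lower_stem_pairs = lower, stringsAsFactors = FALSE)
    last_end <- p + k - 1L + upper_stem_pairs + lower
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
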