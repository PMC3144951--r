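# Light nucleotide-sequence container plus FASTA I/O (Biostrings-backed).

#' Nucleotide sequence container
#'
#' Minimal validated container for a DNA or RNA sequence.  The alphabet is
#' auto-detected from the presence of U (RNA) vs T (DNA); a sequence
#' containing both is rejected.
#'
#' @param id Sequence identifier.
#' @param residues Character scalar over `A C G T U N` (case-insensitive).
#' @param alphabet `"auto"`, `"dna"` or `"rna"`.
#' @return An object of class `nt_sequence` with fields `id`, `residues`
#'   (upper-cased) and `alphabet`.
#' @examples
#' nt_sequence("ire", "ctttgctgcgtcagtgaacgtacgagc")
#' @export
nt_sequence <- function(id, residues, alphabet = c("auto", "dna", "rna")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("empty sequence")
  bad <- regmatches(residues, regexpr("[^ACGTUN]", residues))
  if (length(bad) && nzchar(bad))
    stop("invalid residue '", bad, "' in sequence '", id, "'")
  has_t <- grepl("T", residues, fixed = TRUE)
  has_u <- grepl("U", residues, fixed = TRUE)
  if (has_t && has_u)
    stop("sequence '", id, "' mixes T and U")
  if (alphabet == "auto")
    alphabet <- if (has_u) "rna" else "dna"
  if (alphabet == "dna" && has_u)
    stop("U residue in a sequence declared as DNA")
  if (alphabet == "rna" && has_t)
    stop("T residue in a sequence declared as RNA")
  structure(list(id = as.character(id), residues = residues,
                 alphabet = alphabet),
            class = "nt_sequence")
}

#' @export
print.nt_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<nt_sequence> %s (%s, %d nt)\n  %s\n",
              x$id, x$alphabet, n, shown))
  invisible(x)
}

# Coerce character / nt_sequence input to an upper-case DNA-alphabet
# residue string (U -> T), validating through nt_sequence().
as_dna_string <- function(seq, id = "seq") {
  if (!inherits(seq, "nt_sequence")) seq <- nt_sequence(id, seq)
  chartr("U", "T", seq$residues)
}

# Same, but RNA alphabet (T -> U), for stem-loop scanning.
as_rna_string <- function(seq, id = "seq") {
  if (!inherits(seq, "nt_sequence")) seq <- nt_sequence(id, seq)
  chartr("T", "U", seq$residues)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named list of [nt_sequence()] objects.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    nt_sequence(names(set)[i], as.character(set[[i]]))
  })
  names(out) <- names(set)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A single [nt_sequence()] or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "nt_sequence")) seqs <- list(seqs)
  res <- vapply(seqs, function(s) {
    if (inherits(s, "nt_sequence")) chartr("U", "T", s$residues) else toupper(s)
  }, character(1))
  ids <- vapply(seqs, function(s)
    if (inherits(s, "nt_sequence")) s$id else "seq", character(1))
  set <- Biostrings::DNAStringSet(res)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
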