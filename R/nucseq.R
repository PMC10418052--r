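#' Validated nucleotide sequence
#'
#' Light-weight container for a single DNA or RNA sequence. Only the
#' unambiguous alphabet characters are accepted (`A`, `C`, `G` plus `T`
#' for DNA or `U` for RNA); IUPAC ambiguity codes such as `N` are
#' rejected at construction so malformed inputs surface immediately
#' rather than silently propagating through scoring. All positions in
#' this package are 1-based.
#'
#' @param residues Character scalar, the sequence. Case-insensitive.
#' @param alphabet `"DNA"`, `"RNA"`, or `NULL` to infer from the
#'   characters present (a sequence containing `U` is RNA, one
#'   containing `T` is DNA, and a sequence with neither defaults to
#'   DNA).
#'
#' @return An object of class `nucseq`: the upper-cased sequence string
#'   with an `alphabet` attribute.
#' @examples
#' nucseq("ATGC")
#' nucseq("AUGC")
#' @export
nucseq <- function(residues, alphabet = NULL) {
  if (inherits(residues, "nucseq")) {
    if (!is.null(alphabet) && alphabet != nucseq_alphabet(residues))
      stop("sequence is ", nucseq_alphabet(residues), ", not ", alphabet)
    return(residues)
  }
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  s <- toupper(residues)
  if (nchar(s) < 1L) stop("empty sequence")
  has_t <- grepl("T", s, fixed = TRUE)
  has_u <- grepl("U", s, fixed = TRUE)
  if (has_t && has_u) stop("sequence mixes T and U")
  if (is.null(alphabet)) alphabet <- if (has_u) "RNA" else "DNA"
  alphabet <- match.arg(alphabet, c("DNA", "RNA"))
  allowed <- if (alphabet == "DNA") "ACGT" else "ACGU"
  bad <- gsub(sprintf("[%s]", allowed), "", s)
  if (nchar(bad) > 0L)
    stop(sprintf("invalid %s character(s): %s", alphabet,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")))
  structure(s, alphabet = alphabet, class = "nucseq")
}

#' @export
print.nucseq <- function(x, ...) {
  s <- unclass(x)
  shown <- if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat(sprintf("<nucseq %s, %d nt> %s\n", attr(x, "alphabet"), nchar(s), shown))
  invisible(x)
}

#' Alphabet of a nucseq
#' @param x A `nucseq`.
#' @return `"DNA"` or `"RNA"`.
#' @export
nucseq_alphabet <- function(x) attr(nucseq(x), "alphabet")

#' Sequence length in nucleotides
#' @param x A `nucseq` or character scalar.
#' @return Integer length.
#' @export
nucseq_length <- function(x) nchar(unclass(nucseq(x)))

# Split into a character vector of single bases. Internal workhorse;
# `canonical = TRUE` maps T to U so DNA input can be scored without an
# explicit transcription step (T and U are equivalent everywhere the
# hairpin rules look at identity or pairing).
nuc_chars <- function(x, canonical = FALSE) {
  s <- if (inherits(x, "nucseq")) unclass(x) else toupper(x)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  if (canonical) v[v == "T"] <- "U"
  v
}

#' Transcribe a DNA sequence to RNA
#'
#' Replaces every `T` with `U`. The input must be DNA; transcribing an
#' RNA sequence is an error rather than a no-op, so alphabet mix-ups in
#' calling code are caught.
#'
#' @param seq A DNA `nucseq` (or character coercible to one).
#' @return An RNA `nucseq` of the same length.
#' @examples
#' transcribe(nucseq("ATGC"))
#' @export
transcribe <- function(seq) {
  seq <- nucseq(seq)
  if (nucseq_alphabet(seq) != "DNA")
    stop("transcribe() expects a DNA sequence, got ", nucseq_alphabet(seq))
  nucseq(chartr("T", "U", unclass(seq)), alphabet = "RNA")
}

# Watson-Crick complement of single-character DNA bases.
complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", U = "A")[b])
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning plain
#' character sequences named by the first whitespace-delimited token of
#' each description line (the gene-symbol convention used by per-gene
#' CDS files).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-cased sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (or list) of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- unlist(seqs)
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
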