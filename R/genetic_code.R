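#' Translate a single DNA codon
#'
#' Standard genetic code (NCBI translation table 1). Stop codons
#' translate to `"*"`.
#'
#' @param codon Character scalar, exactly three unambiguous DNA bases
#'   (U accepted in place of T).
#' @return Single-letter amino-acid code, or `"*"` for a stop codon.
#' @examples
#' translate_codon("ATG")  # "M"
#' translate_codon("TGA")  # "*"
#' @export
translate_codon <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L)
  codon <- chartr("U", "T", toupper(codon))
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("codon must be 3 unambiguous DNA bases, got '", codon, "'")
  unname(Biostrings::GENETIC_CODE[codon])
}

# 3-letter <-> 1-letter amino-acid code maps (Ter/* for stop).
AA_3TO1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*"
)

#' Convert an amino-acid token to its one-letter code
#'
#' Accepts 3-letter codes (`"Arg"`, `"Ter"`), 1-letter codes, or `"*"`.
#'
#' @param aa Character vector of amino-acid tokens.
#' @return One-letter codes (`"*"` for stop); `NA` for unrecognised
#'   tokens.
#' @export
aa_one_letter <- function(aa) {
  out <- character(length(aa))
  for (i in seq_along(aa)) {
    tok <- aa[i]
    if (is.na(tok) || !nzchar(tok)) { out[i] <- NA_character_; next }
    if (tok == "*") { out[i] <- "*"; next }
    if (nchar(tok) == 1L && toupper(tok) %in% AA_3TO1) {
      out[i] <- toupper(tok); next
    }
    tok3 <- paste0(toupper(substr(tok, 1, 1)), tolower(substr(tok, 2, 3)))
    out[i] <- if (tok3 %in% names(AA_3TO1)) unname(AA_3TO1[tok3]) else NA_character_
  }
  out
}

#' Enumerate every single-nucleotide codon change
#'
#' All 64 codons x 3 positions x 3 alternate bases = 576 changes, each
#' classified as synonymous or non-synonymous under the standard
#' genetic code. Stop codons are treated as products: a stop-to-stop
#' change is synonymous, and a change into or out of a stop codon
#' (nonsense / read-through) is non-synonymous.
#'
#' @return A data.frame with 576 rows and columns `from_codon`,
#'   `position_in_codon` (1..3), `ref_base`, `alt_base`, `to_codon`,
#'   `from_product`, `to_product` (one-letter codes, `"*"` = stop) and
#'   `synonymous` (logical).
#' @examples
#' cc <- enumerate_codon_changes()
#' nrow(cc)              # 576
#' sum(!cc$synonymous)   # non-synonymous changes
#' @export
enumerate_codon_changes <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- names(Biostrings::GENETIC_CODE)
  n <- 64L * 3L * 3L
  from_codon <- character(n); pos <- integer(n)
  ref <- character(n); alt <- character(n); to_codon <- character(n)
  k <- 0L
  for (cd in codons) {
    cv <- strsplit(cd, "")[[1]]
    for (p in 1:3) {
      for (b in setdiff(bases, cv[p])) {
        k <- k + 1L
        from_codon[k] <- cd; pos[k] <- p; ref[k] <- cv[p]; alt[k] <- b
        nv <- cv; nv[p] <- b
        to_codon[k] <- paste(nv, collapse = "")
      }
    }
  }
  from_product <- unname(Biostrings::GENETIC_CODE[from_codon])
  to_product <- unname(Biostrings::GENETIC_CODE[to_codon])
  data.frame(
    from_codon = from_codon, position_in_codon = pos,
    ref_base = ref, alt_base = alt, to_codon = to_codon,
    from_product = from_product, to_product = to_product,
    synonymous = from_product == to_product,
    stringsAsFactors = FALSE
  )
}

#' Fraction of non-synonymous codon changes that are C>T or G>A
#'
#' Among all single-nucleotide codon changes that alter the encoded
#' product (stop counted as a product), the percentage whose
#' nucleotide change is C-to-T or G-to-A -- i.e. the changes a C>U
#' deamination event on either strand could produce. Under the
#' standard code this is 63/438 = 14.4%.
#'
#' @param changes Optionally, a precomputed result of
#'   [enumerate_codon_changes()].
#' @param digits Decimal places for the returned percentage (half-up
#'   rounding). Use `NULL` for the unrounded value.
#' @return Percentage (numeric scalar), e.g. `14.4`.
#' @export
nonsyn_transition_fraction <- function(changes = enumerate_codon_changes(),
                                       digits = 1) {
  ns <- changes[!changes$synonymous, ]
  hit <- (ns$ref_base == "C" & ns$alt_base == "T") |
         (ns$ref_base == "G" & ns$alt_base == "A")
  pct <- 100 * sum(hit) / nrow(ns)
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

# Round half away from zero at `digits` decimals (base round() is
# half-to-even, which would print 14.35 -> 14.3).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
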