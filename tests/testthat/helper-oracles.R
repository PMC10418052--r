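# Independent oracles used to check the implementation. These are
# deliberately written from scratch (no calls into the package's
# scoring/enumeration internals).

# Hard-coded standard genetic code, one-letter products, * = stop.
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Brute-force enumeration of all 576 single-nucleotide codon changes
# using only the hard-coded table. `synonymy` can be disabled to model
# a hypothetical code where every change alters the product.
oracle_codon_changes <- function(synonymy = TRUE) {
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (cd in names(GENETIC_CODE_TABLE)) {
    for (p in 1:3) {
      for (b in bases) {
        ref <- substr(cd, p, p)
        if (b == ref) next
        to <- cd
        substr(to, p, p) <- b
        syn <- if (synonymy)
          GENETIC_CODE_TABLE[[cd]] == GENETIC_CODE_TABLE[[to]]
        else FALSE
        rows[[length(rows) + 1L]] <-
          data.frame(ref = ref, alt = b, syn = syn)
      }
    }
  }
  do.call(rbind, rows)
}

# Exhaustive hairpin enumerator: tries every loop length in {3, 4} and
# every stem length, checking pairing base by base on the raw string,
# and applies the printed scoring formula directly. Returns the best
# total (NA when no hairpin) and the call.
oracle_score_site <- function(seq, c_pos, min_stem = 3, max_stem = 10,
                              window = 25, threshold = 10,
                              allow_gu = FALSE) {
  s <- chartr("T", "U", toupper(seq))
  n <- nchar(s)
  at <- function(i) substr(s, i, i)
  stopifnot(at(c_pos) == "C")
  comp_ok <- function(a, b) {
    ok <- (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "A" && b == "U") || (a == "U" && b == "A")
    if (allow_gu) ok <- ok || (a == "G" && b == "U") || (a == "U" && b == "G")
    ok
  }
  lo <- max(1, c_pos - window); hi <- min(n, c_pos + window)
  best <- NA
  for (L in c(3, 4)) {
    loop_start <- c_pos - L + 1
    if (loop_start < lo) next
    for (stem in min_stem:max_stem) {
      if (loop_start - stem < lo || c_pos + stem > hi) break
      ok <- TRUE; gc <- 0; au <- 0
      for (k in 1:stem) {
        a <- at(loop_start - k); b <- at(c_pos + k)
        if (!comp_ok(a, b)) { ok <- FALSE; break }
        if ((a == "G" && b == "C") || (a == "C" && b == "G")) gc <- gc + 1
        if ((a == "A" && b == "U") || (a == "U" && b == "A")) au <- au + 1
      }
      if (!ok) break
      loop <- substr(s, loop_start, c_pos)
      total <- 3 * gc + au +
        2 * grepl("U", loop) +
        2 * (c_pos < n && at(c_pos + 1) %in% c("A", "G")) -
        2 * grepl("G", loop)
      if (is.na(best) || total > best) best <- total
    }
  }
  list(total = best, call = !is.na(best) && best >= threshold)
}

# AUROC as the exhaustive concordant-pair fraction (ties get half
# credit).
oracle_auroc <- function(scores, labels) {
  scores[is.na(scores)] <- -Inf
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Decode a 50-bit feature vector back to the 25-nt window (RNA
# letters): (1,0)=A, (1,1)=G, (0,1)=C, (0,0)=U.
oracle_decode_window <- function(bits) {
  stopifnot(length(bits) == 50)
  m <- matrix(bits, nrow = 2)
  paste(vapply(seq_len(25), function(i) {
    pur <- m[1, i]; gc <- m[2, i]
    if (pur == 1 && gc == 0) "A"
    else if (pur == 1 && gc == 1) "G"
    else if (pur == 0 && gc == 1) "C"
    else "U"
  }, ""), collapse = "")
}

# Random DNA string helper for property tests.
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}
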