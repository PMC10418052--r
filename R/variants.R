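# Mandatory columns of the variant-summary dialect.
VARIANT_COLUMNS <- c("Type", "GeneSymbol", "Name", "ClinicalSignificance",
                     "Assembly", "ReferenceAlleleVCF", "AlternateAlleleVCF",
                     "PhenotypeList")

# Significance phrases that contain "pathogenic" as a substring but do
# not assert pathogenicity; matched case-insensitively before the
# substring rules. Conflicting assertions must not be binned as
# pathogenic.
SIGNIFICANCE_EXCEPTIONS <- c("conflicting interpretations of pathogenicity",
                             "conflicting classifications of pathogenicity")

#' Parse a variant table in the ClinVar variant_summary dialect
#'
#' Reads a tab-separated table with a header row and extracts, per
#' variant: gene symbol, allele id, the protein change parsed from the
#' HGVS `p.` suffix of the Name column (3-letter or 1-letter amino-acid
#' codes; `Ter`/`*` accepted), clinical significance, rsID, reference
#' and alternate alleles, assembly, and phenotype list.
#'
#' @param path Path to the TSV file, or a data.frame already read.
#' @return data.frame with one row per input row, columns `gene`,
#'   `allele_id`, `type`, `name`, `ref_aa`, `aa_pos`, `alt_aa`
#'   (one-letter, `NA` when no protein change is recorded),
#'   `significance`, `rsid`, `ref_allele`, `alt_allele` (upper-cased),
#'   `assembly`, `phenotypes`.
#' @export
parse_variant_table <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      quote = "", comment.char = "", colClasses = "character")
  # tolerate the leading-# header ClinVar uses on AlleleID
  names(tab) <- sub("^#", "", names(tab))
  missing <- setdiff(VARIANT_COLUMNS, names(tab))
  if (length(missing) > 0L)
    stop("variant table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  pc <- parse_protein_change(tab$Name)
  data.frame(
    gene = tab$GeneSymbol,
    allele_id = if ("AlleleID" %in% names(tab)) tab$AlleleID
                else rep(NA_character_, nrow(tab)),
    type = tab$Type,
    name = tab$Name,
    ref_aa = pc$ref_aa, aa_pos = pc$aa_pos, alt_aa = pc$alt_aa,
    significance = tab$ClinicalSignificance,
    rsid = if ("RS# (dbSNP)" %in% names(tab)) tab[["RS# (dbSNP)"]]
           else rep(NA_character_, nrow(tab)),
    ref_allele = toupper(tab$ReferenceAlleleVCF),
    alt_allele = toupper(tab$AlternateAlleleVCF),
    assembly = tab$Assembly,
    phenotypes = tab$PhenotypeList,
    stringsAsFactors = FALSE
  )
}

# Parse "(p.Arg2Trp)" / "(p.R2W)" / "(p.Arg2Ter)" / "(p.Arg2*)" /
# "(p.Arg2=)" from HGVS-style names. Returns one-letter codes; "="
# (synonymous shorthand) yields alt_aa == ref_aa.
parse_protein_change <- function(names_col) {
  pat <- "\\(p\\.([A-Za-z]{3}|[A-Z])([0-9]+)([A-Za-z]{3}|[A-Z*=])\\)"
  m <- regmatches(names_col, regexec(pat, names_col))
  ref_aa <- alt_aa <- rep(NA_character_, length(names_col))
  aa_pos <- rep(NA_integer_, length(names_col))
  for (i in seq_along(m)) {
    if (length(m[[i]]) != 4L) next
    r <- aa_one_letter(m[[i]][2L])
    a <- if (m[[i]][4L] == "=") r else aa_one_letter(m[[i]][4L])
    if (is.na(r) || is.na(a)) next
    ref_aa[i] <- r; alt_aa[i] <- a
    aa_pos[i] <- as.integer(m[[i]][3L])
  }
  list(ref_aa = ref_aa, aa_pos = aa_pos, alt_aa = alt_aa)
}

#' Filter variants to exonic, non-synonymous SNVs
#'
#' Applies the screen's inclusion filters: single nucleotide variants
#' only, the requested assembly only (GRCh38 by default; the duplicate
#' GRCh37 records are dropped), specific single-base alleles (no
#' `A>X`), no like-to-like changes (`A>A`), a recorded protein change,
#' and a non-synonymous one. Each excluded record is assigned the first
#' failing filter as its exclusion reason; the filters are pure
#' predicates, so the retained set does not depend on their order.
#'
#' @param records Output of [parse_variant_table()].
#' @param assembly Assembly to keep. Default `"GRCh38"`.
#' @return list with `kept` (data.frame), `excluded` (data.frame with a
#'   `reason` column), and `counts` (named integer vector over all
#'   exclusion reasons plus `retained`).
#' @export
filter_variants <- function(records, assembly = "GRCh38") {
  single_base <- function(x) !is.na(x) & x %in% c("A", "C", "G", "T")
  reasons <- rep(NA_character_, nrow(records))
  fail <- function(cond, why) {
    hit <- is.na(reasons) & cond
    reasons[hit] <<- why
  }
  fail(records$type != "single nucleotide variant", "not_snv")
  fail(records$assembly != assembly, "wrong_assembly")
  fail(!(single_base(records$ref_allele) & single_base(records$alt_allele)),
       "nonspecific_allele")
  fail(records$ref_allele == records$alt_allele, "like_to_like")
  fail(is.na(records$ref_aa) | is.na(records$alt_aa), "no_protein_change")
  fail(records$ref_aa == records$alt_aa, "synonymous")
  kept <- records[is.na(reasons), , drop = FALSE]
  excluded <- records[!is.na(reasons), , drop = FALSE]
  excluded$reason <- reasons[!is.na(reasons)]
  lv <- c("not_snv", "wrong_assembly", "nonspecific_allele", "like_to_like",
          "no_protein_change", "synonymous")
  counts <- c(table(factor(excluded$reason, levels = lv)),
              retained = nrow(kept))
  list(kept = kept, excluded = excluded, counts = counts)
}

#' Bin a clinical-significance string
#'
#' Three-way collapse by case-insensitive substring containment:
#' strings containing "pathogenic" are binned pathogenic, otherwise
#' strings containing "benign" are binned benign, otherwise
#' unspecified. "Conflicting interpretations of pathogenicity" (which
#' contains the substring but asserts nothing) is explicitly mapped to
#' unspecified via an exception list.
#'
#' @param text Character vector of significance strings.
#' @param exceptions Phrases mapped to unspecified before substring
#'   matching.
#' @return Character vector over `{"pathogenic", "benign",
#'   "unspecified"}`.
#' @export
bin_significance <- function(text, exceptions = SIGNIFICANCE_EXCEPTIONS) {
  s <- tolower(ifelse(is.na(text), "", text))
  for (ex in exceptions) s <- gsub(ex, "", s, fixed = TRUE)
  ifelse(grepl("pathogenic", s, fixed = TRUE), "pathogenic",
         ifelse(grepl("benign", s, fixed = TRUE), "benign", "unspecified"))
}

#' Verify a variant's reference amino acid against a coding sequence
#'
#' Protein position `p` corresponds to CDS bases `3p-2..3p` (1-based;
#' CDS files are assumed to start at the initiator codon). The codon at
#' that location must translate to the recorded reference amino acid;
#' otherwise the CDS is incompatible with the record.
#'
#' @param ref_aa One-letter reference amino acid (`"*"` for stop).
#' @param aa_pos Protein position (1-based).
#' @param cds Coding sequence (`nucseq` or character, DNA).
#' @return list with `ok` (logical), `codon` (the 3-mer, `NA` on
#'   failure), `codon_index` (= `aa_pos`), and `reason` (`"ok"`,
#'   `"position_beyond_cds"`, or `"ref_aa_mismatch"`).
#' @export
verify_against_cds <- function(ref_aa, aa_pos, cds) {
  s <- chartr("U", "T", unclass(nucseq(cds)))
  attributes(s) <- NULL
  if (is.na(aa_pos) || 3L * aa_pos > nchar(s))
    return(list(ok = FALSE, codon = NA_character_, codon_index = aa_pos,
                reason = "position_beyond_cds"))
  codon <- substr(s, 3L * aa_pos - 2L, 3L * aa_pos)
  if (translate_codon(codon) != ref_aa)
    return(list(ok = FALSE, codon = codon, codon_index = aa_pos,
                reason = "ref_aa_mismatch"))
  list(ok = TRUE, codon = codon, codon_index = aa_pos, reason = "ok")
}

#' Resolve whether a SNP corresponds to a C>U mRNA change
#'
#' Enumerates the (at most nine) single-nucleotide changes of the
#' verified codon, keeps those that produce the recorded alternate
#' amino acid, and disambiguates with the genomic alleles: a candidate
#' codon change (from, to) is allele-consistent when it equals
#' (ref, alt) directly (gene transcribed from the plus strand) or
#' equals its complement (minus-strand gene, so a genomic G>A reads as
#' a coding C>T). The SNP is a C>U site exactly when the single
#' consistent candidate is a coding-strand C-to-T change.
#'
#' @param ref_aa,alt_aa One-letter amino acids of the recorded change.
#' @param codon The verified 3-mer at the protein position.
#' @param codon_index Protein position (1-based).
#' @param ref_allele,alt_allele Genomic alleles (single DNA bases).
#' @param allele_check Require allele consistency (default `TRUE`).
#'   When `FALSE`, only the amino-acid change is used and all
#'   candidates must agree.
#' @return list with `status` (`"cu_site"`, `"not_cu"`,
#'   `"aa_change_not_reproducible"`, `"allele_inconsistent"`, or
#'   `"ambiguous_codon_change"`), and for resolved sites
#'   `cds_position` (1-based position of the changed base),
#'   `position_in_codon`, `from_base`, `to_base`.
#' @export
resolve_cu_change <- function(ref_aa, alt_aa, codon, codon_index,
                              ref_allele, alt_allele, allele_check = TRUE) {
  cv <- strsplit(codon, "")[[1]]
  cand <- list()
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), cv[p])) {
      nv <- cv; nv[p] <- b
      if (translate_codon(paste(nv, collapse = "")) == alt_aa)
        cand[[length(cand) + 1L]] <- c(pos = p, from = cv[p], to = b)
    }
  }
  if (length(cand) == 0L)
    return(list(status = "aa_change_not_reproducible"))
  if (allele_check) {
    ok <- vapply(cand, function(cc) {
      (cc[["from"]] == ref_allele && cc[["to"]] == alt_allele) ||
        (cc[["from"]] == complement_base(ref_allele) &&
           cc[["to"]] == complement_base(alt_allele))
    }, logical(1))
    cand <- cand[ok]
    if (length(cand) == 0L)
      return(list(status = "allele_inconsistent"))
  }
  if (length(cand) > 1L)
    return(list(status = "ambiguous_codon_change"))
  cc <- cand[[1L]]
  pos <- as.integer(cc[["pos"]])
  list(
    status = if (cc[["from"]] == "C" && cc[["to"]] == "T") "cu_site"
             else "not_cu",
    cds_position = 3L * (codon_index - 1L) + pos,
    position_in_codon = pos,
    from_base = cc[["from"]], to_base = cc[["to"]]
  )
}

#' Run the full variant screen
#'
#' Orchestrates the pipeline: filter parsed variants to exonic
#' non-synonymous SNVs, pick for each gene the longest CDS compatible
#' with all of its variants (genes with no compatible CDS are excluded
#' wholesale), resolve which SNPs correspond to C>U mRNA changes, bin
#' pathogenicity, and annotate each C>U site with the rules-based,
#' forest, union and intersection predictions.
#'
#' @param records Output of [parse_variant_table()].
#' @param cds Either a directory of per-gene FASTA files (named
#'   `<GENE>.fa`/`.fasta`, possibly multi-record) or a named list /
#'   character vector of CDS sequences (names may carry a `GENE` or
#'   `GENE|isoform` convention; everything after `|` is ignored).
#' @param forest Optional trained `cusee_forest`; when `NULL`, forest
#'   and consensus columns are `NA` and predictions reduce to the rules
#'   model.
#' @param rules_cfg A [rules_config()].
#' @param assembly Assembly filter passed to [filter_variants()].
#' @param allele_check Passed to [resolve_cu_change()].
#' @return list with `variants` (annotated table: one row per retained,
#'   CDS-verified variant with `is_cu`, `cds_position`, `bin`,
#'   `rules_score`, `call_rules`, `forest_prob`, `call_forest`,
#'   `call_union`, `call_intersection`), `exclusions` (one row per
#'   excluded record with its reason), and `summary` (counts and
#'   percentages of pathogenicity bins within the exonic, C>U, and
#'   predicted sets, per consensus model).
#' @export
run_screen <- function(records, cds, forest = NULL,
                       rules_cfg = rules_config(), assembly = "GRCh38",
                       allele_check = TRUE) {
  records$row_id <- seq_len(nrow(records))
  flt <- filter_variants(records, assembly = assembly)
  kept <- flt$kept
  excl <- flt$excluded[, c("row_id", "gene", "name", "reason")]

  cds_by_gene <- load_cds_collection(cds)
  out_rows <- list(); excl_rows <- list(excl)
  if (nrow(kept) > 0) for (g in unique(kept$gene)) {
    gv <- kept[kept$gene == g, , drop = FALSE]
    seqs <- cds_by_gene[[g]]
    if (is.null(seqs) || length(seqs) == 0L) {
      excl_rows[[length(excl_rows) + 1L]] <-
        data.frame(row_id = gv$row_id, gene = g, name = gv$name,
                   reason = "cds_missing")
      next
    }
    # longest CDS compatible with every variant of the gene
    seqs <- seqs[order(-nchar(seqs))]
    chosen <- NULL
    for (s in seqs) {
      ok <- vapply(seq_len(nrow(gv)), function(i)
        verify_against_cds(gv$ref_aa[i], gv$aa_pos[i], s)$ok, logical(1))
      if (all(ok)) { chosen <- s; break }
    }
    if (is.null(chosen)) {
      excl_rows[[length(excl_rows) + 1L]] <-
        data.frame(row_id = gv$row_id, gene = g, name = gv$name,
                   reason = "cds_mismatch")
      next
    }
    for (i in seq_len(nrow(gv))) {
      ver <- verify_against_cds(gv$ref_aa[i], gv$aa_pos[i], chosen)
      res <- resolve_cu_change(gv$ref_aa[i], gv$alt_aa[i], ver$codon,
                               ver$codon_index, gv$ref_allele[i],
                               gv$alt_allele[i], allele_check = allele_check)
      if (res$status %in% c("aa_change_not_reproducible",
                            "allele_inconsistent",
                            "ambiguous_codon_change")) {
        excl_rows[[length(excl_rows) + 1L]] <-
          data.frame(row_id = gv$row_id[i], gene = g, name = gv$name[i],
                     reason = res$status)
        next
      }
      out_rows[[length(out_rows) + 1L]] <- data.frame(
        row_id = gv$row_id[i], gene = g, name = gv$name[i],
        ref_aa = gv$ref_aa[i], aa_pos = gv$aa_pos[i], alt_aa = gv$alt_aa[i],
        is_cu = res$status == "cu_site",
        cds_position = res$cds_position,
        bin = bin_significance(gv$significance[i]),
        cds = chosen, stringsAsFactors = FALSE
      )
    }
  }
  variants <- if (length(out_rows)) do.call(rbind, out_rows) else
    data.frame(row_id = integer(), gene = character(), name = character(),
               ref_aa = character(), aa_pos = integer(),
               alt_aa = character(), is_cu = logical(),
               cds_position = integer(), bin = character(),
               cds = character())
  variants <- annotate_predictions(variants, forest, rules_cfg)
  variants$cds <- NULL
  exclusions <- do.call(rbind, excl_rows)
  rownames(variants) <- rownames(exclusions) <- NULL
  list(variants = variants, exclusions = exclusions,
       summary = screen_summary(variants))
}

# Accept a directory of per-gene FASTA files or an in-memory named
# collection; returns list(gene -> named character vector of CDSs).
load_cds_collection <- function(cds) {
  if (is.character(cds) && length(cds) == 1L && dir.exists(cds)) {
    files <- list.files(cds, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    out <- list()
    for (f in files) {
      g <- sub("\\.(fa|fasta)$", "", basename(f))
      out[[g]] <- read_fasta(f)
    }
    return(out)
  }
  seqs <- unlist(as.list(cds))
  if (is.null(names(seqs))) stop("CDS collection must be named by gene")
  genes <- sub("\\|.*$", "", names(seqs))
  split(stats::setNames(seqs, names(seqs)), genes)
}

# Rules / forest / consensus predictions at each C>U site, evaluated on
# the transcribed CDS context.
annotate_predictions <- function(variants, forest, rules_cfg) {
  n <- nrow(variants)
  variants$rules_score <- rep(NA_integer_, n)
  variants$call_rules <- rep(NA, n)
  variants$forest_prob <- rep(NA_real_, n)
  variants$call_forest <- rep(NA, n)
  variants$call_union <- rep(NA, n)
  variants$call_intersection <- rep(NA, n)
  for (i in seq_len(n)) {
    if (!variants$is_cu[i]) next
    s <- variants$cds[i]; p <- variants$cds_position[i]
    r <- score_site(s, p, rules_cfg)
    variants$rules_score[i] <- if (is.null(r$best)) NA_integer_ else
      r$best$total
    variants$call_rules[i] <- r$call
    if (!is.null(forest)) {
      fp <- predict_site(forest, s, p)
      variants$forest_prob[i] <- fp$prob
      variants$call_forest[i] <- fp$call
      variants$call_union[i] <- consensus_call(r$call, fp$call, "union")
      variants$call_intersection[i] <-
        consensus_call(r$call, fp$call, "intersection")
    }
  }
  variants
}

# Pathogenicity-bin breakdown of the exonic / C>U / predicted sets.
screen_summary <- function(variants, model = "call_union") {
  bins <- c("pathogenic", "benign", "unspecified")
  sets <- list(
    all_exonic = variants,
    cu = variants[variants$is_cu, , drop = FALSE],
    predicted = variants[variants$is_cu &
                           !is.na(variants[[model]]) &
                           variants[[model]], , drop = FALSE]
  )
  out <- lapply(names(sets), function(nm) {
    d <- sets[[nm]]
    cnt <- table(factor(d$bin, levels = bins))
    data.frame(set = nm, bin = bins, n = as.integer(cnt),
               percent = if (nrow(d) > 0)
                 round(100 * as.integer(cnt) / nrow(d), 1) else NA_real_)
  })
  do.call(rbind, out)
}
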