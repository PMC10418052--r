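# Minimal variant-table rows in the variant_summary dialect.
make_rows <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    base <- data.frame(
      Type = "single nucleotide variant", GeneSymbol = "GENE1",
      Name = "NM_1.1(GENE1):c.4C>T (p.Arg2Trp)",
      ClinicalSignificance = "Pathogenic", Assembly = "GRCh38",
      ReferenceAlleleVCF = "C", AlternateAlleleVCF = "T",
      PhenotypeList = "cond", check.names = FALSE,
      stringsAsFactors = FALSE
    )
    for (nm in names(r)) base[[nm]] <- r[[nm]]
    base
  }))
}

test_that("variant-table parsing extracts fields and protein changes", {
  tab <- make_rows(
    list(Name = "NM_1.1(GENE1):c.4C>T (p.Arg2Trp)"),
    list(Name = "NM_2.1(GENE2):c.88G>A (p.V30M)", GeneSymbol = "GENE2"),
    list(Name = "NM_3.1(GENE3):c.1A>G", GeneSymbol = "GENE3")
  )
  rec <- parse_variant_table(tab)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$gene, c("GENE1", "GENE2", "GENE3"))  # order preserved
  expect_equal(rec$ref_aa[1], "R"); expect_equal(rec$alt_aa[1], "W")
  expect_equal(rec$aa_pos[1], 2L)
  expect_equal(rec$ref_aa[2], "V"); expect_equal(rec$alt_aa[2], "M")
  expect_true(is.na(rec$ref_aa[3]))  # no p. suffix
  # nonsense and synonymous notations
  tab2 <- make_rows(list(Name = "x (p.Arg2Ter)"),
                    list(Name = "x (p.Arg2*)"),
                    list(Name = "x (p.Arg2=)"))
  rec2 <- parse_variant_table(tab2)
  expect_equal(rec2$alt_aa, c("*", "*", "R"))
  # round-trip through an on-disk TSV
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(parse_variant_table(f), rec)
})

test_that("a missing mandatory column is reported by name", {
  tab <- make_rows(list())
  tab$Assembly <- NULL
  expect_error(parse_variant_table(tab), "Assembly")
})

test_that("filters exclude the documented record classes", {
  tab <- make_rows(
    list(),                                              # retained
    list(Type = "Deletion"),                             # not_snv
    list(Assembly = "GRCh37"),                           # wrong_assembly
    list(AlternateAlleleVCF = "X"),                      # nonspecific
    list(ReferenceAlleleVCF = "A", AlternateAlleleVCF = "A"),  # like-to-like
    list(Name = "no protein change here"),               # no_protein_change
    list(Name = "x (p.Lys5Lys)")                         # synonymous
  )
  rec <- parse_variant_table(tab)
  flt <- filter_variants(rec)
  expect_equal(nrow(flt$kept), 1L)
  expect_equal(flt$excluded$reason,
               c("not_snv", "wrong_assembly", "nonspecific_allele",
                 "like_to_like", "no_protein_change", "synonymous"))
  # conservation: every record lands in exactly one bucket
  expect_equal(nrow(flt$kept) + nrow(flt$excluded), nrow(rec))
  expect_equal(sum(flt$counts), nrow(rec))
})

test_that("significance binning is total and handles precedence", {
  expect_equal(bin_significance("Likely pathogenic"), "pathogenic")
  expect_equal(bin_significance("Benign/Likely benign"), "benign")
  expect_equal(bin_significance("Uncertain significance"), "unspecified")
  expect_equal(bin_significance("PATHOGENIC"), "pathogenic")
  # pathogenic takes precedence when both words occur
  expect_equal(bin_significance("Benign; Pathogenic"), "pathogenic")
  # conflicting assertions are not pathogenicity assertions
  expect_equal(bin_significance("Conflicting interpretations of pathogenicity"),
               "unspecified")
  expect_equal(
    bin_significance("Conflicting interpretations of pathogenicity; Benign"),
    "benign")
  expect_equal(bin_significance(c("", NA)), c("unspecified", "unspecified"))
})

test_that("CDS verification checks the codon at the protein position", {
  cds <- "ATGCGGAAATTT"
  ok <- verify_against_cds("R", 2L, cds)   # codon 2 = CGG = Arg
  expect_true(ok$ok)
  expect_equal(ok$codon, "CGG")
  bad <- verify_against_cds("R", 3L, cds)  # codon 3 = AAA = Lys
  expect_false(bad$ok)
  expect_equal(bad$reason, "ref_aa_mismatch")
  oob <- verify_against_cds("R", 9L, cds)
  expect_false(oob$ok)
  expect_equal(oob$reason, "position_beyond_cds")
})

test_that("C>U resolution distinguishes strand and detects ambiguity", {
  # CGG (Arg) -> Trp: only TGG; genomic C>T matches directly
  r1 <- resolve_cu_change("R", "W", "CGG", 2L, "C", "T")
  expect_equal(r1$status, "cu_site")
  expect_equal(r1$cds_position, 4L)      # codon 2, position 1
  expect_equal(r1$position_in_codon, 1L)
  # same change reported with minus-strand alleles (G>A): complement
  r2 <- resolve_cu_change("R", "W", "CGG", 2L, "G", "A")
  expect_equal(r2$status, "cu_site")
  # GGA (Gly) -> Arg via genomic G>A: a coding G>A, not C>U
  r3 <- resolve_cu_change("G", "R", "GGA", 3L, "G", "A")
  expect_equal(r3$status, "not_cu")
  expect_equal(r3$from_base, "G"); expect_equal(r3$to_base, "A")
  # TGG (Trp) -> Ter: both TGA and TAG arise from G>A; alleles cannot
  # disambiguate
  r4 <- resolve_cu_change("W", "*", "TGG", 5L, "G", "A")
  expect_equal(r4$status, "ambiguous_codon_change")
  # no single-nucleotide change of ATG yields Pro
  r5 <- resolve_cu_change("M", "P", "ATG", 1L, "A", "C")
  expect_equal(r5$status, "aa_change_not_reproducible")
  # alleles incompatible with every candidate
  r6 <- resolve_cu_change("R", "W", "CGG", 2L, "A", "G")
  expect_equal(r6$status, "allele_inconsistent")
  # without the allele check a unique candidate still resolves
  r7 <- resolve_cu_change("R", "W", "CGG", 2L, "A", "G",
                          allele_check = FALSE)
  expect_equal(r7$status, "cu_site")
})

test_that("the screen recovers planted truth on a synthetic fixture", {
  fx <- gen_variant_fixture(n_genes = 4, n_variants = 16, frac_cu = 0.25,
                            frac_pathogenic = 0.25, seed = 51)
  rec <- parse_variant_table(fx$variants)
  scr <- run_screen(rec, fx$cds)
  truth <- fx$truth[fx$truth$reason == "retained", ]
  got <- scr$variants
  expect_equal(nrow(got), nrow(truth))
  # exact C>U recovery, including minus-strand (G>A) presentations
  expect_setequal(paste(got$gene, got$cds_position)[got$is_cu],
                  paste(truth$gene, truth$cds_position)[truth$is_cu])
  expect_equal(sum(got$is_cu), 4L)
  minus <- truth[truth$is_cu & truth$strand == "-", ]
  expect_gt(nrow(minus), 0)
  expect_true(all(paste(minus$gene, minus$cds_position) %in%
                    paste(got$gene, got$cds_position)[got$is_cu]))
  # bins match the planted assignment row by row
  m <- match(got$row_id, seq_len(nrow(fx$truth)))
  expect_equal(got$bin, fx$truth$bin[m])
  # every edge-case row lands in its named exclusion bucket
  edge <- fx$truth[fx$truth$reason != "retained", ]
  excl <- scr$exclusions
  for (i in seq_len(nrow(edge)))
    expect_true(any(excl$gene == edge$gene[i] &
                      excl$reason == edge$reason[i]),
                info = edge$reason[i])
  # conservation of records
  expect_equal(nrow(got) + nrow(excl), nrow(rec))
})

test_that("screen handles empty input and all-benign fixtures", {
  rec <- parse_variant_table(make_rows(list())[0, ])
  scr <- run_screen(rec, list(GENE1 = "ATGCGGAAA"))
  expect_equal(nrow(scr$variants), 0L)
  expect_true(all(scr$summary$n == 0L))
  # all-benign: pathogenic rows are zero
  fx <- gen_variant_fixture(n_genes = 3, n_variants = 8, frac_cu = 0.25,
                            frac_pathogenic = 0, seed = 52,
                            include_edge_cases = FALSE)
  scr2 <- run_screen(parse_variant_table(fx$variants), fx$cds)
  s <- scr2$summary
  expect_true(all(s$n[s$bin == "pathogenic"] == 0L))
})

test_that("missing CDS files exclude the whole gene", {
  fx <- gen_variant_fixture(n_genes = 3, n_variants = 6, seed = 53,
                            include_edge_cases = FALSE)
  cds <- fx$cds[setdiff(names(fx$cds), "GENE01")]
  scr <- run_screen(parse_variant_table(fx$variants), cds)
  gone <- scr$exclusions[scr$exclusions$reason == "cds_missing", ]
  expect_true(all(gone$gene == "GENE01"))
  expect_false("GENE01" %in% scr$variants$gene)
})

test_that("CDS collections load from a per-gene FASTA directory", {
  fx <- gen_variant_fixture(n_genes = 2, n_variants = 4, seed = 54,
                            include_edge_cases = FALSE)
  dir <- withr::local_tempdir()
  for (g in names(fx$cds))
    write_fasta(setNames(fx$cds[g], g), file.path(dir, paste0(g, ".fa")))
  scr_dir <- run_screen(parse_variant_table(fx$variants), dir)
  scr_mem <- run_screen(parse_variant_table(fx$variants), fx$cds)
  expect_equal(scr_dir$variants, scr_mem$variants)
})
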