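# Fixture generators. Every generator is seeded and restores the
# caller's RNG state, so identical seeds reproduce identical fixtures.

# Random DNA background at a given GC content.
random_bases <- function(n, gc_content = 0.5) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc_content) / 2, (1 - gc_content) / 2,
                  gc_content / 2, gc_content / 2))
}

#' Generate labeled editing/non-editing sites with planted hairpins
#'
#' Positives embed a designed stem-loop whose rules score is at least
#' the call threshold: a stem of 2-4 GC plus 0-2 AU pairs (at least 3
#' pairs total) whose loop-proximal pair places a purine directly after
#' the target cytosine, closing a 3-4 nt loop that ends in the target
#' C, contains a U, and no G. Negatives are random windows whose
#' central cytosine is rejection-sampled until the rules-based model
#' makes no call on it. Each site is emitted as its own 51-nt
#' mini-transcript with the target C at position 26.
#'
#' @param n_pos,n_neg Numbers of editing / non-editing sites.
#' @param cfg [rules_config()] the negatives are rejected against.
#' @param seed Integer seed.
#' @param gc_content Background GC fraction. Default 0.5; high values
#'   inflate accidental hairpins and may exhaust rejection sampling.
#' @param max_retries Rejection-sampling cap per negative site.
#' @return list with `sites` (data.frame `gene`, `position`, `context`,
#'   `label`, `planted_score`), `sequences` (named character vector),
#'   and `manifest` (seed and parameters).
#' @export
gen_hairpin_dataset <- function(n_pos, n_neg, cfg = rules_config(),
                                seed = 1L, gc_content = 0.5,
                                max_retries = 100L) {
  stopifnot(n_pos >= 1L, n_neg >= 0L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  win <- 2L * CONTEXT_FLANK + 1L
  c_at <- CONTEXT_FLANK + 1L

  make_positive <- function() {
    L <- sample(3:4, 1L)
    # loop: L-1 bases over {A, U, C} with >= 1 U, then the target C
    loop <- sample(c("A", "T", "C"), L - 1L, replace = TRUE)
    if (!"T" %in% loop) loop[sample(L - 1L, 1L)] <- "T"
    loop <- c(loop, "C")
    n_gc <- sample(2:4, 1L)
    n_au <- sample(max(0L, cfg$min_stem_pairs - n_gc):2L, 1L)
    # loop-proximal pair is C:G so the base after the C is a purine
    pairs <- list(c("C", "G"))
    others <- c(replicate(n_gc - 1L, sample(c("C", "G"))[c(1, 2)],
                          simplify = FALSE),
                replicate(n_au, sample(c("A", "T"))[c(1, 2)],
                          simplify = FALSE))
    if (length(others)) pairs <- c(pairs, sample(others))
    stem_len <- length(pairs)
    up <- vapply(pairs, `[`, "", 1L)   # loop-proximal outward
    dn <- vapply(pairs, `[`, "", 2L)
    hairpin <- c(rev(up), loop, dn)
    h_c <- stem_len + L                # index of the C in the hairpin
    left <- c_at - h_c
    right <- win - left - length(hairpin)
    window <- c(random_bases(left, gc_content), hairpin,
                random_bases(right, gc_content))
    score <- 3L * n_gc + n_au + 2L + 2L  # stem + U-in-loop + purine bonuses
    list(context = paste(window, collapse = ""), planted_score = score)
  }

  make_negative <- function() {
    for (k in seq_len(max_retries)) {
      window <- random_bases(win, gc_content)
      window[c_at] <- "C"
      ctx <- paste(window, collapse = "")
      if (!score_site(ctx, c_at, cfg)$call)
        return(ctx)
    }
    stop("rejection sampling failed after ", max_retries,
         " tries; lower gc_content")
  }

  pos <- replicate(n_pos, make_positive(), simplify = FALSE)
  neg <- if (n_neg > 0L) replicate(n_neg, make_negative()) else character(0)
  sites <- data.frame(
    gene = c(sprintf("pos_%04d", seq_len(n_pos)),
             if (n_neg > 0L) sprintf("neg_%04d", seq_len(n_neg))),
    position = c_at,
    context = c(vapply(pos, `[[`, "", "context"), neg),
    label = c(rep(1L, n_pos), rep(0L, n_neg)),
    planted_score = c(vapply(pos, `[[`, 0L, "planted_score"),
                      rep(NA_integer_, n_neg)),
    stringsAsFactors = FALSE
  )
  sequences <- stats::setNames(sites$context, sites$gene)
  list(sites = sites, sequences = sequences,
       manifest = list(seed = seed, n_pos = n_pos, n_neg = n_neg,
                       gc_content = gc_content,
                       rules_config = unclass(cfg)))
}

# Non-stop codons of the standard code.
non_stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

aa_three_letter <- function(aa1) {
  names(AA_3TO1)[match(aa1, AA_3TO1)]
}

#' Generate an internally consistent CDS + variant-table fixture
#'
#' Builds per-gene coding sequences (ATG start, no internal stops, TAA
#' stop) and a variant table in the ClinVar variant_summary dialect
#' whose C>U truth is known by construction: `round(frac_cu *
#' n_variants)` variants are coding-strand C-to-T changes (half
#' reported with genomic alleles C>T as on a plus-strand gene, half
#' reported as G>A as on a minus-strand gene), the rest are
#' non-synonymous changes that are not C>U. Every planted change is
#' verified during construction to be uniquely resolvable from its
#' amino-acid change and alleles. Optional edge-case rows exercise each
#' exclusion filter: a Deletion record, a GRCh37 duplicate, a
#' like-to-like allele pair, a synonymous protein change, and a gene
#' whose CDS contradicts the recorded reference amino acid.
#'
#' @param n_genes Number of genes. Default 5.
#' @param n_variants Number of core (retained) variant rows. Default
#'   20.
#' @param frac_cu Fraction of core variants that are C>U sites.
#' @param frac_pathogenic Fraction of core variants binned pathogenic;
#'   the remainder are split between benign and unspecified.
#' @param seed Integer seed.
#' @param n_codons Codons per CDS (including start and stop). Default
#'   40.
#' @param include_edge_cases Append the five filter edge-case rows.
#' @return list with `cds` (named character vector, gene to sequence),
#'   `variants` (data.frame in the variant_summary dialect), `truth`
#'   (per-row data.frame: `gene`, `aa_pos`, `cds_position`, `is_cu`,
#'   `strand`, `bin`, `reason`), and `manifest`.
#' @export
gen_variant_fixture <- function(n_genes = 5L, n_variants = 20L,
                                frac_cu = 0.2, frac_pathogenic = 0.3,
                                seed = 1L, n_codons = 40L,
                                include_edge_cases = TRUE) {
  stopifnot(frac_cu >= 0, frac_cu <= 1,
            frac_pathogenic >= 0, frac_pathogenic <= 1, n_codons >= 5L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  genes <- sprintf("GENE%02d", seq_len(n_genes))
  pool <- non_stop_codons()
  cds <- vapply(genes, function(g)
    paste(c("ATG", sample(pool, n_codons - 2L, replace = TRUE), "TAA"),
          collapse = ""), "")

  n_cu <- round(frac_cu * n_variants)
  used <- character(0)

  # find a codon-level change satisfying `want_cu`, uniquely resolvable
  draw_change <- function(want_cu) {
    repeat {
      g <- sample(genes, 1L)
      ci <- sample(2:(n_codons - 1L), 1L)
      key <- paste(g, ci)
      if (key %in% used) next
      codon <- substr(cds[[g]], 3L * ci - 2L, 3L * ci)
      cv <- strsplit(codon, "")[[1]]
      opts <- list()
      for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), cv[p])) {
        nv <- cv; nv[p] <- b
        alt <- translate_codon(paste(nv, collapse = ""))
        ref <- translate_codon(codon)
        if (alt == ref) next
        is_ct <- cv[p] == "C" && b == "T"
        if (want_cu != is_ct) next
        opts[[length(opts) + 1L]] <- list(pos = p, from = cv[p], to = b,
                                          ref_aa = ref, alt_aa = alt)
      }
      if (length(opts) == 0L) next
      ch <- opts[[sample(length(opts), 1L)]]
      # construction-time uniqueness: the amino-acid change plus the
      # allele pair (read on either strand) must single out this change
      consistent <- 0L
      for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), cv[p])) {
        nv <- cv; nv[p] <- b
        if (translate_codon(paste(nv, collapse = "")) != ch$alt_aa) next
        if ((cv[p] == ch$from && b == ch$to) ||
            (cv[p] == complement_base(ch$from) &&
               b == complement_base(ch$to)))
          consistent <- consistent + 1L
      }
      if (consistent != 1L) next
      used <<- c(used, key)
      return(c(list(gene = g, codon_index = ci, codon = codon), ch))
    }
  }

  changes <- c(replicate(n_cu, draw_change(TRUE), simplify = FALSE),
               replicate(n_variants - n_cu, draw_change(FALSE),
                         simplify = FALSE))
  changes <- sample(changes)  # shuffle C>U rows among the rest

  # strand presentation: half of the C>U rows (and of the others) are
  # reported with minus-strand (complemented) genomic alleles
  is_cu <- vapply(changes, function(ch) ch$from == "C" && ch$to == "T",
                  logical(1))
  strand <- rep("+", n_variants)
  for (grp in list(which(is_cu), which(!is_cu))) {
    if (length(grp) > 1L)
      strand[grp[seq_len(floor(length(grp) / 2))]] <- "-"
  }

  n_path <- round(frac_pathogenic * n_variants)
  n_ben <- floor((n_variants - n_path) / 2)
  bins <- sample(c(rep("pathogenic", n_path), rep("benign", n_ben),
                   rep("unspecified", n_variants - n_path - n_ben)))
  sig_for <- function(bin) switch(bin,
    pathogenic = sample(c("Pathogenic", "Likely pathogenic"), 1L),
    benign = sample(c("Benign", "Benign/Likely benign"), 1L),
    unspecified = sample(c("Uncertain significance", "not provided"), 1L))

  row_for <- function(ch, strand, sig, id) {
    ref <- if (strand == "+") ch$from else complement_base(ch$from)
    alt <- if (strand == "+") ch$to else complement_base(ch$to)
    data.frame(
      Type = "single nucleotide variant",
      GeneSymbol = ch$gene,
      Name = sprintf("NM_%05d.1(%s):c.%d%s>%s (p.%s%d%s)",
                     match(ch$gene, genes), ch$gene,
                     3L * (ch$codon_index - 1L) + ch$pos, ch$from, ch$to,
                     aa_three_letter(ch$ref_aa), ch$codon_index,
                     aa_three_letter(ch$alt_aa)),
      ClinicalSignificance = sig,
      Assembly = "GRCh38",
      ReferenceAlleleVCF = ref, AlternateAlleleVCF = alt,
      PhenotypeList = paste(sprintf("condition_%02d",
                                    sample(10L, sample(1:3, 1L))),
                            collapse = ";"),
      AlleleID = as.character(id),
      `RS# (dbSNP)` = as.character(sample(1e6, 1L)),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }

  rows <- vector("list", n_variants)
  truth <- vector("list", n_variants)
  for (i in seq_len(n_variants)) {
    ch <- changes[[i]]
    rows[[i]] <- row_for(ch, strand[i], sig_for(bins[i]), i)
    truth[[i]] <- data.frame(
      allele_id = as.character(i), gene = ch$gene,
      aa_pos = ch$codon_index,
      cds_position = 3L * (ch$codon_index - 1L) + ch$pos,
      is_cu = is_cu[i], strand = strand[i], bin = bins[i],
      reason = "retained", stringsAsFactors = FALSE
    )
  }

  if (include_edge_cases) {
    base <- rows[[1L]]
    edge <- list()
    del <- base; del$Type <- "Deletion"; del$AlleleID <- "E1"
    g37 <- base; g37$Assembly <- "GRCh37"; g37$AlleleID <- "E2"
    l2l <- base; l2l$ReferenceAlleleVCF <- "A"; l2l$AlternateAlleleVCF <- "A"
    l2l$AlleleID <- "E3"
    syn <- base
    ch1 <- changes[[1L]]
    syn$Name <- sprintf("NM_%05d.1(%s):c.%dA>G (p.%s%d%s)",
                        match(ch1$gene, genes), ch1$gene,
                        3L * (ch1$codon_index - 1L) + 1L,
                        aa_three_letter(ch1$ref_aa), ch1$codon_index,
                        aa_three_letter(ch1$ref_aa))
    syn$AlleleID <- "E4"
    mm_gene <- "GENEMM"
    cds[[mm_gene]] <- paste(c("ATG", sample(pool, 8L, replace = TRUE),
                              "TAA"), collapse = "")
    mm_codon <- substr(cds[[mm_gene]], 4L, 6L)
    mm_ref <- translate_codon(mm_codon)
    wrong <- setdiff(setdiff(unname(AA_3TO1), "*"), mm_ref)[1L]
    mm <- base; mm$GeneSymbol <- mm_gene; mm$AlleleID <- "E5"
    mm$Name <- sprintf("NM_99999.1(%s):c.4A>G (p.%s2%s)", mm_gene,
                       aa_three_letter(wrong), aa_three_letter("G"))
    edge <- list(del, g37, l2l, syn, mm)
    edge_reason <- c("not_snv", "wrong_assembly", "like_to_like",
                     "synonymous", "cds_mismatch")
    for (j in seq_along(edge)) {
      rows[[length(rows) + 1L]] <- edge[[j]]
      truth[[length(truth) + 1L]] <- data.frame(
        allele_id = edge[[j]]$AlleleID, gene = edge[[j]]$GeneSymbol,
        aa_pos = NA_integer_, cds_position = NA_integer_,
        is_cu = FALSE, strand = NA_character_, bin = NA_character_,
        reason = edge_reason[j], stringsAsFactors = FALSE
      )
    }
  }

  variants <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  rownames(variants) <- rownames(truth) <- NULL
  list(cds = cds, variants = variants, truth = truth,
       manifest = list(seed = seed, n_genes = n_genes,
                       n_variants = n_variants, frac_cu = frac_cu,
                       frac_pathogenic = frac_pathogenic,
                       n_codons = n_codons,
                       include_edge_cases = include_edge_cases))
}

#' Generate a toy MeSH tree with known rollup truth
#'
#' Builds a regular forest: `branching` top-level headings, each node
#' having `branching` children down to `depth` levels (so each
#' top-level term has `branching^2` grandchildren when `depth >= 3`).
#' One condition is created per node (mapped to that node's heading)
#' plus a few "Not found" conditions. SNPs draw 1-3 conditions each.
#' Expected per-top-level counts and grandchild coverage are computed
#' at construction time by direct tree-number prefix arithmetic, so
#' they are independent of the rollup implementation.
#'
#' @param branching Children per node. Default 3.
#' @param depth Tree depth (levels); must be >= 3 so grandchildren
#'   exist. Default 3.
#' @param n_snps Number of SNPs. Default 12.
#' @param frac_notfound Probability that a drawn condition is an
#'   unmapped ("Not found") one. Default 0.1.
#' @param seed Integer seed.
#' @return list with `tree_lines` (the `Heading;TreeNumber` file
#'   content), `condition_map` (data.frame `condition`, `heading`),
#'   `snps` (data.frame `snp_id`, `bin`, `conditions`, `predicted`),
#'   `assignments` (data.frame `snp_id`, `heading`, `predicted`, one
#'   row per SNP-heading pair, for coverage analysis), and `truth`
#'   (list: `top_counts`, `coverage`).
#' @export
gen_mesh_fixture <- function(branching = 3L, depth = 3L, n_snps = 12L,
                             frac_notfound = 0.1, seed = 1L) {
  stopifnot(depth >= 3L, branching >= 1L, n_snps >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  codes <- sprintf("C%02d", seq_len(branching))
  all_codes <- codes
  frontier <- codes
  for (d in seq_len(depth - 1L)) {
    frontier <- unlist(lapply(frontier, function(p)
      paste0(p, ".", sprintf("%03d", 100L * seq_len(branching)))))
    all_codes <- c(all_codes, frontier)
  }
  heading_of <- function(code) paste0("H_", code)
  tree_lines <- paste0(heading_of(all_codes), ";", all_codes)

  n_nf <- max(1L, round(frac_notfound * length(all_codes)))
  condition_map <- rbind(
    data.frame(condition = paste0("cond_", all_codes),
               heading = heading_of(all_codes), stringsAsFactors = FALSE),
    data.frame(condition = sprintf("cond_nf_%02d", seq_len(n_nf)),
               heading = "Not found", stringsAsFactors = FALSE)
  )

  bins <- c("pathogenic", "benign", "unspecified")
  snp_rows <- vector("list", n_snps)
  assign_rows <- list()
  top_of <- function(code) sub("\\..*$", "", code)
  snp_tops <- vector("list", n_snps)
  for (i in seq_len(n_snps)) {
    k <- sample(1:3, 1L)
    conds <- unique(vapply(seq_len(k), function(j) {
      if (stats::runif(1) < frac_notfound)
        sample(condition_map$condition[condition_map$heading == "Not found"], 1L)
      else paste0("cond_", sample(all_codes, 1L))
    }, ""))
    pred <- stats::runif(1) < 0.5
    snp_rows[[i]] <- data.frame(
      snp_id = sprintf("snp_%03d", i), bin = sample(bins, 1L),
      conditions = paste(conds, collapse = ";"), predicted = pred,
      stringsAsFactors = FALSE
    )
    heads <- condition_map$heading[match(conds, condition_map$condition)]
    for (h in unique(heads))
      assign_rows[[length(assign_rows) + 1L]] <- data.frame(
        snp_id = snp_rows[[i]]$snp_id, heading = h, predicted = pred,
        stringsAsFactors = FALSE)
    node_codes <- sub("^cond_", "", conds[heads != "Not found"])
    snp_tops[[i]] <- unique(c(
      if (length(node_codes)) heading_of(unique(top_of(node_codes))),
      if (any(heads == "Not found")) "Not found"
    ))
  }
  snps <- do.call(rbind, snp_rows)
  assignments <- do.call(rbind, assign_rows)

  # expected counts: once per SNP per top-level heading
  top_counts <- as.data.frame(table(unlist(snp_tops)),
                              stringsAsFactors = FALSE)
  names(top_counts) <- c("heading", "count")
  top_counts <- top_counts[order(-top_counts$count, top_counts$heading), ]
  rownames(top_counts) <- NULL

  # expected grandchild coverage by direct prefix arithmetic
  lvl <- lengths(strsplit(all_codes, ".", fixed = TRUE))
  gkids <- all_codes[lvl == 3L]
  snp_code_sets <- lapply(seq_len(n_snps), function(i) {
    conds <- strsplit(snps$conditions[i], ";", fixed = TRUE)[[1]]
    heads <- condition_map$heading[match(conds, condition_map$condition)]
    sub("^cond_", "", conds[heads != "Not found"])
  })
  pred_codes <- unique(unlist(snp_code_sets[snps$predicted]))
  any_codes <- unique(unlist(snp_code_sets))
  hit <- function(g, set) any(set == g | startsWith(set, paste0(g, ".")))
  coverage <- do.call(rbind, lapply(codes, function(tc) {
    g <- gkids[startsWith(gkids, paste0(tc, "."))]
    cp <- vapply(g, hit, logical(1), set = pred_codes)
    ca <- vapply(g, hit, logical(1), set = any_codes)
    data.frame(term = heading_of(tc), n_grandchildren = length(g),
               frac_predicted = sum(cp) / length(g),
               frac_cu_only = sum(ca & !cp) / length(g),
               stringsAsFactors = FALSE)
  }))
  rownames(coverage) <- NULL

  list(tree_lines = tree_lines, condition_map = condition_map,
       snps = snps, assignments = assignments,
       truth = list(top_counts = top_counts, coverage = coverage),
       manifest = list(seed = seed, branching = branching, depth = depth,
                       n_snps = n_snps, frac_notfound = frac_notfound))
}
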