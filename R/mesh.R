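#' Parse a MeSH-style tree file
#'
#' One `Heading;TreeNumber` pair per line (the MeSH ASCII tree
#' convention); a heading may appear on several lines with different
#' tree numbers and then belongs to every listed lineage. Every tree
#' number's parent prefix (all but the last dot-separated component)
#' must itself be present, except for top-level numbers; orphans are an
#' error. Duplicate (heading, number) pairs are dropped with a warning.
#'
#' @param path Path to the tree file, or a character vector of lines.
#' @return Object of class `mesh_tree`: a data.frame with `heading`,
#'   `code`, and `level` (number of dot-separated components).
#' @export
parse_mesh_tree <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ";", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed tree line(s): ", paste(lines[bad], collapse = " | "))
  df <- data.frame(heading = trimws(vapply(parts, `[`, "", 1L)),
                   code = trimws(vapply(parts, `[`, "", 2L)),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df)
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicate (heading, code) pair(s)")
    df <- df[!dup, , drop = FALSE]
  }
  if (anyDuplicated(df$code))
    stop("tree number assigned to multiple headings: ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "))
  df$level <- lengths(strsplit(df$code, ".", fixed = TRUE))
  parents <- vapply(df$code, code_parent, "")
  orphan <- !is.na(parents) & !(parents %in% df$code)
  if (any(orphan))
    stop("orphan tree number(s) with missing parent: ",
         paste(df$code[orphan], collapse = ", "))
  rownames(df) <- NULL
  structure(df, class = c("mesh_tree", "data.frame"))
}

# Parent tree number by prefix truncation; NA for top-level codes.
code_parent <- function(code) {
  if (!grepl(".", code, fixed = TRUE)) return(NA_character_)
  sub("\\.[^.]*$", "", code)
}

# All ancestor codes (nearest first), by repeated prefix truncation.
code_ancestors <- function(code) {
  out <- character(0)
  repeat {
    code <- code_parent(code)
    if (is.na(code)) break
    out <- c(out, code)
  }
  out
}

#' Top-level ancestors of a heading
#'
#' Rolls a heading up to the top of every lineage it belongs to. The
#' sentinel `"Not found"` (conditions with no matching heading) is its
#' own top-level heading.
#'
#' @param heading A heading present in `tree`, or `"Not found"`.
#' @param tree A [parse_mesh_tree()] result.
#' @return Character vector of top-level headings (unique, sorted).
#' @export
rollup_top_level <- function(heading, tree) {
  if (heading == "Not found") return("Not found")
  codes <- tree$code[tree$heading == heading]
  if (length(codes) == 0L) stop("unknown heading: ", heading)
  tops <- vapply(codes, function(cd) {
    anc <- code_ancestors(cd)
    root <- if (length(anc)) anc[length(anc)] else cd
    tree$heading[tree$code == root]
  }, "")
  sort(unique(tops))
}

#' Count SNPs per top-level heading
#'
#' Maps each SNP's conditions to headings, rolls every heading up to
#' its top-level ancestors, and counts each top-level heading at most
#' once per SNP, however many of the SNP's conditions roll up to it.
#'
#' @param snps data.frame with columns `snp_id`, `bin`, and
#'   `conditions` (semicolon-joined condition strings; duplicates are
#'   ignored).
#' @param condition_map data.frame with columns `condition` and
#'   `heading` (`"Not found"` allowed); must cover every condition.
#' @param tree A [parse_mesh_tree()] result.
#' @param bin_filter Optional pathogenicity bin; when given, only SNPs
#'   in that bin are counted.
#' @return data.frame `heading`, `count`, sorted by decreasing count.
#' @export
count_headings <- function(snps, condition_map, tree, bin_filter = NULL) {
  if (!is.null(bin_filter))
    snps <- snps[snps$bin == bin_filter, , drop = FALSE]
  tally <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(snps))) {
    conds <- unique(trimws(strsplit(snps$conditions[i], ";", fixed = TRUE)[[1]]))
    conds <- conds[nzchar(conds)]
    if (length(conds) == 0L) next
    idx <- match(conds, condition_map$condition)
    if (anyNA(idx))
      stop("unmapped condition(s): ",
           paste(conds[is.na(idx)], collapse = ", "))
    heads <- unique(condition_map$heading[idx])
    tops <- unique(unlist(lapply(heads, rollup_top_level, tree = tree)))
    for (h in tops)
      assign(h, (if (exists(h, tally, inherits = FALSE)) get(h, tally) else 0L) + 1L,
             envir = tally)
  }
  heads <- ls(tally)
  out <- data.frame(heading = heads,
                    count = vapply(heads, get, 0L, envir = tally),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$heading), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Third-level ("grandchild") disease coverage per top-level heading
#'
#' Treats third-level tree terms as individual diseases. For each
#' requested term, counts its level-3 descendants and the fraction of
#' them "covered": a grandchild is covered by a set of SNPs when any
#' SNP's heading maps to the grandchild itself or to any of its
#' descendants. Two coverage fractions are reported: grandchildren
#' with at least one predicted editing site, and grandchildren with at
#' least one C>U SNP but no predicted site.
#'
#' @param tree A [parse_mesh_tree()] result.
#' @param assignments data.frame with columns `snp_id`, `heading`
#'   (a heading in the tree; `"Not found"` rows are ignored here), and
#'   `predicted` (logical: called an editing site). All rows are
#'   assumed to be C>U SNPs.
#' @param terms Headings to report on; defaults to every top-level
#'   heading. Second-level headings may be supplied, in which case
#'   their level-3 children are the "grandchildren".
#' @return data.frame with `term`, `n_grandchildren`, `frac_predicted`,
#'   `frac_cu_only` (fractions `NA` when a term has no level-3
#'   descendants).
#' @export
grandchild_coverage <- function(tree, assignments, terms = NULL) {
  if (is.null(terms)) terms <- unique(tree$heading[tree$level == 1L])
  assignments <- assignments[assignments$heading != "Not found", ,
                             drop = FALSE]
  idx <- match(assignments$heading, tree$heading)
  if (anyNA(idx))
    stop("assignment heading(s) not in tree: ",
         paste(unique(assignments$heading[is.na(idx)]), collapse = ", "))
  # all codes each SNP-heading assignment maps to
  snp_codes <- lapply(assignments$heading, function(h)
    tree$code[tree$heading == h])
  covered_by <- function(gcode, rows) {
    pref <- paste0(gcode, ".")
    any(vapply(rows, function(cds)
      any(cds == gcode | startsWith(cds, pref)), logical(1)))
  }
  out <- lapply(terms, function(tm) {
    tcodes <- tree$code[tree$heading == tm]
    if (length(tcodes) == 0L) stop("unknown term: ", tm)
    gks <- unique(unlist(lapply(tcodes, function(tc) {
      pref <- paste0(tc, ".")
      tree$code[tree$level == 3L & startsWith(tree$code, pref)]
    })))
    n <- length(gks)
    if (n == 0L)
      return(data.frame(term = tm, n_grandchildren = 0L,
                        frac_predicted = NA_real_, frac_cu_only = NA_real_))
    pred_rows <- snp_codes[assignments$predicted]
    all_rows <- snp_codes
    cov_pred <- vapply(gks, covered_by, logical(1), rows = pred_rows)
    cov_any <- vapply(gks, covered_by, logical(1), rows = all_rows)
    data.frame(term = tm, n_grandchildren = n,
               frac_predicted = sum(cov_pred) / n,
               frac_cu_only = sum(cov_any & !cov_pred) / n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
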