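#' Configuration for the rules-based hairpin model
#'
#' Controls hairpin detection and the score-based editing call.
#' APOBEC3A/G preferentially deaminate cytosines sitting at the
#' 3'-terminal position of a 3-4 nt loop closed by a base-paired stem;
#' the rules model searches for exactly that substrate around a
#' candidate cytosine and scores it.
#'
#' @param min_stem_pairs,max_stem_pairs Allowed range of contiguous
#'   stem base pairs (no bulges). Defaults 3 and 10.
#' @param allow_gu_in_stem Accept G:U wobble pairs in the stem. Wobble
#'   pairs extend the stem but contribute 0 to the score, which prices
#'   only GC and AU pairs. Default `FALSE` (strict Watson-Crick).
#' @param search_window Nucleotides searched on each side of the
#'   cytosine; hairpin bases must fall inside this window (truncated at
#'   sequence ends). Default 25.
#' @param call_threshold Minimum total score for an editing call
#'   (score greater than nine, i.e. `>= 10`). Default 10.
#' @param anchor Where the target cytosine sits in the loop:
#'   `"loop3p"` (default; the 3'-terminal loop position, the substrate
#'   geometry seen in structural studies of APOBEC3A/G) or `"loop5p"`
#'   (first loop position), retained as a sensitivity switch.
#' @param bonus_mode `"each"` (default): the +2 bonuses for a uracil in
#'   the loop and for a purine following the cytosine are applied
#'   independently (max +4). `"either"`: a single +2 when at least one
#'   feature is present.
#' @return A list of class `rules_config`.
#' @export
rules_config <- function(min_stem_pairs = 3L, max_stem_pairs = 10L,
                         allow_gu_in_stem = FALSE, search_window = 25L,
                         call_threshold = 10L,
                         anchor = c("loop3p", "loop5p"),
                         bonus_mode = c("each", "either")) {
  anchor <- match.arg(anchor)
  bonus_mode <- match.arg(bonus_mode)
  stopifnot(min_stem_pairs >= 1L, max_stem_pairs >= min_stem_pairs,
            search_window >= 1L)
  structure(list(
    min_stem_pairs = as.integer(min_stem_pairs),
    max_stem_pairs = as.integer(max_stem_pairs),
    allow_gu_in_stem = isTRUE(allow_gu_in_stem),
    search_window = as.integer(search_window),
    call_threshold = as.integer(call_threshold),
    anchor = anchor, bonus_mode = bonus_mode
  ), class = "rules_config")
}

#' @export
print.rules_config <- function(x, ...) {
  cat("Rules-based model configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, x[[nm]]))
  invisible(x)
}

# Is (x, y) an allowed stem pair? T treated as U.
pair_ok <- function(x, y, allow_gu = FALSE) {
  p <- paste0(x, y)
  wc <- p %in% c("GC", "CG", "AU", "UA")
  if (allow_gu) wc | p %in% c("GU", "UG") else wc
}

#' Find candidate hairpins anchored at a cytosine
#'
#' Enumerates every stem-loop in which the target cytosine occupies the
#' configured loop anchor position, the loop is 3 or 4 nt, and the stem
#' is a run of contiguous complementary pairs of length
#' `min_stem_pairs` to `max_stem_pairs`, all bases within
#' `search_window` nt of the cytosine. Nested stems (each qualifying
#' stem length for a given loop) are all reported; scoring picks the
#' best.
#'
#' @param seq Sequence (`nucseq` or character); DNA or RNA.
#' @param c_pos 1-based position of the target cytosine.
#' @param cfg A [rules_config()].
#' @return A list of hairpin records, each a list with `loop_start`,
#'   `loop_end` (1-based inclusive), `loop_len`, `c_pos`, `stem_len`,
#'   and `stem_pairs` (2-column matrix of upstream/downstream bases,
#'   loop-proximal first). Empty list when no hairpin qualifies.
#' @export
find_hairpins <- function(seq, c_pos, cfg = rules_config()) {
  v <- nuc_chars(nucseq(seq), canonical = TRUE)
  n <- length(v)
  stopifnot(c_pos >= 1L, c_pos <= n)
  if (v[c_pos] != "C")
    stop("target position ", c_pos, " is '", v[c_pos], "', not C")
  lo <- max(1L, c_pos - cfg$search_window)
  hi <- min(n, c_pos + cfg$search_window)
  out <- list()
  for (L in c(3L, 4L)) {
    if (cfg$anchor == "loop3p") {
      loop_start <- c_pos - L + 1L
      loop_end <- c_pos
    } else {
      loop_start <- c_pos
      loop_end <- c_pos + L - 1L
    }
    if (loop_start < lo || loop_end > hi) next
    # maximal run of contiguous pairs closing the loop
    maxs <- 0L
    repeat {
      k <- maxs + 1L
      up <- loop_start - k
      dn <- loop_end + k
      if (up < lo || dn > hi || k > cfg$max_stem_pairs) break
      if (!pair_ok(v[up], v[dn], cfg$allow_gu_in_stem)) break
      maxs <- k
    }
    if (maxs < cfg$min_stem_pairs) next
    for (s in cfg$min_stem_pairs:maxs) {
      k <- seq_len(s)
      out[[length(out) + 1L]] <- list(
        loop_start = loop_start, loop_end = loop_end, loop_len = L,
        c_pos = c_pos, stem_len = s,
        stem_pairs = cbind(upstream = v[loop_start - k],
                           downstream = v[loop_end + k])
      )
    }
  }
  out
}

#' Score a hairpin with the rules-based formula
#'
#' Total = 3 x (GC pairs) + (AU pairs) + 2 if the loop contains a
#' uracil + 2 if the base following the cytosine is a purine - 2 if the
#' loop contains a guanine (with `bonus_mode = "either"`, the two +2
#' bonuses collapse to a single +2 when at least one applies). G:U
#' wobble pairs, if allowed in the stem, score 0.
#'
#' @param hairpin One record from [find_hairpins()].
#' @param seq The sequence the hairpin was found in.
#' @param cfg A [rules_config()].
#' @return A list of class `rules_score`: `gc_pairs`, `au_pairs`,
#'   `u_in_loop`, `purine_after_c`, `g_in_loop`, `total`, plus
#'   diagnostics `pyrimidine_before_c` (motif reported but not scored)
#'   and `after_c_oob` (`TRUE` when the cytosine is the last base, so
#'   the purine bonus could not be evaluated).
#' @export
score_hairpin <- function(hairpin, seq, cfg = rules_config()) {
  v <- nuc_chars(nucseq(seq), canonical = TRUE)
  sp <- hairpin$stem_pairs
  p <- paste0(sp[, 1L], sp[, 2L])
  gc <- sum(p %in% c("GC", "CG"))
  au <- sum(p %in% c("AU", "UA"))
  loop <- v[hairpin$loop_start:hairpin$loop_end]
  u_in_loop <- "U" %in% loop
  g_in_loop <- "G" %in% loop
  after_oob <- hairpin$c_pos >= length(v)
  purine_after <- !after_oob && v[hairpin$c_pos + 1L] %in% c("A", "G")
  before <- if (hairpin$c_pos > 1L) v[hairpin$c_pos - 1L] else NA_character_
  bonus <- if (cfg$bonus_mode == "each") {
    2L * u_in_loop + 2L * purine_after
  } else {
    2L * (u_in_loop || purine_after)
  }
  total <- 3L * gc + au + bonus - 2L * g_in_loop
  structure(list(
    gc_pairs = gc, au_pairs = au, u_in_loop = u_in_loop,
    purine_after_c = purine_after, g_in_loop = g_in_loop,
    total = as.integer(total),
    pyrimidine_before_c = !is.na(before) && before %in% c("C", "U"),
    after_c_oob = after_oob,
    loop_len = hairpin$loop_len, stem_len = hairpin$stem_len,
    loop_start = hairpin$loop_start
  ), class = "rules_score")
}

#' Score a candidate cytosine and make the rules-based call
#'
#' Detects all qualifying hairpins at the site, scores each, and
#' returns the best score. Ties on total are broken toward more GC
#' pairs, then the shorter loop, then the smallest loop start, so the
#' reported best hairpin is deterministic.
#'
#' @param seq Sequence (`nucseq` or character).
#' @param c_pos 1-based position of the target cytosine.
#' @param cfg A [rules_config()].
#' @return A list: `best` (a `rules_score`, or `NULL` when no hairpin
#'   was found), `call` (`TRUE` iff a hairpin exists and its total is
#'   at or above `cfg$call_threshold`), and `n_hairpins`.
#' @examples
#' # 3-pair GC stem closing the triloop UUC, purine (G) after the C
#' s <- score_site("AAGGCUUCGCCAA", 8)
#' s$best$total  # 13
#' s$call        # TRUE
#' @export
score_site <- function(seq, c_pos, cfg = rules_config()) {
  hp <- find_hairpins(seq, c_pos, cfg)
  if (length(hp) == 0L)
    return(list(best = NULL, call = FALSE, n_hairpins = 0L))
  scores <- lapply(hp, score_hairpin, seq = seq, cfg = cfg)
  key <- vapply(scores, function(s)
    c(-s$total, -s$gc_pairs, s$loop_len, s$loop_start), numeric(4))
  best <- scores[[order(key[1, ], key[2, ], key[3, ], key[4, ])[1L]]]
  list(best = best, call = best$total >= cfg$call_threshold,
       n_hairpins = length(hp))
}

#' Rules-based score for many cytosines of a sequence
#'
#' Applies [score_site()] to the given positions (default: every
#' cytosine) of one sequence.
#'
#' @param seq Sequence (`nucseq` or character).
#' @param positions 1-based cytosine positions; default all cytosines.
#' @param cfg A [rules_config()].
#' @return data.frame with `position`, `score` (`NA` when no hairpin),
#'   `call`, and the score components.
#' @export
score_all_sites <- function(seq, positions = NULL, cfg = rules_config()) {
  v <- nuc_chars(nucseq(seq), canonical = TRUE)
  if (is.null(positions)) positions <- which(v == "C")
  res <- lapply(positions, function(p) {
    r <- score_site(seq, p, cfg)
    if (is.null(r$best))
      data.frame(position = p, score = NA_integer_, call = FALSE,
                 gc_pairs = NA_integer_, au_pairs = NA_integer_,
                 u_in_loop = NA, purine_after_c = NA, g_in_loop = NA)
    else
      data.frame(position = p, score = r$best$total, call = r$call,
                 gc_pairs = r$best$gc_pairs, au_pairs = r$best$au_pairs,
                 u_in_loop = r$best$u_in_loop,
                 purine_after_c = r$best$purine_after_c,
                 g_in_loop = r$best$g_in_loop)
  })
  do.call(rbind, res)
}
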