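# Transcription-factor motif catalog, REG catalog, octamer classification,
# REG annotation by treatment, co-localization contingency analysis, and
# position-frequency matrices.

#' Transcription-factor recognition motif catalog
#'
#' The built-in catalog of short recognition motifs (ACGT core, DRE,
#' CGCG, Myc E-box, Dof, GCCCA, H box, W box, AACCGG, AuxRE, GCC box).
#' Patterns use a restricted IUPAC-style syntax: literal A/C/G/T, `N`
#' for any base, and `(X/Y)` for alternation.
#'
#' @param path Catalog TSV (columns `name`, `pattern`); defaults to the
#'   copy shipped with the package.
#' @return A `data.frame` with columns `name` and `pattern` (plus any
#'   annotation columns present in the file).
#' @export
motif_catalog <- function(path = system.file("extdata",
                                             "motif_catalog.tsv",
                                             package = "octascan")) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE)
  stopifnot(all(c("name", "pattern") %in% names(cat)))
  cat
}

#' REG (Regulatory Element Group) octamer catalog
#'
#' The shipped catalog maps REG identifiers to their octamers and
#' carries, per treatment, the published direction-insensitive RARf
#' values used for annotation. Lookup is direction-insensitive: a REG is
#' present wherever its octamer or the reverse complement occurs.
#'
#' @param path Catalog TSV; defaults to the shipped 53-REG subset.
#' @return A `data.frame` with columns `reg_id`, `octamer`, one numeric
#'   column per treatment, and `annotation`.
#' @export
reg_catalog <- function(path = system.file("extdata", "reg_rarf.tsv",
                                           package = "octascan")) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  stopifnot(all(c("reg_id", "octamer") %in% names(cat)),
            !anyDuplicated(cat$reg_id),
            all(grepl("^[ACGT]{8}$", cat$octamer)))
  cat
}

#' Expand a catalog pattern to explicit ACGT strings
#'
#' Supports literal bases, `N` (any base) and `(X/Y)` alternation, e.g.
#' `"TTGAC(C/T)"` expands to `TTGACC`, `TTGACT` and `"CANNTG"` to 16
#' hexamers.
#'
#' @param pattern Pattern string.
#' @return Character vector of explicit sequences.
#' @export
expand_motif_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(pattern, "")[[1]]
  choices <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- which(chars == ")" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("unbalanced '(' in pattern: ", pattern)
      alt <- strsplit(paste(chars[(i + 1L):(j - 1L)], collapse = ""),
                      "/", fixed = TRUE)[[1]]
      if (any(!alt %in% c("A", "C", "G", "T")))
        stop("alternation must list single bases: ", pattern)
      choices[[length(choices) + 1L]] <- alt
      i <- j + 1L
    } else if (ch == "N") {
      choices[[length(choices) + 1L]] <- c("A", "C", "G", "T")
      i <- i + 1L
    } else if (ch %in% c("A", "C", "G", "T")) {
      choices[[length(choices) + 1L]] <- ch
      i <- i + 1L
    } else stop("invalid character '", ch, "' in pattern: ", pattern)
  }
  grid <- do.call(expand.grid,
                  c(rev(choices), list(stringsAsFactors = FALSE)))
  sort(apply(grid[, rev(seq_along(choices)), drop = FALSE], 1L, paste,
             collapse = ""))
}

#' Match a motif pattern against a sequence
#'
#' TRUE iff any expansion of the pattern occurs as a substring of the
#' sequence or, with `both_strands` (the default), of its reverse
#' complement. Both strands are the default because several catalog
#' motifs (e.g. DRE in AGTCGGTC) lie on the complementary strand of REG
#' octamers.
#'
#' @param x Sequence (typically an octamer or a predicted element).
#' @param pattern Catalog pattern (see [expand_motif_pattern()]).
#' @param both_strands Also search the reverse complement (default TRUE).
#' @return Logical scalar (vectorized over `x`).
#' @export
match_motif <- function(x, pattern, both_strands = TRUE) {
  pats <- expand_motif_pattern(pattern)
  hit <- vapply(x, function(s) any(vapply(pats, grepl, logical(1),
                                          x = s, fixed = TRUE)),
                logical(1), USE.NAMES = FALSE)
  if (both_strands) {
    rc <- revcomp_octamer(x)
    hit <- hit | vapply(rc, function(s)
      any(vapply(pats, grepl, logical(1), x = s, fixed = TRUE)),
      logical(1), USE.NAMES = FALSE)
  }
  hit
}

#' Classify high-RARf octamers by recognition motif
#'
#' Counts octamers with RARf strictly above `cutoff` that match each
#' catalog motif; an octamer matching several motifs counts toward each
#' of them. The unmatched remainder is returned alongside.
#'
#' @param table An `octamer_stat_table`.
#' @param cutoff RARf cutoff (default 3; 5 gives the stricter
#'   classification).
#' @param motifs A [motif_catalog()].
#' @param both_strands Match on both strands (default TRUE).
#' @return List with `counts` (named integer vector per motif, in
#'   catalog order), `n_high` (octamers above cutoff), and `unmatched`
#'   (character vector of octamers matching no motif).
#' @export
classify_high_rarf <- function(table, cutoff = 3.0,
                               motifs = motif_catalog(),
                               both_strands = TRUE) {
  stopifnot(inherits(table, "octamer_stat_table"), cutoff > 0)
  high <- table$octamer[table$rarf > cutoff]
  if (length(high) == 0L)
    return(list(counts = stats::setNames(integer(nrow(motifs)),
                                         motifs$name),
                n_high = 0L, unmatched = character(0)))
  hits <- vapply(motifs$pattern, function(p)
    match_motif(high, p, both_strands), logical(length(high)))
  hits <- matrix(hits, nrow = length(high))
  counts <- stats::setNames(as.integer(colSums(hits)), motifs$name)
  unmatched <- high[!apply(hits, 1L, any)]
  list(counts = counts, n_high = length(high), unmatched = unmatched)
}

#' Annotate REGs with the treatments that select them
#'
#' A REG is annotated with every treatment whose direction-insensitive
#' RARf for the REG octamer is at or above `cutoff`. Treatments are
#' returned in order of decreasing RARf. An octamer absent from a table
#' is treated as RARf 0.
#'
#' @param regs A [reg_catalog()] (only `reg_id` and `octamer` are used).
#' @param tables Named list mapping treatment label to either an
#'   `octamer_stat_table` (ideally strand-merged) or a named numeric
#'   RARf vector keyed by octamer.
#' @param cutoff Annotation threshold (default 3.0).
#' @return Named list mapping `reg_id` to a character vector of
#'   treatments (possibly empty).
#' @export
annotate_reg <- function(regs, tables, cutoff = 3.0) {
  stopifnot(is.data.frame(regs), length(tables) > 0,
            !is.null(names(tables)), all(nzchar(names(tables))))
  lookup <- function(tab, oct) {
    v <- if (inherits(tab, "octamer_stat_table")) table_values(tab, "rarf")
         else tab
    # direction-insensitive: the merged table stores equal values under
    # both keys; with unmerged input take the larger of the two strands
    val <- suppressWarnings(max(v[oct], v[revcomp_octamer(oct)],
                                na.rm = TRUE))
    if (!is.finite(val)) 0 else val
  }
  out <- lapply(seq_len(nrow(regs)), function(i) {
    vals <- vapply(tables, lookup, numeric(1), oct = regs$octamer[i])
    names(sort(vals[vals >= cutoff], decreasing = TRUE))
  })
  stats::setNames(out, regs$reg_id)
}

#' Co-localization ratios from contingency counts
#'
#' Pure arithmetic on the four promoter counts: marginal percentages of
#' each octamer group and the conditional percentages of one group given
#' the other, all rounded to two decimals.
#'
#' @param n_all Total promoter count.
#' @param n_a,n_b Promoters containing at least one octamer of group A
#'   (resp. B).
#' @param n_both Promoters containing at least one octamer of each group.
#' @return A list of class `colocalization_table` with the four counts
#'   and `ratio_a`, `ratio_b`, `ratio_b_given_a`, `ratio_a_given_b`
#'   (percent).
#' @export
colocalization_ratios <- function(n_all, n_a, n_b, n_both) {
  stopifnot(is_count(n_all), is_count(n_a), is_count(n_b),
            is_count(n_both))
  if (n_both > min(n_a, n_b) || max(n_a, n_b) > n_all)
    stop("counts must satisfy n_both <= min(n_a, n_b) <= n_all")
  pct <- function(num, den) if (den == 0) NA_real_ else
    round(100 * num / den, 2L)
  structure(list(n_all = n_all, n_a = n_a, n_b = n_b, n_both = n_both,
                 ratio_a = pct(n_a, n_all), ratio_b = pct(n_b, n_all),
                 ratio_b_given_a = pct(n_both, n_a),
                 ratio_a_given_b = pct(n_both, n_b)),
            class = "colocalization_table")
}

#' @export
print.colocalization_table <- function(x, ...) {
  cat(sprintf(paste0("colocalization: %d promoters; A %d (%.2f%%), ",
                     "B %d (%.2f%%), both %d (B|A %.2f%%, A|B %.2f%%)\n"),
              x$n_all, x$n_a, x$ratio_a, x$n_b, x$ratio_b, x$n_both,
              x$ratio_b_given_a, x$ratio_a_given_b))
  invisible(x)
}

#' Co-localization of two octamer groups across promoters
#'
#' Counts promoters containing at least one octamer of group A, of group
#' B, and of both, then derives the marginal and conditional percentages
#' via [colocalization_ratios()]. Membership is substring containment on
#' the given strand; include reverse complements in the sets for
#' direction-insensitive analysis.
#'
#' @param pset A [promoter_set()].
#' @param set_a,set_b Non-empty character vectors of octamers.
#' @return A `colocalization_table`.
#' @export
colocalization <- function(pset, set_a, set_b) {
  stopifnot(inherits(pset, "promoter_set"),
            length(set_a) > 0, length(set_b) > 0)
  has_any <- function(octs) {
    pd <- Biostrings::PDict(unique(octs))
    hits <- Biostrings::vcountPDict(pd, pset$seqs)
    colSums(hits) > 0L
  }
  in_a <- has_any(set_a)
  in_b <- has_any(set_b)
  colocalization_ratios(n_promoters(pset), sum(in_a), sum(in_b),
                        sum(in_a & in_b))
}

#' Position-frequency matrix from anchored octamers
#'
#' Aligns octamers on the first occurrence of an anchor pattern and
#' accumulates appearance-count-weighted base frequencies, an internal
#' stand-in for alignment-plus-logo summaries of octamer groups. Columns
#' not covered by a given octamer receive nothing from it; within the
#' anchor span every octamer contributes, so those column sums equal the
#' total weight.
#'
#' @param octamers Character vector of octamers, each containing the
#'   anchor.
#' @param weights Appearance counts (default 1 each).
#' @param anchor_pattern Pattern (see [expand_motif_pattern()]) on which
#'   to register the alignment.
#' @return A 4 x W numeric matrix (rows A, C, G, T) of class `pfm`, with
#'   attributes `anchor_cols` (columns spanned by the anchor) and
#'   `coverage` (total weight covering each column).
#' @export
build_pfm <- function(octamers, weights = rep(1, length(octamers)),
                      anchor_pattern) {
  stopifnot(length(octamers) > 0, length(weights) == length(octamers),
            all(weights >= 0))
  pats <- expand_motif_pattern(anchor_pattern)
  anchor_at <- vapply(octamers, function(o) {
    hits <- vapply(pats, function(p) regexpr(p, o, fixed = TRUE)[[1]],
                   integer(1))
    hits <- hits[hits > 0L]
    if (!length(hits)) stop("octamer lacks anchor '", anchor_pattern,
                            "': ", o)
    min(hits)
  }, integer(1))
  offset <- max(anchor_at) - anchor_at   # left padding per octamer
  W <- max(offset + nchar(octamers))
  pfm <- matrix(0, nrow = 4L, ncol = W,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  coverage <- numeric(W)
  for (i in seq_along(octamers)) {
    cols <- offset[i] + seq_len(nchar(octamers[i]))
    bases <- strsplit(octamers[i], "")[[1]]
    for (j in seq_along(cols))
      pfm[bases[j], cols[j]] <- pfm[bases[j], cols[j]] + weights[i]
    coverage[cols] <- coverage[cols] + weights[i]
  }
  anchor_cols <- max(anchor_at) - 1L + seq_len(min(nchar(pats)))
  structure(pfm, anchor_cols = anchor_cols, coverage = coverage,
            class = c("pfm", class(pfm)))
}

#' Write a position-frequency matrix as 4-row TSV
#' @param pfm A `pfm` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  utils::write.table(cbind(base = rownames(pfm), as.data.frame(pfm)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
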