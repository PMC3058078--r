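# Octamer enumeration, counting, and the RAR / RARf statistic table.
#
# RAR (Relative Appearance Ratio) for an octamer o:
#   RAR(o) = (count_set(o) / n_set) / (count_total(o) / n_total)
# where counts are per-set octamer tallies and n_* are promoter numbers.
# Significance: one-sided Fisher exact test (enrichment tail) on the 2x2
# table of responsive vs non-responsive windows; P is turned into a LOD
# score (-log10 P) and RAR values with LOD < 1.3 (P > 0.05) are masked to
# zero, giving RARf.

OCTAMER_K <- 8L

#' Enumerate the octamer universe
#'
#' All 4^8 = 65,536 DNA 8-mers in lexicographic order (A < C < G < T).
#'
#' @return Character vector of length 65,536 starting at `"AAAAAAAA"`.
#' @export
enumerate_octamers <- function() {
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), OCTAMER_K)
}

#' Reverse complement of octamers
#'
#' @param oct Character vector of strings over A,C,G,T (any length).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp_octamer("AGTCGGTC")  # "GACCGACT"
#' @export
revcomp_octamer <- function(oct) {
  if (length(oct) == 0L) return(character(0))
  if (any(!grepl("^[ACGT]+$", oct)))
    stop("octamers must contain only A,C,G,T")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(oct)))
}

# Cached permutation mapping each octamer index to its reverse complement.
.octascan_cache <- new.env(parent = emptyenv())

revcomp_index <- function() {
  if (is.null(.octascan_cache$rc_idx)) {
    octs <- enumerate_octamers()
    .octascan_cache$rc_idx <- match(revcomp_octamer(octs), octs)
  }
  .octascan_cache$rc_idx
}

#' Count octamers in a promoter set
#'
#' In `occurrence` mode every window position (length - 7 per promoter)
#' whose 8-mer is ACGT-only is tallied; windows containing N are excluded
#' from both the counts and the valid-window total. In `promoter` mode a
#' promoter contributes at most 1 per octamer (presence/absence) and the
#' unit total is the promoter count. With `strand = "merged"`, counts of
#' an octamer and its reverse complement are pooled and reported under
#' both keys; palindromes are left unchanged (not doubled).
#'
#' @param pset A [promoter_set()] of promoters with length >= 8.
#' @param mode `"occurrence"` (default) or `"promoter"`.
#' @param strand `"given"` (default) or `"merged"`.
#' @return List with `counts` (named integer vector over all 65,536
#'   octamers), `n_units` (valid windows, or promoters in promoter mode),
#'   `mode`, and `strand`.
#' @export
count_octamers <- function(pset, mode = c("occurrence", "promoter"),
                           strand = c("given", "merged")) {
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  stopifnot(inherits(pset, "promoter_set"))
  if (n_promoters(pset) > 0L && pset$length < OCTAMER_K)
    stop("promoters shorter than ", OCTAMER_K, " nt cannot be counted")
  if (mode == "occurrence") {
    if (n_promoters(pset) == 0L) {
      counts <- stats::setNames(integer(4^OCTAMER_K), enumerate_octamers())
      n_units <- 0
    } else {
      counts <- Biostrings::oligonucleotideFrequency(
        pset$seqs, width = OCTAMER_K, simplify.as = "collapsed")
      n_units <- sum(counts)
    }
  } else {
    counts <- integer(4^OCTAMER_K)
    # chunked per-sequence presence to bound memory at ~65536 x chunk
    idx <- seq_len(n_promoters(pset))
    for (chunk in split(idx, ceiling(idx / 128))) {
      m <- Biostrings::oligonucleotideFrequency(pset$seqs[chunk],
                                                width = OCTAMER_K)
      counts <- counts + colSums(m > 0L)
    }
    names(counts) <- enumerate_octamers()
    n_units <- n_promoters(pset)
  }
  counts <- as.integer(counts)
  names(counts) <- enumerate_octamers()
  if (strand == "merged") counts <- pool_revcomp(counts)
  list(counts = counts, n_units = n_units, mode = mode, strand = strand)
}

#' Pool counts of complementary octamers
#' @noRd
pool_revcomp <- function(counts) {
  rc <- revcomp_index()
  pooled <- counts + counts[rc]
  pal <- rc == seq_along(counts)
  pooled[pal] <- counts[pal]            # palindromes counted once
  names(pooled) <- names(counts)
  pooled
}

#' Relative Appearance Ratio
#'
#' `RAR = (count_set/n_set) / (count_total/n_total)`. An octamer absent
#' from the total set (`count_total = 0`) has RAR 0 rather than NaN: a
#' sequence that never occurs cannot be an element.
#'
#' @param count_set,count_total Non-negative octamer counts (vectorized).
#' @param n_set,n_total Positive promoter numbers.
#' @return Numeric RAR value(s).
#' @export
compute_rar <- function(count_set, n_set, count_total, n_total) {
  stopifnot(n_set > 0, n_total > 0)
  if (any(count_set < 0) || any(count_total < 0))
    stop("counts must be non-negative")
  rar <- ifelse(count_total > 0,
                (count_set / n_set) / (count_total / n_total), 0)
  as.numeric(rar)
}

#' One-sided Fisher exact enrichment P
#'
#' P for overrepresentation of an octamer in the responsive window class,
#' from the 2x2 table
#' `[[count_set, windows_set - count_set], [count_rest, windows_rest - count_rest]]`
#' with disjoint classes (responsive windows vs all other windows). The
#' one-sided Fisher P is the hypergeometric upper tail
#' `P(X >= count_set)` with `count_set + count_rest` successes among
#' `windows_set + windows_rest` units and `windows_set` draws. Vectorized.
#'
#' @param count_set,count_rest Octamer counts in the responsive and the
#'   complementary window class.
#' @param windows_set,windows_rest Valid-window totals per class.
#' @return P value(s) in \[0, 1\].
#' @export
fisher_enrichment_p <- function(count_set, windows_set, count_rest,
                                windows_rest) {
  if (any(count_set < 0) || any(count_rest < 0) ||
      any(count_set > windows_set) || any(count_rest > windows_rest))
    stop("inconsistent 2x2 margins: need 0 <= count <= windows per class")
  phyper(count_set - 1,
         m = count_set + count_rest,
         n = (windows_set - count_set) + (windows_rest - count_rest),
         k = windows_set,
         lower.tail = FALSE)
}

#' LOD score of a P value
#'
#' `-log10(P)`; the masking boundary LOD 1.3 corresponds to P = 0.05.
#'
#' @param p P value(s) in (0, 1].
#' @return Non-negative LOD score(s).
#' @export
lod_score <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("P values must lie in (0, 1]")
  -log10(p)
}

#' Analysis configuration
#'
#' Bundles the pipeline constants: fold-change selection thresholds for
#' table building (3.0) and for scanned promoters (5.0), the RARf peak
#' cutoff (3.0), the LOD masking threshold (1.3, i.e. P = 0.05), the
#' crosstalk co-localization distance (4 bp), counting and strand modes,
#' and an RNG seed.
#'
#' @param table_fold_threshold,scan_fold_threshold Ratio-scale
#'   fold-change cutoffs (strictly-greater comparisons).
#' @param rarf_peak_cutoff RARf above which scan windows become peaks.
#' @param lod_threshold LOD at or above which an octamer keeps its RAR.
#' @param crosstalk_max_distance Maximum peak distance (bp) counted as
#'   co-localized.
#' @param counting_mode,strand_mode Passed to [count_octamers()].
#' @param bh_correct Apply Benjamini-Hochberg correction to the Fisher P
#'   values before masking (off by default; masking is per-octamer).
#' @param rng_seed Optional integer seed recorded in outputs.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(table_fold_threshold = 3.0,
                            scan_fold_threshold = 5.0,
                            rarf_peak_cutoff = 3.0,
                            lod_threshold = 1.3,
                            crosstalk_max_distance = 4L,
                            counting_mode = c("occurrence", "promoter"),
                            strand_mode = c("given", "merged"),
                            bh_correct = FALSE,
                            rng_seed = NULL) {
  counting_mode <- match.arg(counting_mode)
  strand_mode <- match.arg(strand_mode)
  stopifnot(table_fold_threshold > 0, scan_fold_threshold > 0,
            rarf_peak_cutoff > 0, lod_threshold > 0,
            crosstalk_max_distance >= 0)
  structure(list(table_fold_threshold = table_fold_threshold,
                 scan_fold_threshold = scan_fold_threshold,
                 rarf_peak_cutoff = rarf_peak_cutoff,
                 lod_threshold = lod_threshold,
                 crosstalk_max_distance = as.integer(crosstalk_max_distance),
                 counting_mode = counting_mode,
                 strand_mode = strand_mode,
                 bh_correct = isTRUE(bh_correct),
                 rng_seed = rng_seed),
            class = "analysis_config")
}

#' Build the full octamer RAR/RARf statistic table
#'
#' Counts octamers in the responsive and total sets, computes RAR per
#' octamer, the one-sided Fisher enrichment P on disjoint window classes
#' (responsive windows vs the remaining windows of the total set), the
#' LOD score, and the masked RARf (`rarf = rar` when `lod >=
#' lod_threshold`, else 0).
#'
#' @param responsive A `promoter_set`, a subset by gene ID of `total`.
#' @param total The total promoter set.
#' @param config An [analysis_config()].
#' @param label Treatment label stored with the table (default the
#'   responsive set's label).
#' @return An `octamer_stat_table`: a `data.frame` with one row per
#'   octamer (65,536 rows) and columns `octamer`, `count_set`,
#'   `count_total`, `rar`, `p_value`, `lod`, `rarf`, plus metadata in
#'   `attr(, "meta")` (promoter and window totals, modes, thresholds,
#'   label).
#' @export
build_stat_table <- function(responsive, total, config = analysis_config(),
                             label = responsive$label) {
  stopifnot(inherits(responsive, "promoter_set"),
            inherits(total, "promoter_set"),
            inherits(config, "analysis_config"))
  if (n_promoters(responsive) == 0L || n_promoters(total) == 0L)
    stop("responsive and total promoter sets must be non-empty")
  if (!all(gene_ids(responsive) %in% gene_ids(total)))
    stop("responsive set must be a subset of the total set by gene ID")
  cs <- count_octamers(responsive, mode = config$counting_mode,
                       strand = config$strand_mode)
  ct <- count_octamers(total, mode = config$counting_mode,
                       strand = config$strand_mode)
  make_stat_table(count_set = cs$counts, count_total = ct$counts,
                  n_set = n_promoters(responsive),
                  n_total = n_promoters(total),
                  windows_set = cs$n_units, windows_total = ct$n_units,
                  config = config, label = label)
}

#' Assemble a statistic table from raw counts
#'
#' Lower-level constructor used by [build_stat_table()] and
#' [merge_strands()]; exposed so tables can be rebuilt from stored counts.
#'
#' @param count_set,count_total Named integer vectors over the octamer
#'   universe.
#' @param n_set,n_total Promoter numbers.
#' @param windows_set,windows_total Valid-window (or promoter-unit)
#'   totals per set.
#' @param config An [analysis_config()].
#' @param label Treatment label.
#' @return An `octamer_stat_table`.
#' @export
make_stat_table <- function(count_set, count_total, n_set, n_total,
                            windows_set, windows_total,
                            config = analysis_config(), label = "table") {
  octs <- enumerate_octamers()
  stopifnot(length(count_set) == length(octs),
            length(count_total) == length(octs))
  count_rest <- count_total - count_set
  windows_rest <- windows_total - windows_set
  if (any(count_rest < 0))
    stop("count_set exceeds count_total for some octamer; responsive ",
         "counts must be included in total counts")
  if (windows_rest < 0) stop("windows_set exceeds windows_total")
  rar <- compute_rar(count_set, n_set, count_total, n_total)
  p <- fisher_enrichment_p(count_set, windows_set, count_rest, windows_rest)
  if (config$bh_correct) p <- stats::p.adjust(p, method = "BH")
  lod <- lod_score(p)
  rarf <- ifelse(lod >= config$lod_threshold, rar, 0)
  tab <- data.frame(octamer = octs,
                    count_set = as.integer(count_set),
                    count_total = as.integer(count_total),
                    rar = rar, p_value = p, lod = lod, rarf = rarf,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(tab, "meta") <- list(label = label, n_set = n_set, n_total = n_total,
                            windows_set = windows_set,
                            windows_total = windows_total,
                            counting_mode = config$counting_mode,
                            strand_mode = config$strand_mode,
                            lod_threshold = config$lod_threshold,
                            bh_correct = config$bh_correct)
  class(tab) <- c("octamer_stat_table", "data.frame")
  tab
}

#' @export
print.octamer_stat_table <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf(paste0("octamer_stat_table '%s': %d octamers; %d/%d promoters",
                     " (%s windows set / %s total); %s counting, %s strand\n"),
              m$label, nrow(x), m$n_set, m$n_total,
              format(m$windows_set, big.mark = ","),
              format(m$windows_total, big.mark = ","),
              m$counting_mode, m$strand_mode))
  cat(sprintf("  octamers with RARf > 3: %d (masking at LOD %.2f)\n",
              sum(x$rarf > 3), m$lod_threshold))
  invisible(x)
}

#' Merge complementary-strand information in a statistic table
#'
#' Pools the counts of each octamer with those of its reverse complement
#' (palindromes unchanged) and recomputes RAR, P, LOD and RARf, so that
#' every statistic is identical for an octamer and its complement. This
#' direction-insensitive form is the one used for REG annotation.
#'
#' @param table An `octamer_stat_table` built with `strand_mode "given"`.
#' @param config Optional [analysis_config()]; defaults to the table's
#'   stored thresholds.
#' @return A direction-insensitive `octamer_stat_table`.
#' @export
merge_strands <- function(table, config = NULL) {
  stopifnot(inherits(table, "octamer_stat_table"))
  m <- attr(table, "meta")
  if (identical(m$strand_mode, "merged"))
    return(table)
  if (is.null(config))
    config <- analysis_config(lod_threshold = m$lod_threshold,
                              counting_mode = m$counting_mode,
                              strand_mode = "merged",
                              bh_correct = m$bh_correct)
  cs <- pool_revcomp(stats::setNames(table$count_set, table$octamer))
  ct <- pool_revcomp(stats::setNames(table$count_total, table$octamer))
  config$strand_mode <- "merged"
  make_stat_table(cs, ct, m$n_set, m$n_total, m$windows_set,
                  m$windows_total, config = config, label = m$label)
}

#' Write / read a statistic table as TSV with a YAML metadata sidecar
#'
#' Values are serialized with 17 significant digits so that a reload
#' reproduces the numbers bit-exactly. The sidecar (`<path>.meta.yaml`)
#' stores promoter/window totals, modes and thresholds.
#'
#' @param table An `octamer_stat_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly (for `write_stat_table`); the reloaded
#'   `octamer_stat_table` (for `read_stat_table`).
#' @export
write_stat_table <- function(table, path) {
  stopifnot(inherits(table, "octamer_stat_table"))
  out <- table
  for (col in c("rar", "p_value", "lod", "rarf"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(attr(table, "meta"), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_stat_table
#' @export
read_stat_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(octamer = "character",
                                          count_set = "integer",
                                          count_total = "integer",
                                          rar = "numeric",
                                          p_value = "numeric",
                                          lod = "numeric",
                                          rarf = "numeric"))
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  attr(tab, "meta") <- meta
  class(tab) <- c("octamer_stat_table", "data.frame")
  tab
}

#' Named RARf vector of a statistic table
#' @param table An `octamer_stat_table`.
#' @param channel Column to extract (`"rarf"`, `"rar"`, or `"lod"`).
#' @return Named numeric vector keyed by octamer.
#' @export
table_values <- function(table, channel = c("rarf", "rar", "lod")) {
  channel <- match.arg(channel)
  stats::setNames(table[[channel]], table$octamer)
}
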