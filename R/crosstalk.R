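# Crosstalk: co-localization of predicted elements from two different
# treatment tables within the same promoter.

#' Find cross-treatment co-localized elements
#'
#' Two predicted elements from different treatment tables in the same
#' promoter are counted as co-localized when the distance between their
#' reported positions is at most `max_distance` bp (default 4; the
#' boundary is inclusive, so distance 4 qualifies and 5 does not).
#' Pairs are emitted once, with the treatment pair stored canonically
#' (lexicographic order).
#'
#' @param elements Either a single element `data.frame` (as produced by
#'   [extract_peaks()] / [annotate_elements()], with a `treatment`
#'   column) or a list of such frames, one per treatment; a named list
#'   overrides the `treatment` column with its names.
#' @param max_distance Maximum distance in bp (default 4).
#' @param anchor `"start"` measures between element start positions (the
#'   reported coordinate); `"gap"` measures the gap between the element
#'   intervals (0 when they overlap).
#' @return A `data.frame` with columns `gene_id`, `treatment_a`,
#'   `treatment_b`, `pos_a`, `pos_b`, `distance`, sorted for
#'   determinism.
#' @export
find_crosstalk <- function(elements, max_distance = 4L,
                           anchor = c("start", "gap")) {
  anchor <- match.arg(anchor)
  stopifnot(max_distance >= 0)
  if (is.data.frame(elements)) elements <- list(elements)
  if (!is.null(names(elements)) && all(nzchar(names(elements))))
    elements <- Map(function(df, nm) { df$treatment <- nm; df },
                    elements, names(elements))
  all_el <- do.call(rbind, lapply(elements, function(df)
    df[, c("gene_id", "treatment", "start", "end"), drop = FALSE]))
  empty <- data.frame(gene_id = character(0), treatment_a = character(0),
                      treatment_b = character(0), pos_a = integer(0),
                      pos_b = integer(0), distance = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(all_el) || nrow(all_el) < 2L) return(empty)
  recs <- list()
  for (gid in unique(all_el$gene_id)) {
    g <- all_el[all_el$gene_id == gid, , drop = FALSE]
    if (nrow(g) < 2L) next
    idx <- utils::combn(nrow(g), 2L)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1L, k]; j <- idx[2L, k]
      if (g$treatment[i] == g$treatment[j]) next
      d <- if (anchor == "start") abs(g$start[i] - g$start[j]) else
        max(0L, max(g$start[i], g$start[j]) - min(g$end[i], g$end[j]))
      if (d > max_distance) next
      swap <- g$treatment[i] > g$treatment[j]
      a <- if (swap) j else i
      b <- if (swap) i else j
      recs[[length(recs) + 1L]] <-
        data.frame(gene_id = gid, treatment_a = g$treatment[a],
                   treatment_b = g$treatment[b], pos_a = g$start[a],
                   pos_b = g$start[b], distance = as.integer(d),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  out <- out[order(out$gene_id, out$treatment_a, out$treatment_b,
                   out$pos_a, out$pos_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise crosstalk counts
#'
#' Tallies crosstalk records per canonical (unordered) treatment pair;
#' the counts sum to the number of records.
#'
#' @param records Record `data.frame` from [find_crosstalk()].
#' @return A `data.frame` with columns `treatment_a`, `treatment_b`,
#'   `n`, sorted by pair.
#' @export
crosstalk_matrix <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L)
    return(data.frame(treatment_a = character(0),
                      treatment_b = character(0), n = integer(0),
                      stringsAsFactors = FALSE))
  key <- paste(records$treatment_a, records$treatment_b, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(treatment_a = vapply(parts, `[[`, "", 1L),
                    treatment_b = vapply(parts, `[[`, "", 2L),
                    n = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$treatment_a, out$treatment_b), , drop = FALSE]
}
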