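# 1-bp promoter scanning with a statistic table and peak extraction.
#
# A promoter of length L spans TSS-relative positions -L..-1; the octamer
# window starting at position p covers p..p+7, so valid starts run
# -L..-8. String index i (1..L-7) maps to position i - L - 1.

#' Scan a promoter with an octamer statistic table
#'
#' Looks up the table value of the octamer starting at every window
#' position in 1-bp steps. Windows containing N carry `NA` (missing), not
#' zero: unknown sequence is not evidence of absence.
#'
#' @param pset A [promoter_set()] containing the promoter.
#' @param table An `octamer_stat_table` (or a named numeric vector over
#'   the full octamer universe).
#' @param gene_id Gene to scan; may be omitted when `pset` holds exactly
#'   one promoter.
#' @param channel Table channel to report: `"rarf"` (default), `"rar"`,
#'   or `"lod"`.
#' @return A `scan_profile`: a `data.frame` with columns `position`
#'   (TSS-relative window start, -L..-8), `octamer`, and `value`;
#'   attributes `gene_id`, `table_label`, `channel`, and `sequence`.
#' @export
scan_promoter <- function(pset, table, gene_id = NULL,
                          channel = c("rarf", "rar", "lod")) {
  channel <- match.arg(channel)
  stopifnot(inherits(pset, "promoter_set"))
  if (is.null(gene_id)) {
    if (n_promoters(pset) != 1L)
      stop("gene_id required when the promoter set holds more than one record")
    gene_id <- gene_ids(pset)
  }
  if (!gene_id %in% gene_ids(pset))
    stop("gene '", gene_id, "' not in promoter set '", pset$label, "'")
  L <- pset$length
  if (L < 8L) stop("promoter shorter than 8 nt cannot be scanned")
  if (inherits(table, "octamer_stat_table")) {
    values <- table_values(table, channel)
    label <- attr(table, "meta")$label
  } else {
    stopifnot(is.numeric(table), !is.null(names(table)))
    values <- table
    label <- "table"
  }
  seq <- as.character(pset$seqs[[gene_id]])
  starts <- seq_len(L - 7L)
  wins <- substring(seq, starts, starts + 7L)
  vals <- unname(values[wins])          # N windows miss the lookup -> NA
  prof <- data.frame(position = starts - L - 1L, octamer = wins,
                     value = vals, stringsAsFactors = FALSE)
  structure(prof, gene_id = gene_id, table_label = label,
            channel = channel, sequence = seq,
            class = c("scan_profile", "data.frame"))
}

#' Extract predicted cis-elements from a scan profile
#'
#' Window starts with value strictly greater than `cutoff` are collected;
#' the 8-nt intervals they cover are merged wherever they overlap or abut
#' (separation up to `max_gap` bases, default 0). Missing (N) windows
#' cannot exceed the cutoff and therefore break merges. Each merged
#' region becomes one predicted element whose reported position is its
#' 5'-most base and whose `peak_value` is the maximum over the
#' triggering windows.
#'
#' @param profile A `scan_profile` (conventionally on the `rarf`
#'   channel).
#' @param cutoff Peak threshold (default 3.0, chosen to keep all
#'   potential elements at the cost of later secondary selection).
#' @param max_gap Maximum unsupported separation between covered
#'   intervals that still merges them (default 0 = overlap-or-abut).
#' @return A `data.frame` of predicted elements with columns `gene_id`,
#'   `start`, `end` (TSS-relative, inclusive), `length`, `sequence`,
#'   `peak_value`, `treatment`, and empty annotation columns
#'   `motif_hits`, `reg_ids` (filled by [annotate_elements()]).
#' @export
extract_peaks <- function(profile, cutoff = 3.0, max_gap = 0L) {
  stopifnot(inherits(profile, "scan_profile"), is.numeric(cutoff),
            max_gap >= 0)
  hit <- which(!is.na(profile$value) & profile$value > cutoff)
  empty <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      sequence = character(0), peak_value = numeric(0),
                      treatment = character(0), motif_hits = character(0),
                      reg_ids = character(0), stringsAsFactors = FALSE)
  if (length(hit) == 0L) return(empty)
  pos <- profile$position[hit]          # ascending (5' to 3')
  val <- profile$value[hit]
  iv_start <- pos
  iv_end <- pos + 7L
  # merge sorted intervals that overlap or lie within max_gap of each other
  grp <- cumsum(c(1L, as.integer(iv_start[-1L] >
                                   cummax_int(iv_end)[-length(iv_end)] +
                                   1L + max_gap)))
  seq_chr <- attr(profile, "sequence")
  L <- nchar(seq_chr)
  out <- do.call(rbind, lapply(split(seq_along(hit), grp), function(ii) {
    s <- min(iv_start[ii]); e <- max(iv_end[ii])
    data.frame(gene_id = attr(profile, "gene_id"),
               start = s, end = e, length = e - s + 1L,
               sequence = substr(seq_chr, s + L + 1L, e + L + 1L),
               peak_value = max(val[ii]),
               treatment = attr(profile, "table_label"),
               motif_hits = "", reg_ids = "",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Running maximum of an integer vector
#' @noRd
cummax_int <- function(x) as.integer(cummax(x))

#' Annotate predicted elements with motifs and REG octamers
#'
#' `motif_hits` lists every catalog motif whose expanded pattern occurs
#' in the element sequence on either strand; `reg_ids` lists every REG
#' whose octamer (direction-insensitively, i.e. the octamer or its
#' reverse complement) is contained in the element.
#'
#' @param elements Element `data.frame` from [extract_peaks()].
#' @param motifs A [motif_catalog()] data frame.
#' @param regs A [reg_catalog()] data frame.
#' @return `elements` with `motif_hits` and `reg_ids` filled in as
#'   comma-separated strings.
#' @export
annotate_elements <- function(elements, motifs = motif_catalog(),
                              regs = reg_catalog()) {
  stopifnot(is.data.frame(elements))
  if (nrow(elements) == 0L) return(elements)
  elements$motif_hits <- vapply(elements$sequence, function(s) {
    hits <- motifs$name[vapply(motifs$pattern, function(p)
      match_motif(s, p, both_strands = TRUE), logical(1))]
    paste(hits, collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  elements$reg_ids <- vapply(elements$sequence, function(s) {
    # direction-insensitive containment: octamer on either strand
    hit <- vapply(regs$octamer, function(o)
      grepl(o, s, fixed = TRUE) ||
        grepl(revcomp_octamer(o), s, fixed = TRUE), logical(1))
    paste(regs$reg_id[hit], collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  elements
}

#' Write a scan profile / elements as TSV
#'
#' @param profile A `scan_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "scan_profile"))
  out <- data.frame(gene_id = attr(profile, "gene_id"),
                    position = profile$position,
                    octamer = profile$octamer,
                    value = sprintf("%.17g", profile$value),
                    stringsAsFactors = FALSE)
  out$value[is.na(profile$value)] <- "NA"
  hdr <- sprintf("# table=%s channel=%s", attr(profile, "table_label"),
                 attr(profile, "channel"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param elements Element data frame from [extract_peaks()].
#' @rdname write_profile
#' @export
write_elements <- function(elements, path) {
  utils::write.table(elements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
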