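# Promoter FASTA / expression-table input and responsive-set selection.
#
# Promoters are fixed-length upstream regions in TSS-relative coordinates:
# a promoter of length L covers positions -L..-1, with the TSS at +1.
# Octamer windows are addressed by their 5'-most base, so valid window
# start positions run -L..-8.

#' Construct a promoter set
#'
#' A promoter set holds fixed-length upstream sequences keyed by gene ID.
#' Sequences must share a single length and use the alphabet A, C, G, T, N.
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet]
#'   of promoter sequences; names are gene IDs and must be unique.
#' @param label Free-text label for the set (e.g. `"total"`, `"ABA-up"`).
#' @return An object of class `promoter_set`: a list with elements
#'   `seqs` (a `DNAStringSet`), `label`, and `length` (promoter length).
#' @examples
#' ps <- promoter_set(c(g1 = "ACGTACGTAC", g2 = "TTTTACGTGT"), label = "demo")
#' n_promoters(ps)
#' @export
promoter_set <- function(sequences, label = "unlabelled") {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- tryCatch(Biostrings::DNAStringSet(sequences),
                          error = function(e)
                            stop("promoter sequences restricted to ",
                                 "alphabet A,C,G,T,N", call. = FALSE))
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all promoter sequences must be named by gene ID")
  if (anyDuplicated(ids))
    stop("duplicate gene IDs in promoter set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- unique(Biostrings::width(sequences))
  if (length(lens) > 1L)
    stop("promoter sequences must share one length; found lengths: ",
         paste(lens, collapse = ", "))
  freq <- Biostrings::alphabetFrequency(sequences)
  allowed <- c("A", "C", "G", "T", "N")
  extra <- freq[, setdiff(colnames(freq), allowed), drop = FALSE]
  if (any(rowSums(extra) > 0))
    stop("promoter sequences restricted to alphabet A,C,G,T,N; offending: ",
         paste(ids[rowSums(extra) > 0], collapse = ", "))
  structure(list(seqs = sequences, label = label,
                 length = if (length(lens)) lens else 0L),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set '%s': %d promoters of length %d nt (-%d..-1)\n",
              x$label, n_promoters(x), x$length, x$length))
  invisible(x)
}

#' Number of promoters in a set
#' @param x A `promoter_set`.
#' @return Integer count.
#' @export
n_promoters <- function(x) length(x$seqs)

#' Gene IDs of a promoter set
#' @param x A `promoter_set`.
#' @return Character vector of gene IDs.
#' @export
gene_ids <- function(x) names(x$seqs)

#' Read fixed-length promoter sequences from FASTA
#'
#' One record per gene; the gene ID is the first whitespace-delimited
#' token of the header. Records that do not match `expected_length` are
#' rejected (`strict`), trimmed to their 3' (TSS-proximal) end (`trim`),
#' or dropped with a warning (`drop`).
#'
#' @param path FASTA file path.
#' @param expected_length Required promoter length in nt (default 1000).
#' @param on_length_mismatch One of `"strict"`, `"trim"`, `"drop"`.
#' @param label Label for the returned set.
#' @return A [promoter_set()].
#' @export
read_promoter_fasta <- function(path, expected_length = 1000L,
                                on_length_mismatch = c("strict", "trim",
                                                       "drop"),
                                label = basename(path)) {
  on_length_mismatch <- match.arg(on_length_mismatch)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e)
                     stop("malformed FASTA '", path, "': ",
                          conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L) {
    warning("empty FASTA: ", path)
    return(promoter_set(Biostrings::DNAStringSet(stats::setNames(
      character(0), character(0))), label = label))
  }
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, "", 1L)
  w <- Biostrings::width(seqs)
  off <- which(w != expected_length)
  if (length(off)) {
    if (on_length_mismatch == "strict")
      stop("record(s) not of length ", expected_length, ": ",
           paste(names(seqs)[off], " (", w[off], " nt)",
                 sep = "", collapse = ", "))
    if (on_length_mismatch == "drop") {
      warning(length(off), " record(s) dropped for length mismatch")
      seqs <- seqs[-off]
    } else {
      if (any(w[off] < expected_length))
        stop("cannot trim record(s) shorter than ", expected_length, ": ",
             paste(names(seqs)[off][w[off] < expected_length],
                   collapse = ", "))
      # keep the TSS-proximal (3') end of over-long records
      seqs[off] <- Biostrings::subseq(seqs[off],
                                      start = w[off] - expected_length + 1L)
    }
  }
  promoter_set(seqs, label = label)
}

#' Write a promoter set as FASTA
#'
#' @param pset A `promoter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(pset, path) {
  stopifnot(inherits(pset, "promoter_set"))
  Biostrings::writeXStringSet(pset$seqs, path, width = 80L)
  invisible(path)
}

#' Read an expression fold-change table
#'
#' TSV with at least two columns: gene ID and linear-scale fold change
#' (treatment over control). A header line is detected by a non-numeric
#' second field. Rows with non-numeric fold change are skipped and
#' counted; non-positive fold changes and duplicate gene IDs are errors.
#'
#' @param path TSV file path.
#' @return A `data.frame` with columns `gene_id`, `fold_change`, carrying
#'   an attribute `n_rejected` with the number of skipped rows.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  raw <- read.delim(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE, comment.char = "#",
                    blank.lines.skip = TRUE)
  if (ncol(raw) < 2L)
    stop("expression table needs >= 2 columns (gene_id, fold_change)")
  if (nrow(raw) && suppressWarnings(is.na(as.numeric(raw[1L, 2L]))))
    raw <- raw[-1L, , drop = FALSE]    # header line
  fc <- suppressWarnings(as.numeric(raw[[2L]]))
  bad <- is.na(fc)
  if (any(bad))
    message(sum(bad), " row(s) with non-numeric fold change skipped")
  out <- data.frame(gene_id = raw[[1L]][!bad], fold_change = fc[!bad],
                    stringsAsFactors = FALSE)
  if (any(out$fold_change <= 0))
    stop("fold_change must be strictly positive; offending gene(s): ",
         paste(out$gene_id[out$fold_change <= 0], collapse = ", "))
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id in expression table: ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Select responsive genes by fold-change threshold
#'
#' Returns gene IDs with fold change strictly greater than the threshold
#' ("more than x-fold above the control"), sorted for determinism.
#'
#' @param expr Expression table from [read_expression_table()] (or any
#'   data frame with `gene_id` and `fold_change` columns).
#' @param fold_threshold Positive ratio-scale threshold; 3.0 is the usual
#'   choice for building enrichment tables and 5.0 for promoters that are
#'   individually scanned.
#' @return Sorted character vector of gene IDs.
#' @export
select_responsive <- function(expr, fold_threshold = 3.0) {
  stopifnot(is.data.frame(expr),
            all(c("gene_id", "fold_change") %in% names(expr)),
            is.numeric(fold_threshold), length(fold_threshold) == 1L,
            fold_threshold > 0)
  sort(expr$gene_id[expr$fold_change > fold_threshold])
}

#' Subset a promoter set by gene ID
#'
#' IDs absent from the set are reported with a warning, never silently
#' dropped.
#'
#' @param total A `promoter_set`.
#' @param ids Character vector of gene IDs to keep.
#' @param label Label for the subset (default derived from `total`).
#' @return A `promoter_set` with the matching records.
#' @export
subset_promoters <- function(total, ids,
                             label = paste0(total$label, "-subset")) {
  stopifnot(inherits(total, "promoter_set"), is.character(ids) ||
              length(ids) == 0L)
  ids <- as.character(ids)
  missing <- setdiff(ids, gene_ids(total))
  if (length(missing))
    warning(length(missing), " requested gene ID(s) missing from set '",
            total$label, "': ", paste(utils::head(missing, 5L),
                                      collapse = ", "),
            if (length(missing) > 5L) ", ...")
  keep <- intersect(ids, gene_ids(total))
  promoter_set(total$seqs[keep], label = label)
}
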