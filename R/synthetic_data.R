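# Synthetic promoter sets with planted octamers and fold-change tables.
#
# The generator emulates the study design the statistics expect: a large
# total set of fixed-length upstream regions, a responsive subset defined
# by fold change, and an octamer planted at a higher per-promoter
# probability in the responsive promoters than in the background. The
# default base composition is AT-rich (A = T = 0.335, C = G = 0.165),
# typical of plant promoter regions.

#' Default AT-rich promoter base composition
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
default_composition <- function() c(A = 0.335, C = 0.165, G = 0.165,
                                    T = 0.335)

#' Generate random promoters
#'
#' I.i.d. letters from the given base composition; deterministic for a
#' fixed seed.
#'
#' @param n Number of promoters (>= 1).
#' @param length Promoter length in nt (>= 8; default 1000).
#' @param composition Named probabilities over A, C, G, T summing to 1.
#' @param seed Integer RNG seed (global RNG state is left untouched).
#' @param label Label of the returned set.
#' @param prefix Gene-ID prefix; IDs are `prefix` + zero-padded index.
#' @return A [promoter_set()].
#' @export
generate_promoters <- function(n, length = 1000L,
                               composition = default_composition(),
                               seed = 1L, label = "synthetic",
                               prefix = "g") {
  stopifnot(is_count(n), n >= 1, is_count(length), length >= 8)
  composition <- check_composition(composition)
  seqs <- with_seed(seed, {
    s <- paste(sample(names(composition), n * length, replace = TRUE,
                      prob = composition), collapse = "")
    substring(s, seq(1L, n * length, by = length),
              seq(length, n * length, by = length))
  })
  ids <- sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
  promoter_set(stats::setNames(seqs, ids), label = label)
}

#' @noRd
check_composition <- function(composition) {
  if (is.null(names(composition)))
    names(composition) <- c("A", "C", "G", "T")
  stopifnot(length(composition) == 4L,
            setequal(names(composition), c("A", "C", "G", "T")),
            all(composition >= 0))
  if (abs(sum(composition) - 1) > 1e-9)
    stop("base composition must sum to 1")
  composition[c("A", "C", "G", "T")]
}

#' Plant an octamer into promoters by substitution
#'
#' Each selected promoter receives, with probability `prob`, exactly one
#' copy of the octamer written over the existing sequence (substitution,
#' so promoter length and window arithmetic are preserved) at a window
#' start drawn from `positions`. Ground truth (every planted locus) is
#' recorded for benchmarking.
#'
#' @param pset A [promoter_set()].
#' @param octamer The 8-mer to plant.
#' @param prob Per-promoter planting probability in \[0, 1\].
#' @param positions Candidate TSS-relative window starts (defaults to
#'   all of -L..-8, i.e. a uniform positional distribution); probability
#'   weights via `position_weights`.
#' @param position_weights Optional weights over `positions`.
#' @param gene_ids Subset of promoters eligible for planting (default
#'   all).
#' @param seed Integer RNG seed.
#' @return List with `promoters` (modified `promoter_set`) and `truth`
#'   (class `synthetic_truth`: octamer, probability, seed, and a
#'   `data.frame` of planted `gene_id`/`position`).
#' @export
plant_motif <- function(pset, octamer, prob, positions = NULL,
                        position_weights = NULL, gene_ids = NULL,
                        seed = 1L) {
  stopifnot(inherits(pset, "promoter_set"),
            grepl("^[ACGT]{8}$", octamer),
            prob >= 0, prob <= 1)
  L <- pset$length
  valid <- -L:(-8L)
  if (is.null(positions)) positions <- valid
  if (!all(positions %in% valid))
    stop("positions must be valid window starts in -", L, "..-8")
  if (is.null(gene_ids)) gene_ids <- gene_ids(pset)
  stopifnot(all(gene_ids %in% gene_ids(pset)))
  planted <- with_seed(seed, {
    take <- gene_ids[runif(length(gene_ids)) < prob]
    pos <- if (length(take))
      sample(positions, length(take), replace = TRUE,
             prob = position_weights) else integer(0)
    data.frame(gene_id = take, position = as.integer(pos),
               stringsAsFactors = FALSE)
  })
  seqs <- as.character(pset$seqs)
  names(seqs) <- gene_ids(pset)
  if (nrow(planted)) {
    i <- planted$gene_id
    s <- planted$position + L + 1L       # string index of window start
    seqs[i] <- paste0(substr(seqs[i], 1L, s - 1L), octamer,
                      substr(seqs[i], s + 8L, L))
  }
  truth <- structure(list(octamer = octamer, prob = prob, seed = seed,
                          positions = positions, planted = planted),
                     class = "synthetic_truth")
  list(promoters = promoter_set(seqs, label = pset$label), truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %s planted in %d promoters (prob %.3g, seed %d)\n",
              x$octamer, nrow(x$planted), x$prob, x$seed))
  invisible(x)
}

#' Generate a fold-change table with a known responsive subset
#'
#' Responsive genes draw fold changes uniformly from `fold_high`,
#' all others from `fold_low`. With the default ranges the two groups
#' are separated by the 3.0-fold selection threshold, so
#' [select_responsive()] at 3.0 recovers exactly `responsive_ids`.
#'
#' @param responsive_ids Gene IDs of the responsive group.
#' @param all_ids All gene IDs (superset of `responsive_ids`).
#' @param fold_high,fold_low Ranges `(min, max)` for the two groups
#'   (defaults 5-50 and 0.5-2.5).
#' @param seed Integer RNG seed.
#' @return Expression `data.frame` with `gene_id`, `fold_change`.
#' @export
generate_expression <- function(responsive_ids, all_ids,
                                fold_high = c(5, 50),
                                fold_low = c(0.5, 2.5), seed = 1L) {
  stopifnot(all(responsive_ids %in% all_ids),
            length(fold_high) == 2L, length(fold_low) == 2L,
            all(fold_high > 0), all(fold_low > 0),
            diff(fold_high) >= 0, diff(fold_low) >= 0)
  if (fold_low[2L] >= fold_high[1L])
    warning("fold ranges overlap; a threshold between them cannot ",
            "separate the groups exactly")
  resp <- all_ids %in% responsive_ids
  fc <- with_seed(seed, {
    v <- runif(length(all_ids), fold_low[1L], fold_low[2L])
    v[resp] <- runif(sum(resp), fold_high[1L], fold_high[2L])
    v
  })
  data.frame(gene_id = all_ids, fold_change = fc,
             stringsAsFactors = FALSE)
}

#' Simulate a complete planted-motif study
#'
#' Convenience wrapper: generates `n` promoters, designates the first
#' `n_responsive` as responsive, plants `octamer` at probability
#' `prob_responsive` in the responsive and `prob_background` in the
#' remaining promoters, and draws a matching fold-change table.
#'
#' @param n Total promoter count.
#' @param n_responsive Size of the responsive subset.
#' @param length Promoter length (default 1000).
#' @param octamer Planted 8-mer (default `"ACGTGTCC"`, an ABRE-core REG
#'   octamer).
#' @param prob_responsive,prob_background Planting probabilities
#'   (defaults 0.5 and 0.05).
#' @param composition Base composition (default AT-rich).
#' @param seed Master seed; sub-seeds for each stage are derived from it.
#' @return List with `total` (promoter set), `responsive_ids`,
#'   `expression`, and `truth` (a list of the two planting truths).
#' @export
simulate_study <- function(n = 5000L, n_responsive = 300L,
                           length = 1000L, octamer = "ACGTGTCC",
                           prob_responsive = 0.5, prob_background = 0.05,
                           composition = default_composition(),
                           seed = 1L) {
  stopifnot(n_responsive <= n)
  base <- generate_promoters(n, length, composition, seed = seed,
                             label = "total")
  resp_ids <- gene_ids(base)[seq_len(n_responsive)]
  bg_ids <- setdiff(gene_ids(base), resp_ids)
  p1 <- plant_motif(base, octamer, prob_responsive, gene_ids = resp_ids,
                    seed = seed + 101L)
  p2 <- plant_motif(p1$promoters, octamer, prob_background,
                    gene_ids = bg_ids, seed = seed + 202L)
  expr <- generate_expression(resp_ids, gene_ids(base),
                              seed = seed + 303L)
  list(total = p2$promoters, responsive_ids = resp_ids,
       expression = expr, truth = list(responsive = p1$truth,
                                       background = p2$truth))
}

#' Analytic enrichment ratio of a planted octamer
#'
#' Expected RAR of an octamer planted at per-promoter probability
#' `prob_responsive` in the responsive set and `prob_background`
#' elsewhere, on top of a composition-driven chance occurrence rate of
#' `(L - 7) * P(octamer)` per promoter.
#'
#' @inheritParams simulate_study
#' @return Expected RAR (numeric scalar).
#' @export
expected_planted_rar <- function(n = 5000L, n_responsive = 300L,
                                 length = 1000L, octamer = "ACGTGTCC",
                                 prob_responsive = 0.5,
                                 prob_background = 0.05,
                                 composition = default_composition()) {
  composition <- check_composition(composition)
  q <- prod(composition[strsplit(octamer, "")[[1]]])
  b <- (length - 7) * q
  mu_resp <- prob_responsive + b
  mu_bg <- prob_background + b
  mu_total <- (n_responsive * mu_resp + (n - n_responsive) * mu_bg) / n
  mu_resp / mu_total
}
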