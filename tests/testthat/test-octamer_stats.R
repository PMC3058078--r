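# Octamer enumeration, counting, RAR arithmetic, Fisher/LOD masking.

test_that("octamer universe is the 65,536 8-mers in lexicographic order", {
  octs <- enumerate_octamers()
  expect_length(octs, 65536L)
  expect_identical(octs[1], "AAAAAAAA")
  expect_identical(octs[65536], "TTTTTTTT")
  expect_false(anyDuplicated(octs) > 0)
  expect_identical(octs, sort(octs))
})

test_that("reverse complement is correct, involutive, and strict", {
  expect_identical(revcomp_octamer("AGTCGGTC"), "GACCGACT")
  expect_identical(revcomp_octamer("ACACGTGT"), "ACACGTGT")  # palindrome
  set.seed(3)
  octs <- sample(enumerate_octamers(), 200)
  expect_identical(revcomp_octamer(revcomp_octamer(octs)), octs)
  expect_error(revcomp_octamer("ACGTACGN"), "A,C,G,T")
})

test_that("occurrence counting matches a per-window rescan oracle", {
  # corrected hand-countable fixture: 12-mer has 5 windows and contains
  # ACGTACGT at string starts 1 and 5
  ps <- promoter_set(c(g1 = "ACGTACGTACGT"))
  ct <- count_octamers(ps)
  expect_equal(ct$n_units, 5)
  expect_equal(unname(ct$counts[["ACGTACGT"]]), 2L)

  # promoter of all N contributes no windows
  psN <- promoter_set(c(g1 = strrep("N", 20)))
  ctN <- count_octamers(psN)
  expect_equal(ctN$n_units, 0)
  expect_true(all(ctN$counts == 0L))

  # random sequences (with occasional N) against the naive oracle
  set.seed(42)
  seqs <- setNames(vapply(1:50, function(i)
    oracle_random_seq(60, c("A", "C", "G", "T", "N"),
                      c(.24, .24, .24, .24, .04)), character(1)),
    paste0("g", 1:50))
  ps <- promoter_set(seqs)
  ct <- count_octamers(ps)
  expect_equal(ct$n_units, oracle_valid_windows(seqs))
  probe <- sample(enumerate_octamers(), 100)
  for (o in probe)
    expect_equal(unname(ct$counts[[o]]), oracle_count_occurrences(seqs, o),
                 info = o)
  # all windows accounted for
  expect_error(count_octamers(promoter_set(c(g = "ACGT"))), "shorter")
})

test_that("promoter-mode counting tallies promoters, not occurrences", {
  ps <- promoter_set(c(g1 = "ACGTACGTACGT", g2 = "ACGTACGTTTTT",
                       g3 = "TTTTTTTTTTTT"))
  ct <- count_octamers(ps, mode = "promoter")
  expect_equal(ct$n_units, 3)
  expect_equal(unname(ct$counts[["ACGTACGT"]]), 2L)   # g1 counts once
  expect_equal(unname(ct$counts[["TTTTTTTT"]]), 1L)
})

test_that("strand merging pools complements and spares palindromes", {
  ps <- promoter_set(c(g1 = paste0(strrep("A", 9), "CC", strrep("T", 10))))
  given <- count_octamers(ps)
  merged <- count_octamers(ps, strand = "merged")
  expect_equal(unname(given$counts[["AAAAAAAA"]]), 2L)
  expect_equal(unname(given$counts[["TTTTTTTT"]]), 3L)
  expect_equal(unname(merged$counts[["AAAAAAAA"]]), 5L)
  expect_equal(unname(merged$counts[["TTTTTTTT"]]), 5L)
  # palindromic octamer is not doubled
  ps2 <- promoter_set(c(g1 = "ACACGTGTAA"))
  m2 <- count_octamers(ps2, strand = "merged")
  expect_equal(unname(m2$counts[["ACACGTGT"]]), 1L)
})

test_that("RAR follows the definition and its degenerate conventions", {
  expect_equal(compute_rar(10, 100, 20, 2000), 10)
  expect_equal(compute_rar(0, 10, 5, 100), 0)
  expect_equal(compute_rar(3, 10, 0, 100), 0)   # absent genome-wide
  expect_error(compute_rar(-1, 10, 5, 100), "non-negative")
  # set identical to total: RAR 1 wherever present
  set.seed(8)
  ps <- promoter_set(setNames(replicate(20, oracle_random_seq(50)),
                              paste0("g", 1:20)))
  tab <- build_stat_table(ps, ps)
  present <- tab$count_total > 0
  expect_true(all(tab$rar[present] == 1))
  expect_true(all(tab$rarf <= 1))
})

test_that("one-sided Fisher P matches the hypergeometric oracle", {
  # symmetric table shows no enrichment; zero observed gives P = 1
  expect_gt(fisher_enrichment_p(5, 100, 5, 100), 0.5)
  expect_equal(fisher_enrichment_p(0, 100, 10, 100), 1.0)
  expect_error(fisher_enrichment_p(10, 5, 0, 10), "margins")

  set.seed(99)
  for (rep in 1:30) {
    ws <- sample(1:40, 1); wr <- sample(1:40, 1)
    cs <- sample(0:ws, 1); cr <- sample(0:wr, 1)
    expect_equal(fisher_enrichment_p(cs, ws, cr, wr),
                 oracle_fisher_p(cs, ws, cr, wr), tolerance = 1e-12,
                 info = sprintf("[[%d,%d],[%d,%d]]", cs, ws, cr, wr))
  }
  # and against R's own Fisher test as a second, independent route
  for (rep in 1:20) {
    ws <- sample(5:60, 1); wr <- sample(5:60, 1)
    cs <- sample(0:ws, 1); cr <- sample(0:wr, 1)
    ft <- fisher.test(matrix(c(cs, ws - cs, cr, wr - cr), 2, byrow = TRUE),
                      alternative = "greater")$p.value
    expect_equal(fisher_enrichment_p(cs, ws, cr, wr), ft,
                 tolerance = 1e-9)
  }
})

test_that("LOD transform and its domain", {
  expect_equal(round(lod_score(0.05), 3), 1.301)
  expect_equal(lod_score(1), 0)
  expect_equal(lod_score(0.001), 3)
  expect_error(lod_score(0), "0, 1")
  expect_error(lod_score(1.01), "0, 1")
})

test_that("stat tables mask by LOD and obey structural invariants", {
  set.seed(21)
  sim <- simulate_study(n = 400, n_responsive = 60, length = 300,
                        seed = 21)
  resp <- subset_promoters(sim$total, sim$responsive_ids, label = "resp")
  tab <- build_stat_table(resp, sim$total)
  expect_equal(nrow(tab), 65536L)
  expect_true(all(tab$rarf <= tab$rar + 1e-12))
  m <- attr(tab, "meta")
  masked <- tab$lod < m$lod_threshold
  expect_true(all(tab$rarf[masked] == 0))
  expect_true(all(tab$rarf[!masked] == tab$rar[!masked]))
  expect_true(all(tab$count_set <= tab$count_total))
  # boundary: P = 0.05 exactly (LOD ~ 1.3010) keeps its RAR
  cfg <- analysis_config()
  expect_true(lod_score(0.05) >= cfg$lod_threshold)

  # weighted-mean conservation (fixed lengths, no N)
  lhs <- sum(tab$rar * tab$count_total / m$windows_total)
  rhs <- (m$n_total * m$windows_set) / (m$n_set * m$windows_total)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_equal(rhs, 1, tolerance = 1e-9)  # equal lengths, no N

  # responsive set must be a subset of total
  other <- generate_promoters(5, 300, seed = 77, prefix = "x")
  expect_error(build_stat_table(other, sim$total), "subset")
})

test_that("planted enrichment is recovered and rare flukes are masked", {
  sim <- simulate_study(n = 800, n_responsive = 80, length = 400,
                        octamer = "ACGTGTCC", prob_responsive = 0.6,
                        prob_background = 0.06, seed = 31)
  resp <- subset_promoters(sim$total, sim$responsive_ids, label = "resp")
  tab <- build_stat_table(resp, sim$total)
  row <- tab[tab$octamer == "ACGTGTCC", ]
  exp_rar <- expected_planted_rar(800, 80, 400, "ACGTGTCC", 0.6, 0.06)
  expect_lt(abs(row$rar - exp_rar) / exp_rar, 0.35)
  expect_gt(row$rarf, 3)

  # a rare octamer (1 of 3 occurrences in the set) in a 100-vs-5000
  # design: RAR is high but the Fisher mask zeroes it
  ws <- 100 * 993; wt <- 5000 * 993
  p <- fisher_enrichment_p(1, ws, 2, wt - ws)
  expect_gt(p, 0.05)
  # log-space summation at ~5e6-window margins rounds at ~1e-11 relative
  expect_equal(oracle_fisher_p(1, ws, 2, wt - ws), p, tolerance = 1e-9)
  rar <- compute_rar(1, 100, 3, 5000)
  expect_gt(rar, 3)
  expect_equal(ifelse(lod_score(p) >= 1.3, rar, 0), 0)
})

test_that("strand-merged tables are complement-symmetric", {
  sim <- simulate_study(n = 150, n_responsive = 25, length = 200,
                        seed = 13)
  resp <- subset_promoters(sim$total, sim$responsive_ids, label = "resp")
  tab <- build_stat_table(resp, sim$total)
  merged <- merge_strands(tab)
  rc <- revcomp_octamer(merged$octamer)
  idx <- match(rc, merged$octamer)
  for (col in c("count_set", "count_total", "rar", "p_value", "rarf"))
    expect_equal(merged[[col]], merged[[col]][idx], info = col)
  # counts pooled exactly; palindromes untouched
  pal <- tab$octamer == rc
  expect_equal(merged$count_total[!pal],
               tab$count_total[!pal] + tab$count_total[idx][!pal])
  expect_equal(merged$count_total[pal], tab$count_total[pal])
  expect_identical(merge_strands(merged), merged)
})

test_that("stat tables reload bit-exactly from TSV", {
  sim <- simulate_study(n = 60, n_responsive = 12, length = 120,
                        seed = 17)
  resp <- subset_promoters(sim$total, sim$responsive_ids, label = "resp")
  tab <- build_stat_table(resp, sim$total)
  path <- tempfile(fileext = ".tsv")
  write_stat_table(tab, path)
  back <- read_stat_table(path)
  for (col in c("octamer", "count_set", "count_total"))
    expect_identical(back[[col]], tab[[col]])
  for (col in c("rar", "p_value", "lod", "rarf"))
    expect_identical(back[[col]], tab[[col]], info = col)
  expect_equal(attr(back, "meta")$windows_total,
               attr(tab, "meta")$windows_total)
})
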