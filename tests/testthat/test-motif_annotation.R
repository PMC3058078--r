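# Motif catalog matching, REG annotation, co-localization, PFMs.

test_that("catalog patterns expand to explicit ACGT strings", {
  expect_identical(expand_motif_pattern("ACGT"), "ACGT")
  expect_setequal(expand_motif_pattern("TTGAC(C/T)"),
                  c("TTGACC", "TTGACT"))
  expect_setequal(expand_motif_pattern("AGCC(A/G)CC"),
                  c("AGCCACC", "AGCCGCC"))
  expect_length(expand_motif_pattern("CANNTG"), 16L)
  expect_true(all(grepl("^CA[ACGT][ACGT]TG$",
                        expand_motif_pattern("CANNTG"))))
  expect_error(expand_motif_pattern("ACGT("), "unbalanced")
  expect_error(expand_motif_pattern("ACXT"), "invalid character")
})

test_that("motif matching covers both strands and is strand-symmetric", {
  # DRE (CCGAC) lies on the complement of AGTCGGTC
  expect_true(match_motif("AGTCGGTC", "CCGAC", both_strands = TRUE))
  expect_false(match_motif("AGTCGGTC", "CCGAC", both_strands = FALSE))
  expect_true(match_motif("CACGTGTA", "ACGT", both_strands = FALSE))
  expect_false(match_motif("AAAAAAAA", "CCGAC", both_strands = TRUE))

  cat <- motif_catalog()
  expect_equal(nrow(cat), 11L)
  set.seed(19)
  octs <- sample(enumerate_octamers(), 60)
  for (p in cat$pattern)
    expect_identical(match_motif(octs, p, TRUE),
                     match_motif(revcomp_octamer(octs), p, TRUE),
                     info = p)
})

test_that("high-RARf octamers classify by motif, anti-monotone in cutoff", {
  rarf <- setNames(numeric(65536), enumerate_octamers())
  rarf[c("CACGTGTA", "ACGTGTCC", "AGTCGGTC")] <- c(4.8, 4.6, 9.4)
  tab <- make_stat_table(rep(0L, 65536), rep(0L, 65536), 10, 100,
                         1000, 10000)
  tab$rarf <- unname(rarf)
  cls <- classify_high_rarf(tab, 3)
  expect_equal(unname(cls$counts[["ACGT"]]), 2L)
  expect_equal(unname(cls$counts[["DRE"]]), 1L)
  expect_equal(cls$n_high, 3L)

  # empty table -> all zeros
  tab$rarf <- 0
  cls0 <- classify_high_rarf(tab, 3)
  expect_true(all(cls0$counts == 0L))

  # counts shrink (never grow) as the cutoff rises
  set.seed(23)
  tab$rarf <- rexp(65536, 1 / 1.5)
  c3 <- classify_high_rarf(tab, 3)$counts
  c5 <- classify_high_rarf(tab, 5)$counts
  expect_true(all(c5 <= c3))
})

test_that("REG annotation applies the RARf >= 3 rule per treatment", {
  regs <- reg_catalog()
  expect_equal(nrow(regs), 53L)
  treatments <- c("ABA", "Ethylene", "BL", "CK", "Auxin", "JA", "SA",
                  "H2O2", "Drought", "DREB1Aox")
  tables <- lapply(treatments, function(tr)
    setNames(regs[[tr]], regs$octamer))
  names(tables) <- treatments
  ann <- annotate_reg(regs, tables, cutoff = 3)
  expect_setequal(ann$AtREG638, c("DREB1Aox", "ABA"))
  expect_identical(ann$AtREG638, c("DREB1Aox", "ABA"))  # descending RARf
  expect_setequal(ann$AtREG612, "DREB1Aox")
  expect_setequal(ann$AtREG628, "DREB1Aox")
  expect_setequal(ann$AtREG428,
                  c("ABA", "DREB1Aox", "Ethylene", "Drought"))
  # boundary: RARf exactly 3 annotates (AtREG588, ABA = 3)
  expect_true("ABA" %in% ann$AtREG588)
  # octamer absent from a table counts as 0
  ann0 <- annotate_reg(regs, list(X = setNames(1, "AAAAAAAA")), 3)
  expect_length(ann0$AtREG638, 0L)
})

test_that("annotation reproduces the printed sets across the catalog", {
  regs <- reg_catalog()
  treatments <- c("ABA", "Ethylene", "BL", "CK", "Auxin", "JA", "SA",
                  "H2O2", "Drought", "DREB1Aox")
  tables <- setNames(lapply(treatments, function(tr)
    setNames(regs[[tr]], regs$octamer)), treatments)
  ann <- annotate_reg(regs, tables, cutoff = 3)
  printed <- strsplit(regs$annotation, ",\\s*")
  names(printed) <- regs$reg_id
  # AtREG562 carries a typographic artifact in the printed column
  for (id in setdiff(regs$reg_id, "AtREG562"))
    expect_setequal(ann[[id]], printed[[id]])
  expect_setequal(ann$AtREG562, c("ABA", "Auxin"))
})

test_that("co-localization counts match brute force and recompute", {
  ct <- colocalization_ratios(14960, 2642, 2886, 760)
  expect_identical(c(ct$ratio_a, ct$ratio_b, ct$ratio_b_given_a,
                     ct$ratio_a_given_b),
                   c(17.66, 19.29, 28.77, 26.33))
  # internal consistency: ratios recompute exactly from the counts
  expect_identical(ct$ratio_b_given_a, round(100 * ct$n_both / ct$n_a, 2))
  expect_error(colocalization_ratios(10, 5, 4, 6), "n_both")

  set.seed(29)
  seqs <- setNames(vapply(1:20, function(i) oracle_random_seq(40),
                          character(1)), paste0("g", 1:20))
  ps <- promoter_set(seqs)
  set_a <- sample(enumerate_octamers(), 40)
  set_b <- sample(enumerate_octamers(), 40)
  ct2 <- colocalization(ps, set_a, set_b)
  in_a <- vapply(seqs, function(s)
    any(vapply(set_a, grepl, logical(1), x = s, fixed = TRUE)),
    logical(1))
  in_b <- vapply(seqs, function(s)
    any(vapply(set_b, grepl, logical(1), x = s, fixed = TRUE)),
    logical(1))
  expect_equal(ct2$n_a, sum(in_a))
  expect_equal(ct2$n_b, sum(in_b))
  expect_equal(ct2$n_both, sum(in_a & in_b))

  # disjoint occurrence -> n_both = 0
  ps3 <- promoter_set(c(g1 = "AAAAAAAAAA", g2 = "CCCCCCCCCC"))
  ct3 <- colocalization(ps3, "AAAAAAAA", "CCCCCCCC")
  expect_equal(ct3$n_both, 0L)
})

test_that("position-frequency matrices anchor and conserve weight", {
  # single octamer with weight 2: columns are 2x one-hot
  p1 <- build_pfm("ACGTGTCC", weights = 2, anchor_pattern = "ACGT")
  expect_equal(dim(p1), c(4L, 8L))
  expect_true(all(colSums(p1) == 2))
  expect_equal(unname(p1["A", 1]), 2)
  expect_equal(unname(p1["C", 2]), 2)

  # two octamers anchored on ACGT: anchor columns read A,C,G,T at full
  # weight
  p2 <- build_pfm(c("CACGTGTA", "GACACGTA"), anchor_pattern = "ACGT")
  ac <- attr(p2, "anchor_cols")
  expect_equal(unname(p2["A", ac[1]]), 2)
  expect_equal(unname(p2["C", ac[2]]), 2)
  expect_equal(unname(p2["G", ac[3]]), 2)
  expect_equal(unname(p2["T", ac[4]]), 2)
  # column sums equal coverage everywhere (conservation)
  expect_equal(unname(colSums(p2)), attr(p2, "coverage"))
  expect_true(all(colSums(p2)[ac] == 2))

  expect_error(build_pfm("AAAAAAAA", anchor_pattern = "ACGT"), "anchor")
})
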