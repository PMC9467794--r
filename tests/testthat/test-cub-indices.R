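test_that("RSCU matches hand-derived values and conventions", {
  ct <- count_table_from(c(UUU = 3, UUC = 1, AUG = 7))
  t <- rscu(ct)
  phe <- t[t$amino_acid == "Phe", ]
  expect_equal(phe$rscu, c(1.5, 0.5))       # 2*3/4, 2*1/4
  expect_equal(t$rscu[t$codon == "AUG"], 1) # observed Met is always 1
  expect_true(all(is.na(t$rscu[t$amino_acid == "Leu"])))  # unobserved family

  # equal counts in a sixfold family -> all RSCU 1
  leu <- stats::setNames(rep(4, 6), codon_to_rna(CODE$family_of$Leu))
  t <- rscu(count_table_from(leu))
  expect_equal(t$rscu[t$amino_acid == "Leu"], rep(1, 6))

  # stop family only present when requested, with degeneracy 3
  ct <- count_table_from(c(UAA = 1, UAG = 1, UGA = 2))
  expect_false("TER" %in% rscu(ct)$amino_acid)
  ter <- rscu(ct, include_stops = TRUE)
  ter <- ter[ter$amino_acid == "TER", ]
  expect_equal(ter$rscu, c(0.75, 0.75, 1.5))

  # preference flags and flavour tags
  t <- rscu(count_table_from(c(CUG = 10, CUU = 1, CUC = 1)))
  expect_equal(t$preference[t$codon == "CUG"], "strong")
  expect_equal(t$flavour[t$codon == "CUG"], "SAA,BCAA")
  expect_equal(t$flavour[t$codon == "AUU"], "DAA,SAA,BCAA")  # Ile
})

test_that("RSCU family sums equal degeneracy on random tables", {
  for (seed in 1:50) {
    t <- rscu(random_count_table(seed), include_stops = TRUE)
    for (aa in unique(t$amino_acid)) {
      vals <- t$rscu[t$amino_acid == aa]
      if (all(is.na(vals))) next
      expect_equal(sum(vals), length(vals), tolerance = 1e-9)
    }
  }
})

test_that("mean RSCU is idempotent, averages by hand, and keeps identities", {
  t1 <- rscu(random_count_table(21, gene_id = "s1"))
  expect_equal(mean_rscu(list(t1, t1, t1))$rscu, t1$rscu)

  tabs <- lapply(22:24, function(s) rscu(random_count_table(s)))
  m <- mean_rscu(tabs)
  hand <- rowMeans(cbind(tabs[[1]]$rscu, tabs[[2]]$rscu, tabs[[3]]$rscu))
  expect_equal(m$rscu, hand)
  expect_equal(m$count, tabs[[1]]$count + tabs[[2]]$count + tabs[[3]]$count)
  for (aa in unique(m$amino_acid)) {
    vals <- m$rscu[m$amino_acid == aa]
    expect_equal(sum(vals), length(vals), tolerance = 1e-9)
  }
})

test_that("ENC analytic anchors and monotonicity", {
  expect_equal(enc(single_codon_table()), 20)

  u59 <- count_table_from(stats::setNames(rep(100, 59),
                                          codon_to_rna(CODE$syn_codons)))
  expect_equal(enc(u59), 61)   # raw Wright value exceeds 61 and is capped

  # direct evaluation of Wright's formula for the uniform table
  f2 <- (200 * 0.5 - 1) / 199
  f3 <- (300 * (1 / 3) - 1) / 299
  f4 <- (400 * 0.25 - 1) / 399
  f6 <- (600 * (1 / 6) - 1) / 599
  expect_gt(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)

  # ENC decreases as within-family usage concentrates (family totals fixed)
  uniform <- count_table_from(stats::setNames(rep(60, 59),
                                              codon_to_rna(CODE$syn_codons)))
  conc <- uniform
  conc$counts[] <- 0
  multi <- names(CODE$degeneracy)[CODE$degeneracy >= 2 &
                                    names(CODE$degeneracy) != "TER"]
  for (aa in multi) {
    fam <- CODE$family_of[[aa]]
    conc$counts[fam[1]] <- 60 * length(fam)
  }
  prev <- Inf
  for (t in seq(0, 1, by = 0.1)) {
    mix <- uniform
    mix$counts <- (1 - t) * uniform$counts + t * conc$counts
    val <- enc(mix)
    expect_lte(val, prev + 1e-9)
    prev <- val
  }

  expect_error(enc(count_table_from(c(AUG = 5))), "undefined|empty")
})

test_that("ENC imputes the threefold class and reports NA when undefined", {
  # no Ile observed: threefold average imputed from (F2+F4)/2
  ct <- random_count_table(31)
  ct$counts[CODE$family_of$Ile] <- 0L
  expect_false(is.na(enc(ct)))
  # only a twofold family observed -> undefined
  ct2 <- count_table_from(c(UUU = 5, UUC = 5))
  expect_warning(val <- enc(ct2), "undefined")
  expect_true(is.na(val))
})

test_that("CAI follows the weighted geometric mean", {
  w1 <- stats::setNames(rep(1, 59), CODE$syn_codons)
  ct <- random_count_table(41)
  expect_equal(cai(ct, w1), 1)
  expect_equal(cai(ct, w1 * 0.5), 0.5)

  # two codons used equally with w 1 and 0.25 -> sqrt(0.25)
  ct <- count_table_from(c(UUU = 10, UAU = 10))
  w <- w1; w["TTT"] <- 1; w["TAT"] <- 0.25
  expect_equal(cai(ct, w), 0.5)

  # floor guards zero weights
  w["TTT"] <- 0
  expect_message(val <- cai(ct, w, floor = 0.01), "floor")
  expect_equal(val, sqrt(0.01 * 0.25))
  expect_error(cai(ct, w[-1]), "missing")
})

test_that("FOP and CBI match hand arithmetic", {
  opt <- at_optimal_set()
  only_opt <- count_table_from(stats::setNames(rep(5, length(opt)),
                                               codon_to_rna(opt)))
  expect_equal(fop(only_opt, opt), 1)
  expect_equal(cbi(only_opt, opt), 1)

  no_opt <- count_table_from(c(UUC = 9, GCC = 3))  # UUC/GCC not AT-ending
  expect_equal(fop(no_opt, opt), 0)

  # 30 optimal of 120 synonymous codons
  ct <- count_table_from(c(UUU = 30, UUC = 90))
  expect_equal(fop(ct, "TTT"), 0.25)

  # one twofold family, optimal 1 vs other 3: CBI = (1-2)/(4-2)
  ct <- count_table_from(c(UUU = 1, UUC = 3))
  expect_equal(cbi(ct, "TTT"), -0.5)

  # exactly uniform usage in every family -> CBI 0
  u <- count_table_from(stats::setNames(rep(6, 59),
                                        codon_to_rna(CODE$syn_codons)))
  expect_equal(cbi(u, opt), 0)
  expect_error(fop(count_table_from(c(AUG = 2)), opt), "undefined")
})

test_that("indices are invariant under count scaling", {
  ct <- random_count_table(55)
  ct2 <- ct; ct2$counts <- ct$counts * 7L; ct2$n_codons <- ct$n_codons * 7L
  opt <- at_optimal_set()
  w <- reference_weights(rscu(random_count_table(56)))
  expect_equal(cai(ct2, w), cai(ct, w))
  expect_equal(fop(ct2, opt), fop(ct, opt))
  expect_equal(cbi(ct2, opt), cbi(ct, opt))
  expect_equal(rscu(ct2)$rscu, rscu(ct)$rscu)
})

test_that("optimal codon derivation matches the argmax oracle", {
  t <- rscu(count_table_from(c(UUU = 3, UUC = 1)))
  expect_true("TTT" %in% derive_optimal_codons(list(t)))

  # all-uniform table: first codon of each family in canonical order
  u <- rscu(count_table_from(stats::setNames(rep(2, 59),
                                             codon_to_rna(CODE$syn_codons))))
  opt <- derive_optimal_codons(list(u))
  multi <- names(CODE$degeneracy)[CODE$degeneracy >= 2 &
                                    names(CODE$degeneracy) != "TER"]
  expect_equal(sort(unclass(opt)),
               sort(unname(vapply(CODE$family_of[multi], `[`, "", 1L))))

  # 7 random tables vs brute-force argmax on the pooled means
  tabs <- lapply(61:67, function(s) rscu(random_count_table(s)))
  opt <- derive_optimal_codons(tabs)
  pooled <- mean_rscu(tabs)
  dna <- codon_to_dna(pooled$codon)
  for (aa in multi) {
    cods <- CODE$family_of[[aa]]
    vals <- pooled$rscu[match(cods, dna)]
    expect_equal(opt[match(aa, multi)], cods[which.max(vals)])
  }
})

test_that("reference weights have family maxima of 1", {
  w <- reference_weights(mean_rscu(lapply(71:73, function(s)
    rscu(random_count_table(s)))))
  multi <- names(CODE$degeneracy)[CODE$degeneracy >= 2 &
                                    names(CODE$degeneracy) != "TER"]
  for (aa in multi) {
    expect_equal(max(w[CODE$family_of[[aa]]]), 1)
  }
  # round-trip through the two-column text format
  f <- withr::local_tempfile(fileext = ".tsv")
  write_codon_values(w, f)
  expect_equal(read_codon_values(f)[names(w)], unclass(w),
               ignore_attr = TRUE)
})
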