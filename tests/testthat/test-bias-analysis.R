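test_that("expected ENC curve anchors and symmetry identity", {
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  expect_equal(expected_enc(0.5), 60.5)
  s <- seq(0, 1, by = 0.05)
  expect_equal(expected_enc(s) - s, expected_enc(1 - s) - (1 - s))
  expect_error(expected_enc(1.2), "\\[0, 1\\]")
  expect_error(expected_enc(-0.1), "\\[0, 1\\]")
})

test_that("PR2 coordinates match direct ratios and the enumeration oracle", {
  # equal third-base usage within every fourfold box -> plot centre
  ff <- stats::setNames(rep(5, length(CODE$fourfold_codons)),
                        codon_to_rna(CODE$fourfold_codons))
  p <- pr2_point(count_table_from(ff))
  expect_equal(c(p$x, p$y), c(0.5, 0.5))

  # G3=30, C3=10, A3=T3 within one box
  ct <- count_table_from(c(GCG = 30, GCC = 10, GCA = 7, GCU = 7))
  p <- pr2_point(ct)
  expect_equal(p$x, 0.75)
  expect_equal(p$y, 0.5)

  # random tables: brute-force tally over the enumerated fourfold codon list
  for (seed in 81:90) {
    ct <- random_count_table(seed)
    p <- pr2_point(ct)
    x <- ct$counts[CODE$fourfold_codons]
    third <- substr(CODE$fourfold_codons, 3, 3)
    expect_equal(p$x, sum(x[third == "G"]) / sum(x[third %in% c("G", "C")]))
    expect_equal(p$y, sum(x[third == "A"]) / sum(x[third %in% c("A", "T")]))
    # all3 mode uses the 59-codon universe
    p3 <- pr2_point(ct, mode = "all3")
    x3 <- ct$counts[CODE$syn_codons]
    t3 <- substr(CODE$syn_codons, 3, 3)
    expect_equal(p3$x, sum(x3[t3 == "G"]) / sum(x3[t3 %in% c("G", "C")]))
  }

  # zero denominator -> NA with warning
  ct <- count_table_from(c(GCA = 3, GCU = 3))
  expect_warning(p <- pr2_point(ct), "x-axis")
  expect_true(is.na(p$x))
})

test_that("pearson correlation agrees with the covariance-formula oracle", {
  expect_equal(pearson_cor(0:5, 0:5)$r, 1)
  expect_equal(pearson_cor(0:5, -(0:5))$r, -1)
  pc <- pearson_cor(c(0, 1, 2), c(0, 2, 4))
  expect_equal(pc$r, 1)
  expect_equal(pc$slope, 2)
  expect_equal(pc$intercept, 0)

  for (seed in 91:110) {
    withr::with_seed(seed, {
      n <- sample(5:30, 1)
      x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    })
    pc <- pearson_cor(x, y)
    orc <- oracle_pearson(x, y)
    expect_equal(pc$r, orc$r, tolerance = 1e-12)
    expect_equal(pc$p_two_sided, orc$p, tolerance = 1e-12)
    fit <- unname(coef(lm(y ~ x)))
    expect_equal(c(pc$intercept, pc$slope), fit, tolerance = 1e-9)
  }
  expect_error(pearson_cor(1:2, 2:3), "at least 3")
  expect_error(pearson_cor(c(1, 1, 1), 1:3), "zero variance")
})

test_that("neutrality analysis regresses GC12 on GC3s", {
  gc3s <- c(0.2, 0.4, 0.6, 0.8)
  gc12 <- 0.5 + 0.1 * gc3s
  nr <- neutrality_analysis(gc12, gc3s)
  expect_equal(nr$r, 1)
  expect_equal(nr$slope, 0.1)
  expect_equal(nr$intercept, 0.5)
})

test_that("ENC plot classifies points against the reference curve", {
  prof <- data.frame(gene_id = c("a", "b", "c"),
                     gc3s = c(0.637, 0.5, 0.3),
                     enc = c(48.04, expected_enc(0.5), 61))
  ep <- enc_plot(prof)
  expect_equal(ep$expected[1], 56.58667, tolerance = 1e-6)
  expect_equal(ep$position, c("below", "on", "above"))
  curve <- attr(ep, "curve")
  expect_equal(nrow(curve), 101)
  expect_equal(curve$enc, expected_enc(curve$gc3s))
})

test_that("per-codon RSCU~GC3s correlations match the loop oracle", {
  tabs <- lapply(121:127, function(s) rscu(random_count_table(s)))
  gc3s <- vapply(121:127, function(s)
    composition_profile(random_count_table(s))$gc3s, 0)
  m <- codon_gc3s_correlations(tabs, gc3s)
  expect_equal(nrow(m), 61)
  for (i in sample(nrow(m), 12)) {
    v <- vapply(tabs, function(t) t$rscu[t$codon == m$codon[i]], 0)
    ok <- !is.na(v)
    if (m$reason[i] == "") {
      expect_equal(m$r[i], oracle_pearson(gc3s[ok], v[ok])$r,
                   tolerance = 1e-12)
    }
  }
  # Met/Trp have constant RSCU 1 -> zero variance, missing not error
  expect_equal(m$reason[m$codon == "AUG"], "zero variance")
  expect_true(is.na(m$r[m$codon == "AUG"]))

  # a codon whose RSCU is an exact linear function of gc3s -> r = 1
  lin <- lapply(seq_along(tabs), function(i) {
    t <- tabs[[i]]
    t$rscu[t$codon == "UUU"] <- 0.5 + gc3s[i]
    t
  })
  m2 <- codon_gc3s_correlations(lin, gc3s)
  expect_equal(m2$r[m2$codon == "UUU"], 1)
})

test_that("synthetic no-selection sets straddle the ENC curve; selection sinks below", {
  dists <- vapply(1:20, function(i) {
    ct <- codon_counts(generate_cds(synthetic_spec(
      1, 3000, gc3_pressure = 0.5, seed = 700 + i))[[1]])
    enc(ct) - expected_enc(composition_profile(ct)$gc3s)
  }, 0)
  expect_lt(abs(mean(dists)), 2)

  sel <- vapply(1:10, function(i) {
    ct <- codon_counts(generate_cds(synthetic_spec(
      1, 3000, gc3_pressure = 0.5, selection_strength = 2,
      optimal_set = at_optimal_set(), seed = 800 + i))[[1]])
    enc(ct) - expected_enc(composition_profile(ct)$gc3s)
  }, 0)
  expect_lt(mean(sel), 0)
  expect_gte(sum(sel < 0), 9)
})
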