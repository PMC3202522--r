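test_that("sequences that cannot pair are fully unpaired", {
  p <- pair_partition("AAAAAAA")
  expect_equal(p$p_unpaired, rep(1, 7))
  # disabling every pair type removes all structure
  none <- energy_model(gc = NA, au = NA, gu = NA)
  expect_equal(pair_partition("GGGAAACCC", none)$p_unpaired, rep(1, 9))
  # strong-pairing limit: pairable positions are almost surely paired while
  # partnerless positions stay open
  strong <- energy_model(gc = -30, au = -30, gu = NA)
  p2 <- pair_partition("GGGAAACCC", strong)$p_unpaired
  expect_true(all(p2[c(1:3, 7:9)] < 1e-3))
  expect_equal(p2[4:6], rep(1, 3), tolerance = 1e-6)
})

test_that("partition probabilities equal exhaustive structure enumeration", {
  p <- pair_partition("GGGAAACCC")
  want <- oracle_unpaired_probs("GGGAAACCC")
  expect_equal(p$p_unpaired, want, tolerance = 1e-9)

  set.seed(31)
  for (rep in 1:15) {
    s <- random_rna(sample(5:14, 1))
    expect_equal(pair_partition(s)$p_unpaired, oracle_unpaired_probs(s),
                 tolerance = 1e-9)
  }
})

test_that("N positions are unpairable and get probability 1", {
  p <- pair_partition("GGGNAACCC")
  expect_equal(p$p_unpaired[4], 1)
  # and the rest agree with enumeration where N never pairs
  want <- oracle_unpaired_probs("GGGNAACCC")
  expect_equal(p$p_unpaired, want, tolerance = 1e-9)
})

test_that("probabilities are invariant under reversal plus complementation", {
  # complementation maps G:C to C:G and A:U to U:A but turns G:U wobbles
  # into unpairable A:C, so the symmetry holds for the Watson-Crick-only
  # model (it is checked there exactly) and is broken by wobble pairs
  wc <- energy_model(gu = NA)
  set.seed(32)
  for (rep in 1:10) {
    s <- random_rna(sample(8:16, 1))
    p1 <- pair_partition(s, wc)$p_unpaired
    p2 <- pair_partition(reverse_complement(s), wc)$p_unpaired
    expect_equal(p1, rev(p2), tolerance = 1e-12)
  }
})

test_that("local-window folding equals global folding when the window covers all", {
  set.seed(33)
  s <- random_rna(40)
  glob <- pair_partition(s)$p_unpaired
  loc <- fold_accessibility(s, window = 40)$p_unpaired
  loc2 <- fold_accessibility(s, window = 400)$p_unpaired
  expect_equal(loc, glob, tolerance = 1e-12)
  expect_equal(loc2, glob, tolerance = 1e-12)
})

test_that("site accessibility is a geometric mean of window means", {
  prof <- structure(list(id = "x", p_unpaired = rep(1, 30),
                         window = 30L, step = 30L),
                    class = "accessibility_profile")
  expect_equal(site_accessibility(prof, 0L), 1)

  set.seed(34)
  p <- runif(30)
  prof2 <- structure(list(id = "x", p_unpaired = p, window = 30L, step = 30L),
                     class = "accessibility_profile")
  # single-position window returns that position's probability
  expect_equal(site_accessibility(prof2, 5L, windows = list(c(4L, 4L))),
               p[5 + 4])
  # direct recomputation of the default windows
  want <- sqrt(mean(p[(5 + 12):(5 + 19)]) * mean(p[(5 + 1):(5 + 19)]))
  expect_equal(site_accessibility(prof2, 5L), want, tolerance = 1e-12)

  expect_error(site_accessibility(prof2, 5L, windows = list(c(0L, 4L))),
               "window")
  expect_error(site_accessibility(prof2, 20L), "outside")
})

test_that("interaction energy adds hybridization and opening terms", {
  site <- strrep("A", 19)
  prof <- structure(list(id = "x", p_unpaired = rep(1, 19),
                         window = 19L, step = 19L),
                    class = "accessibility_profile")
  e <- interaction_energy(site, prof, 0L)
  expect_equal(as.numeric(e), 19 * -2.0)           # fully accessible: dG_hyb only
  expect_equal(attr(e, "opening"), 0)

  # guide consistency check
  expect_silent(interaction_energy(site, prof, 0L,
                                   guide = paste0(strrep("U", 19), "UU")))
  expect_error(interaction_energy(site, prof, 0L, guide = strrep("A", 19)),
               "complementary")

  # lowering any unpaired probability strictly increases dG_total
  set.seed(35)
  p <- runif(19, 0.2, 1)
  prof2 <- structure(list(id = "x", p_unpaired = p, window = 19L, step = 19L),
                     class = "accessibility_profile")
  base <- as.numeric(interaction_energy(site, prof2, 0L))
  for (j in c(1, 10, 19)) {
    p3 <- p
    p3[j] <- p3[j] * 0.5
    prof3 <- structure(list(id = "x", p_unpaired = p3, window = 19L,
                            step = 19L), class = "accessibility_profile")
    expect_gt(as.numeric(interaction_energy(site, prof3, 0L)), base)
  }

  # an unopenable site has infinite opening cost
  p0 <- rep(1, 19)
  p0[7] <- 0
  prof0 <- structure(list(id = "x", p_unpaired = p0, window = 19L,
                          step = 19L), class = "accessibility_profile")
  expect_equal(as.numeric(interaction_energy(site, prof0, 0L)), Inf)
})

test_that("the accessibility filter passes open sites and rejects stem-buried ones", {
  # unstructured A/G transcript: everything passes
  open_ref <- paste0(strrep("A", 10), "GGAGGAGGA", strrep("A", 20))
  sp <- sequence_space("ref", 0L, nchar(open_ref), nchar(open_ref))
  cand <- enumerate_candidates(sp, open_ref)
  out <- accessibility_filter(cand, open_ref)
  expect_true(all(out$access_pass))
  expect_true(all(out$accessibility == 1))
  expect_true(all(out$dG_total < 0))

  # a candidate buried in a strong planted hairpin stem is rejected
  stem_ref <- paste0(strrep("G", 22), strrep("A", 4), strrep("C", 22))
  sph <- sequence_space("ref", 0L, nchar(stem_ref), nchar(stem_ref))
  candh <- enumerate_candidates(sph, stem_ref)
  outh <- accessibility_filter(candh, stem_ref)
  buried <- outh[outh$start == 0L, ]   # fully inside the 5' stem arm
  expect_lt(buried$accessibility, 0.1)
  expect_false(buried$access_pass)
  # the exhaustive enumerator confirms stem positions rarely open (shorter
  # stem so the full structure ensemble stays enumerable)
  small_stem <- paste0(strrep("G", 6), strrep("A", 4), strrep("C", 6))
  probs <- oracle_unpaired_probs(small_stem)
  expect_equal(pair_partition(small_stem)$p_unpaired, probs,
               tolerance = 1e-9)
  expect_lt(mean(probs[c(1:6, 11:16)]), 0.25)

  # threshold 0 passes everything with negative total energy
  out0 <- accessibility_filter(candh, stem_ref, min_accessibility = 0)
  expect_equal(out0$access_pass, out0$dG_total < 0)
})
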