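test_that("the shipped additive rule table reproduces hand-derived scores", {
  sc <- default_scorers()
  # poly-A site: +5 (A/U at 15-19), +1 (A at 19), +1 (A at 3),
  # +1 (no self-complementary stretch >= 5) = 8
  expect_equal(rule_score(strrep("A", 19), sc$reynolds_like), 8)
  # same site with U at 10 adds the U10 preference
  site_u10 <- paste0(strrep("A", 9), "U", strrep("A", 9))
  expect_equal(rule_score(site_u10, sc$reynolds_like), 9)
  # G at 19 loses A19 and A/U15-19 credit at that position and is penalized
  site_g19 <- paste0(strrep("A", 18), "G")
  expect_equal(rule_score(site_g19, sc$reynolds_like), 4 + 1 - 1 + 1)
  # an empty rule list scores 0
  empty <- rule_table("none", list(), c(0, 0))
  expect_equal(rule_score(strrep("A", 19), empty), 0)
})

test_that("the shipped ordinal condition set classifies by satisfied conditions", {
  sc <- default_scorers()
  ui <- sc$ui_tei_like
  # all four conditions met -> top class Ia (index 3)
  expect_equal(rule_score(paste0("G", strrep("A", 18)), ui), 3)
  # A at position 1 fails the 5'-sense G/C condition -> Ib
  expect_equal(rule_score(strrep("A", 19), ui), 2)
  # G-rich 3' half additionally fails the A/U-richness and terminal conditions
  expect_equal(rule_score(paste0("G", strrep("A", 9), strrep("G", 9)), ui), 0)
})

test_that("self-complementary stretch detection finds planted hairpins", {
  # GGGGG ... CCCCC can fold back on itself
  site <- paste0("GGGGG", strrep("A", 9), "CCCCC")
  expect_true(sirnadesign:::has_self_complementary_stretch(site, 5L))
  expect_false(sirnadesign:::has_self_complementary_stretch(strrep("A", 19), 5L))
  sc <- default_scorers()
  # the hairpin site loses the no-stretch credit relative to a like-composition site
  expect_lt(rule_score(site, sc$reynolds_like),
            rule_score(paste0("GGGGG", strrep("A", 14)), sc$reynolds_like) + 2)
})

test_that("linear scoring equals the independent per-position summation", {
  zero <- coefficient_table("z", 50, matrix(0, 19, 4,
                                            dimnames = list(NULL, c("A", "C", "G", "U"))))
  expect_equal(linear_score(strrep("A", 19), zero), 50)
  w <- matrix(0, 19, 4, dimnames = list(NULL, c("A", "C", "G", "U")))
  w[1, "A"] <- 1
  one <- coefficient_table("o", 0, w)
  expect_equal(linear_score(paste0("A", strrep("C", 18)), one), 1)

  set.seed(21)
  for (rep in 1:30) {
    tab <- random_coefficient_table()
    site <- random_rna(19)
    expect_equal(linear_score(site, tab), oracle_linear(site, tab),
                 tolerance = 1e-12)
  }
  expect_error(linear_score(strrep("A", 18), zero), "length")
})

test_that("scorer files round-trip through the YAML and TSV readers", {
  sc <- default_scorers()
  expect_s3_class(sc$reynolds_like, "sirna_scorer")
  expect_equal(sc$reynolds_like$type, "rules")
  expect_equal(sc$ui_tei_like$classes, c("III", "II", "Ib", "Ia"))

  demo <- read_scorer(system.file("extdata", "scorers",
                                  "linear_demo_synthetic.tsv",
                                  package = "sirnadesign"))
  expect_equal(demo$generation, 2L)
  expect_equal(demo$length, 19L)
  expect_equal(demo$intercept, 52)
  expect_equal(oracle_linear(strrep("A", 19), demo),
               linear_score(strrep("A", 19), demo))
})

test_that("threshold derivation is mean +/- 2 sample SD", {
  expect_equal(derive_thresholds(c(5, 5, 5)), c(min = 5, max = 5))
  expect_equal(derive_thresholds(c(1, 2, 3)), c(min = 0, max = 4))
  expect_error(derive_thresholds(5), "two")
  expect_error(derive_thresholds(c(1, Inf)), "finite")

  # translation equivariance
  set.seed(22)
  for (rep in 1:10) {
    x <- rnorm(sample(3:30, 1), sd = 5)
    cc <- runif(1, -50, 50)
    expect_equal(derive_thresholds(x + cc), derive_thresholds(x) + cc,
                 tolerance = 1e-12)
  }
})

test_that("the intersection filter is a conjunction over registered scorers", {
  sc <- default_scorers()
  th <- default_thresholds()

  inside <- apply_filter(c(reynolds_like = 5, ui_tei_like = 3), sc, th)
  expect_true(inside$ensemble_accept)
  one_out <- apply_filter(c(reynolds_like = 11, ui_tei_like = 3), sc, th)
  expect_false(one_out$ensemble_accept)
  expect_false(one_out$accept[["reynolds_like"]])
  expect_true(one_out$accept[["ui_tei_like"]])

  expect_error(apply_filter(c(a = 1), list(), th), "no scorers")

  # randomized panels against a brute-force conjunction oracle
  set.seed(23)
  for (rep in 1:25) {
    s_rey <- runif(1, -3, 12)
    s_ui <- sample(0:3, 1)
    got <- apply_filter(c(reynolds_like = s_rey, ui_tei_like = s_ui), sc, th)
    want <- (s_rey >= 1.9 && s_rey <= 9.15) && (s_ui >= 2)
    expect_identical(got$ensemble_accept, want)
  }
})

test_that("second-generation scorers accept at the configured inhibition floor", {
  th <- default_thresholds()
  demo <- read_scorer(system.file("extdata", "scorers",
                                  "linear_demo_synthetic.tsv",
                                  package = "sirnadesign"))
  scorers <- list(demo = demo)
  hi <- apply_filter(c(demo = 70), scorers, th)
  lo <- apply_filter(c(demo = 69.99), scorers, th)
  expect_true(hi$ensemble_accept)
  expect_false(lo$ensemble_accept)
})

test_that("registering an extra scorer never grows the accepted set", {
  sc <- default_scorers()
  th <- default_thresholds()
  set.seed(24)
  sites <- vapply(1:40, function(i) random_rna(19), character(1))
  acc1 <- score_candidates(sites, sc["reynolds_like"], th)$ensemble_accept
  acc2 <- score_candidates(sites, sc, th)$ensemble_accept
  expect_true(all(which(acc2) %in% which(acc1)))
})

test_that("final ranking keeps scores above threshold, ordered and stable", {
  cand <- data.frame(site = vapply(1:6, function(i) strrep("A", 19),
                                   character(1)),
                     start = c(30L, 10L, 50L, 0L, 20L, 40L))
  all_in <- final_rank(cand, function(s) 100, threshold = 93)
  expect_equal(nrow(all_in), 6L)
  expect_equal(all_in$start, sort(cand$start))  # ties broken by start

  none <- final_rank(cand, function(s) 0, threshold = 93)
  expect_equal(nrow(none), 0L)

  expect_error(final_rank(cand, function(s) NaN), "non-finite")

  # pluggable numeric ranker matches a brute-force sort
  set.seed(25)
  cand2 <- data.frame(site = vapply(1:20, function(i) random_rna(19),
                                    character(1)),
                      start = seq(0L, by = 19L, length.out = 20L))
  tab <- random_coefficient_table()
  scores <- vapply(cand2$site, function(s) linear_score(s, tab), numeric(1))
  thr <- stats::median(scores)
  got <- final_rank(cand2, tab, threshold = thr)
  want <- cand2[scores > thr, ]
  want <- want[order(-scores[scores > thr], want$start), ]
  expect_equal(got$site, want$site)
})
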