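test_that("the k-mer index stores every k-mer exactly once per occurrence", {
  idx <- build_kmer_index(c(t1 = "ACGUACGUA"), k = 9)
  h <- sirnadesign:::kmer_lookup(idx, "ACGUACGUA")
  expect_equal(h$offset, 0L)
  expect_equal(h$id, "t1")

  # record of length L holds L - k + 1 positions
  set.seed(41)
  s <- random_rna(60)
  idx2 <- build_kmer_index(c(t1 = s), k = 9)
  total <- sum(vapply(ls(idx2$env), function(km) {
    nrow(sirnadesign:::kmer_lookup(idx2, km))
  }, integer(1)))
  expect_equal(total, 60L - 9L + 1L)

  # every stored offset yields exactly that k-mer
  for (km in sample(ls(idx2$env), 10)) {
    h <- sirnadesign:::kmer_lookup(idx2, km)
    for (r in seq_len(nrow(h))) {
      expect_identical(substr(s, h$offset[r] + 1L, h$offset[r] + 9L), km)
    }
  }

  expect_error(build_kmer_index(c(a = "ACGU", a = "ACGU"), 4), "unique")
  expect_error(build_kmer_index(c(a = "ACGU"), 3), "k must be")
})

test_that("full-homology scanning finds planted copies on either strand", {
  set.seed(42)
  site <- random_rna(19)
  bg1 <- random_rna(120)
  bg2 <- random_rna(120)
  planted <- paste0(substr(bg1, 1, 50), site, substr(bg1, 70, 120))
  tx <- c(gene = paste0(random_rna(30), site, random_rna(30)),
          decoy1 = planted, decoy2 = bg2)
  idx <- build_kmer_index(tx, 9)

  hits <- scan_full_homology(site, idx, max_mismatch = 0,
                             intended_ids = "gene")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$id, "decoy1")
  expect_equal(hits$offset, 50L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$strand, "sense")

  # the same copy planted as reverse complement is found on the other strand
  tx_rc <- c(tx, decoy3 = paste0(random_rna(40), reverse_complement(site),
                                 random_rna(40)))
  idx_rc <- build_kmer_index(tx_rc, 9)
  hits_rc <- scan_full_homology(site, idx_rc, 0, "gene")
  expect_true(any(hits_rc$id == "decoy3" & hits_rc$strand == "antisense"))

  # self-exclusion: intended transcripts never reported
  expect_false(any(hits$id == "gene"))
  only_self <- build_kmer_index(tx["gene"], 9)
  expect_equal(nrow(scan_full_homology(site, only_self, 1, "gene")), 0L)

  expect_error(scan_full_homology(strrep("A", 18), idx), "19")
})

test_that("near-complete matches need the one-mismatch radius", {
  set.seed(43)
  site <- random_rna(19)
  mutated <- site
  substr(mutated, 8, 8) <- setdiff(c("A", "C", "G", "U"),
                                   substr(site, 8, 8))[1]
  tx <- c(decoy = paste0(random_rna(25), mutated, random_rna(25)))
  idx <- build_kmer_index(tx, 9)
  expect_equal(nrow(scan_full_homology(site, idx, max_mismatch = 0)), 0L)
  h1 <- scan_full_homology(site, idx, max_mismatch = 1)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$offset, 25L)
  expect_equal(h1$mismatches, 1L)
})

test_that("pigeonhole scanning equals the naive per-offset scan", {
  set.seed(44)
  for (rep in 1:15) {
    tx <- setNames(vapply(1:3, function(i) random_rna(sample(150:400, 1)),
                          character(1)), paste0("t", 1:3))
    site <- if (rep %% 2 == 0) {
      random_rna(19)
    } else {
      # half the reps look for a site actually present (possibly mutated)
      donor <- sample(names(tx), 1)
      off <- sample(nchar(tx[[donor]]) - 19L, 1)
      s <- substr(tx[[donor]], off, off + 18L)
      if (rep %% 4 == 1) substr(s, sample(19, 1), sample(19, 1)) <- "A"
      s
    }
    idx <- build_kmer_index(tx, 9)
    for (mm in 0:1) {
      got <- scan_full_homology(site, idx, mm)
      want <- oracle_full_scan(site, tx, mm)
      expect_equal(got, want)
    }
  }
})

test_that("seed scanning matches the guide seed complement in UTRs only", {
  guide <- paste0(reverse_complement("GGAGGAGGAAAAAAAAAAA"), "UU")
  seed_pat <- reverse_complement(substr(guide, 2, 7))
  utrs <- c(u1 = paste0(strrep("C", 20), seed_pat, strrep("C", 20)),
            u2 = strrep("C", 46))
  hits <- scan_seed(guide, utrs)
  expect_equal(hits$id, "u1")
  expect_equal(hits$offset, 20L)
  expect_equal(nrow(scan_seed(guide, utrs["u2"])), 0L)
  expect_error(scan_seed(guide, utrs, seed = c(2L, 50L)), "seed window")

  set.seed(45)
  for (rep in 1:15) {
    utrs <- setNames(vapply(1:3, function(i) random_rna(sample(50:200, 1)),
                            character(1)), paste0("u", 1:3))
    g <- random_rna(21)
    expect_equal(scan_seed(g, utrs), oracle_seed_scan(g, utrs))
  }
})

test_that("the off-target verdict follows the decision order", {
  no_hits <- data.frame(id = character(0), offset = integer(0))
  full <- data.frame(id = "d1", offset = 3L, mismatches = 0L,
                     strand = "sense")
  seed <- data.frame(id = "d2", offset = 7L)

  expect_equal(offtarget_filter(no_hits, no_hits)$verdict, "accept")
  expect_equal(offtarget_filter(full, no_hits)$verdict, "reject_full")
  # complete homology dominates even when seed hits exist
  expect_equal(offtarget_filter(full, seed)$verdict, "reject_full")
  expect_equal(offtarget_filter(no_hits, seed)$verdict, "reject_seed")

  # verdict independent of hit-list row order
  full2 <- rbind(full, data.frame(id = "d9", offset = 1L, mismatches = 1L,
                                  strand = "antisense"))
  expect_equal(offtarget_filter(full2, seed)$verdict,
               offtarget_filter(full2[2:1, ], seed)$verdict)
})

test_that("the immunostimulatory motif screen flags known motifs", {
  expect_true(immunostimulatory_motifs(paste0("UGUGU", strrep("A", 16)),
                                       strrep("A", 21)))
  expect_true(immunostimulatory_motifs(strrep("A", 21),
                                       paste0(strrep("A", 10), "GGGG",
                                              strrep("A", 7))))
  expect_false(immunostimulatory_motifs(strrep("A", 21), strrep("C", 21)))
})
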