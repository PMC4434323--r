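test_that("pattern enumeration covers 4 arrangements x 16 spacings", {
  pat <- enumerate_patterns()
  expect_equal(nrow(pat), 64)
  expect_setequal(unique(pat$arrangement), c("1F2F", "1F2R", "2R1F", "2F1F"))
  expect_setequal(unique(pat$spacing), -5:10)
  expect_false(any(duplicated(pat)))
})

test_that("log-likelihood matching recovers a planted site and handles N and palindromes", {
  p <- word_pwm("GATTACAT", name = "p")
  set.seed(3)
  bg <- sample_background(1, 100)
  while (grepl("GATTACAT", bg) || grepl("ATGTAATC", bg)) {
    bg <- sample_background(1, 100)
  }
  seq <- bg
  substr(seq, 41, 48) <- "GATTACAT"
  m <- loglik_match_positions(p, seq)
  # exactly one exact-match hit at the planted position on the plus strand
  exact <- m[m$score > 0.9 * max(m$score), ]
  expect_equal(exact$position, 41)
  expect_equal(exact$strand, "+")
  # all N: no matches
  expect_equal(nrow(loglik_match_positions(p, strrep("N", 50))), 0)
  # palindromic consensus matches both strands at the same position
  pal <- word_pwm("ACGCGCGT", name = "pal")  # rc == itself
  s2 <- paste0(strrep("A", 20), "ACGCGCGT", strrep("A", 20))
  m2 <- loglik_match_positions(pal, s2)
  hit <- m2[m2$position == 21, ]
  expect_setequal(hit$strand, c("+", "-"))
  # uninformative motif errors
  expect_error(loglik_match_positions(pwm(matrix(0.25, 4, 4)), s2),
               "uninformative")
})

test_that("pattern counting recovers the planted configuration at the planted rate", {
  pair <- cm_motif_pair()
  pk <- plant_composite_peaks(pair$m1, pair$m2, "1F2F", spacing = 3,
                              planted_fraction = 0.4, n_peaks = 250,
                              peak_length = 150, seed = 19)
  n <- count_pattern(pk, pair$m1, pair$m2, "1F2F", 3)
  # binomial tolerance: 100 +/- 3 * sd(~7.7)
  expect_gt(n, 100 - 3 * sqrt(250 * 0.4 * 0.6))
  expect_lt(n, 100 + 3 * sqrt(250 * 0.4 * 0.6))
  # the planted configuration maximises the count over all 64
  pat <- enumerate_patterns()
  counts <- vapply(seq_len(64), function(i)
    count_pattern(pk, pair$m1, pair$m2, pat$arrangement[i], pat$spacing[i]),
    integer(1))
  best <- which.max(counts)
  expect_equal(pat$arrangement[best], "1F2F")
  expect_equal(pat$spacing[best], 3)
  # empty peak set and absent partner motif count zero
  expect_equal(count_pattern(pk[0, ], pair$m1, pair$m2, "1F2F", 3), 0)
  far <- word_pwm("TTTTAAAA", name = "far")
  none <- plant_composite_peaks(pair$m1, far, "1F2F", 3, planted_fraction = 0,
                                n_peaks = 30, peak_length = 100, seed = 20)
  none$sequence <- gsub("CCAGTGGA|TCCACTGG", "ACGTACGT", none$sequence)
  counts0 <- vapply(seq_len(64), function(i)
    count_pattern(none, pair$m1, pair$m2, pat$arrangement[i], pat$spacing[i],
                  threshold_frac = 0.99), integer(1))
  expect_true(all(counts0 == 0))
})

test_that("pattern counts are invariant to reverse-complementing every peak", {
  pair <- cm_motif_pair()
  pat <- enumerate_patterns()
  for (arr in c("1F2F", "1F2R", "2R1F", "2F1F")) {
    pk <- plant_composite_peaks(pair$m1, pair$m2, arr, spacing = 1,
                                planted_fraction = 0.5, n_peaks = 60,
                                peak_length = 120, seed = 30 + match(arr,
                                  c("1F2F", "1F2R", "2R1F", "2F1F")))
    pk_rc <- pk
    pk_rc$sequence <- oracle_revcomp(pk$sequence)
    idx <- seq(1, 64, by = 7)  # systematic subsample of configurations
    for (i in idx) {
      expect_equal(
        count_pattern(pk, pair$m1, pair$m2, pat$arrangement[i], pat$spacing[i]),
        count_pattern(pk_rc, pair$m1, pair$m2, pat$arrangement[i],
                      pat$spacing[i]))
    }
  }
})

test_that("dinucleotide shuffle conserves composition exactly and is seeded", {
  expect_equal(dinucleotide_shuffle("AAAA", seed = 1), "AAAA")
  seqs <- sample_background(10, 200, seed = 2)
  for (s in seqs) {
    sh <- dinucleotide_shuffle(s, seed = 5)
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, 200, 200), substr(s, 200, 200))
  }
  # reproducible under fixed seeds, different across seeds
  expect_equal(dinucleotide_shuffle(seqs[1], seed = 7),
               dinucleotide_shuffle(seqs[1], seed = 7))
  expect_false(dinucleotide_shuffle(seqs[1], seed = 7) ==
                 dinucleotide_shuffle(seqs[1], seed = 8))
  expect_error(dinucleotide_shuffle("A"), "length")
})

test_that("the sequence-shuffle null calls the planted configuration and only it", {
  pair <- cm_motif_pair()
  pk <- plant_composite_peaks(pair$m1, pair$m2, "1F2F", spacing = 3,
                              planted_fraction = 0.4, n_peaks = 250,
                              peak_length = 150, seed = 40)
  res <- suppressMessages(cm_scan(pk, pair$m1, pair$m2, seed = 41))
  expect_s3_class(res, "cm_scan")
  expect_equal(nrow(res), 64)
  top <- res[1, ]
  expect_true(top$passes)
  expect_equal(top$arrangement, "1F2F")
  expect_equal(top$spacing, 3)
  expect_true(all(res$p_bonf >= res$p - 1e-12))
  expect_true(all(res$passes == (res$observed >= 25 & res$p_bonf <= 0.05)))
  # unplanted background peaks: no passing pattern
  pk0 <- plant_composite_peaks(pair$m1, pair$m2, "1F2F", 3,
                               planted_fraction = 0, n_peaks = 100,
                               peak_length = 150, seed = 42)
  res0 <- suppressMessages(cm_scan(pk0, pair$m1, pair$m2, seed = 43))
  expect_equal(sum(res0$passes), 0)
})

test_that("degenerate null statistics fall back to z = 0, p = 0.5", {
  # observed equals a constant null exactly: z = (0 - 0) / floor
  pair <- cm_motif_pair()
  pk <- plant_composite_peaks(pair$m1, pair$m2, "1F2F", 3,
                              planted_fraction = 0, n_peaks = 10,
                              peak_length = 60, seed = 50)
  res <- suppressMessages(cm_scan(pk, pair$m1, pair$m2, seed = 51,
                                  threshold_frac = 0.99))
  zero <- res[res$observed == 0 & res$null_mean == 0, ]
  expect_gt(nrow(zero), 0)
  expect_true(all(zero$z == 0))
  expect_true(all(zero$p == 0.5))
  expect_false(any(zero$passes))
})

test_that("the motif-shuffle null agrees on planted signal and preserves columns", {
  pair <- cm_motif_pair()
  pk <- plant_composite_peaks(pair$m1, pair$m2, "1F2F", spacing = 3,
                              planted_fraction = 0.4, n_peaks = 120,
                              peak_length = 150, seed = 60)
  res2 <- suppressMessages(cm_scan(pk, pair$m1, pair$m2,
                                   null = "shuffle-motif", seed = 61))
  top2 <- res2[1, ]
  expect_true(top2$passes)
  expect_equal(top2$arrangement, "1F2F")
  expect_equal(top2$spacing, 3)
  # column-shuffled PWM keeps the column multiset
  m <- random_pwm(8, seed = 62)
  withr::with_seed(63, {
    sh <- pbmotif:::shuffle_pwm_columns(m)
    sorted <- function(x) x[do.call(order, as.data.frame(x)), ]
    expect_equal(sorted(pwm_matrix(sh)), sorted(pwm_matrix(m)))
  })
})

test_that("overlapping motif constructions inflate the motif-shuffle null only", {
  # partner is an offset copy of the ChIPed motif: instances overlap at
  # spacing -5, which the column shuffle null is known to over-call
  m1 <- word_pwm("TGACGTCA", name = "m1")
  m2 <- word_pwm("GTCATGAC", name = "m2")
  pk <- plant_composite_peaks(m1, m2, "1F2F", spacing = -5,
                              planted_fraction = 0.4, n_peaks = 120,
                              peak_length = 120, seed = 70)
  r_seq <- suppressMessages(cm_scan(pk, m1, m2, null = "shuffle-seq",
                                    seed = 71))
  r_mot <- suppressMessages(cm_scan(pk, m1, m2, null = "shuffle-motif",
                                    seed = 71))
  expect_gte(sum(r_mot$passes), sum(r_seq$passes))
})

test_that("family odds ratios follow the quoted formulas", {
  fe <- family_odds_ratio(4, 6, 10, 90, family = "NHR")
  expect_equal(fe$odds_ratio, 6)
  expect_equal(fe$se, sqrt(1 / 4 + 1 / 6 + 1 / 10 + 1 / 90))
  expect_equal(fe$ci_low, exp(log(6) - 1.96 * fe$se))
  expect_equal(fe$ci_high, exp(log(6) + 1.96 * fe$se))
  expect_true(fe$ci_low < 6 && 6 < fe$ci_high)
  # no enrichment
  expect_equal(family_odds_ratio(2, 8, 10, 40)$odds_ratio, 1)
  # zero cell: Haldane correction keeps the estimate finite
  fe0 <- suppressMessages(family_odds_ratio(0, 10, 5, 50))
  expect_true(is.finite(fe0$odds_ratio))
  expect_true(fe0$haldane)
  expect_error(family_odds_ratio(0, 0, 0, 0), "all-zero")
})

test_that("composite-motif logos stack matched cassettes in canonical orientation", {
  pair <- cm_motif_pair()
  pk <- plant_composite_peaks(pair$m1, pair$m2, "1F2F", spacing = 2,
                              planted_fraction = 0.6, n_peaks = 100,
                              peak_length = 120, seed = 80)
  lg <- build_cm_logo(pk, pair$m1, pair$m2, "1F2F", 2)
  expect_equal(ncol(lg), 8 + 8 + 2)
  cons <- paste(rownames(lg)[apply(lg, 2, which.max)], collapse = "")
  expect_equal(substr(cons, 1, 8), "TGATTCAG")
  expect_equal(substr(cons, 11, 18), "CCAGTGGA")
  # single match gives an indicator stack
  one <- tibble::tibble(peak_id = "p1",
                        sequence = paste0(strrep("A", 20), "TGATTCAG", "GG",
                                          "CCAGTGGA", strrep("A", 20)))
  class(one) <- c("peak_set", class(one))
  lg1 <- build_cm_logo(one, pair$m1, pair$m2, "1F2F", 2)
  expect_true(all(colSums(lg1) == colSums(lg1)[1]))
  expect_equal(paste(rownames(lg1)[apply(lg1, 2, which.max)], collapse = ""),
               "TGATTCAGGGCCAGTGGA")
  # zero matches error
  expect_error(build_cm_logo(one, pair$m1, pair$m2, "1F2R", 9), "no observed")
})
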