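make_exp <- function(seqs, intensity, flag = "ok", nrow_grid = NULL) {
  n <- length(seqs)
  nc <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  out <- tibble::tibble(
    probe_id = sprintf("p%03d", seq_len(n)),
    row = idx %/% nc + 1L, col = idx %% nc + 1L,
    sequence = seqs, intensity = intensity,
    flag = rep(flag, length.out = n)
  )
  pbmotif:::new_pbm_experiment(out, design_id = "toy", detrended = TRUE)
}

test_that("flag filtering removes bad and suspect spots", {
  seqs <- sample_background(10, 12, seed = 1)
  e <- make_exp(seqs, 1:10)
  expect_identical(nrow(filter_probes(e)), 10L)
  e$flag[1:3] <- c("bad", "suspect", "bad")
  expect_message(f <- filter_probes(e), "removed 3")
  expect_equal(nrow(f), 7)
  e$flag <- "bad"
  expect_error(filter_probes(e), "no probes remain")
})

test_that("detrending is the identity on spatially uniform intensities", {
  seqs <- sample_background(81, 12, seed = 2)
  e <- make_exp(seqs, rep(500, 81))
  d <- spatial_detrend(e)
  expect_equal(d$intensity, e$intensity)
  expect_true(pbmotif:::is_detrended(d))
  expect_error(spatial_detrend(e, window = 4), "odd")
  expect_error(spatial_detrend(e, window = 1), "odd")
})

test_that("detrending flattens a planted smooth gradient", {
  truth <- random_pwm(6, seed = 3)
  # 64 x 64 grid: fine enough that truncated edge windows stay within 2%
  d <- generate_design(8, 23, n_designs = 1, seed = 4)[[1]]
  e <- simulate_intensities(d, truth, affinity_scale = 0, noise_sd = 0,
                            spatial_amplitude = 1, seed = 5)
  # the raw gradient spans 2x corner to corner
  expect_gt(max(e$intensity) / min(e$intensity), 1.9)
  det <- spatial_detrend(e)
  rm <- tapply(det$intensity, det$row, mean)
  expect_lt(max(rm) / min(rm), 1.02)
})

test_that("a median window retains an isolated spike and leaves neighbours alone", {
  seqs <- sample_background(81, 12, seed = 6)
  x <- rep(100, 81)
  e <- make_exp(seqs, x)   # 9 x 9 grid
  spike <- which(e$row == 5 & e$col == 5)
  e$intensity[spike] <- 1000
  d <- spatial_detrend(e, window = 7)
  expect_gt(d$intensity[spike] / median(d$intensity), 9.9)
  others <- setdiff(seq_len(81), spike)
  expect_true(all(abs(d$intensity[others] - 100) / 100 < 0.01))
})

test_that("E-scores match the exhaustive rank-enumeration oracle on a toy table", {
  # 12 probes, 4 containing the word (some via reverse complement)
  word <- "ACGGTA"
  rc <- oracle_revcomp(word)
  set.seed(9)
  bg <- vapply(1:8, function(i) {
    repeat {
      s <- sample_background(1, 12)
      if (!grepl(word, s) && !grepl(rc, s)) return(s)
    }
  }, character(1))
  fg <- paste0(c("AAA", "CCC", "GGG", "TTT"),
               c(word, word, rc, rc),
               c("TTT", "AAA", "CCC", "GGG"))
  seqs <- c(fg, bg)
  intensity <- c(90, 45, 60, 12, 100, 80, 70, 50, 40, 30, 20, 10)
  e <- make_exp(seqs, intensity)
  tab <- compute_escores(e, k = 6)
  expect_equal(tab$E[tab$kmer == oracle_canonical(word)],
               oracle_escore(seqs, intensity, word))
  # every scored k-mer agrees with the oracle
  for (km in tab$kmer) {
    expect_equal(tab$E[tab$kmer == km], oracle_escore(seqs, intensity, km))
  }
})

test_that("E-scores equal the naive reference on a complete order-5 design", {
  d <- generate_design(5, 12, n_designs = 1, seed = 12)[[1]]
  e <- simulate_intensities(d, random_pwm(6, seed = 1), affinity_scale = 5,
                            noise_sd = 0.3, seed = 13)
  e <- spatial_detrend(e)
  tab <- compute_escores(e, k = 5)
  picked <- tab[seq(1, nrow(tab), by = 17), ]  # systematic subsample
  for (i in seq_len(nrow(picked))) {
    expect_equal(picked$E[i],
                 oracle_escore(e$sequence, e$intensity, picked$kmer[i]))
  }
})

test_that("perfect separation yields E = +0.5 and reversal negates E", {
  word <- "ACGGTA"
  seqs <- c(paste0("AAA", word, "TTT"), paste0("CCC", word, "AAA"),
            sample_background(10, 12, seed = 14))
  # drop accidental containment
  rc <- oracle_revcomp(word)
  stopifnot(!any(grepl(word, seqs[-(1:2)]) | grepl(rc, seqs[-(1:2)])))
  up <- c(100, 99, 50 - seq_len(10))
  e_up <- compute_escores(make_exp(seqs, up), k = 6)
  key <- oracle_canonical(word)
  expect_equal(e_up$E[e_up$kmer == key], 0.5)
  e_dn <- compute_escores(make_exp(seqs, -up), k = 6)
  expect_equal(e_dn$E[e_dn$kmer == key], -0.5)
  expect_true(all(e_up$E >= -0.5 & e_up$E <= 0.5))
})

test_that("no-signal 8-mer E-scores concentrate near zero at full coverage", {
  # order-10 design: 32 probes per canonical 8-mer, the regime in which the
  # E statistic is stable
  d <- generate_design(10, 41, n_designs = 1, seed = 3)[[1]]
  e <- spatial_detrend(simulate_intensities(d, random_pwm(8, seed = 4),
                                            affinity_scale = 0, seed = 9))
  tab <- compute_escores(e, k = 8)
  expect_gt(nrow(tab), 3e4)
  expect_lt(abs(mean(tab$E)), 0.02)
  expect_gt(mean(abs(tab$E) < 0.2), 0.9)
})

test_that("score tables are reverse-complement invariant", {
  seqs <- sample_background(40, 15, seed = 15)
  x <- exp(rnorm(40, 5, 1))
  t1 <- kmer_score_table(make_exp(seqs, x), k = 6)
  t2 <- kmer_score_table(make_exp(oracle_revcomp(seqs), x), k = 6)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("Z-score table has median 0 and sd 1 and matches direct arithmetic", {
  fx <- strong_signal_fixture(seed = 31)
  z <- compute_zscores(fx$exps[[1]], k = 6)
  expect_lt(abs(median(z$Z)), 1e-6)
  expect_lt(abs(sd(z$Z) - 1), 1e-6)
  # 3-value toy: statistics {1, 2, 4} -> Z = (x - 2) / sd({1,2,4})
  # build three disjoint words with controlled mean log intensities
  # three probes whose single 11-mers have distinct canonical keys
  seqs <- c("AAAAACAAAAA", "CCCCCACCCCC", "ACGTACGTACG")
  e <- make_exp(seqs, exp(c(1, 2, 4)))
  z3 <- compute_zscores(e, k = 11)
  expect_equal(sort(z3$Z), sort((c(1, 2, 4) - 2) / sd(c(1, 2, 4))))
  # constant intensities: zero spread is an error
  expect_error(compute_zscores(make_exp(seqs, rep(5, 3)), k = 11),
               "zero spread")
})

test_that("experiment success requires joint E, correlations and PWM similarity", {
  fx <- strong_signal_fixture(seed = 41)
  t1 <- kmer_score_table(fx$exps[[1]], k = 6)
  t2 <- kmer_score_table(fx$exps[[2]], k = 6)
  p1 <- derive_pwm_align(t1, min_overlap = 4, name = "p1")
  p2 <- derive_pwm_align(t2, min_overlap = 4, name = "p2")
  s <- assess_success(t1, t2, p1, p2, tf_id = "truth")
  expect_true(s$pass)
  expect_gt(s$max_joint_E, 0.45)
  # identity: correlations exactly 1
  s_id <- assess_success(t1, t1, p1, p1)
  expect_true(s_id$pass)
  expect_equal(s_id$cross_array_E_correlation, 1)
  expect_equal(s_id$pwm_similarity, 1)
  # two independent no-signal experiments fail
  d <- generate_design(6, 13, n_designs = 2, seed = 42)
  n1 <- kmer_score_table(spatial_detrend(
    simulate_intensities(d[[1]], fx$truth, affinity_scale = 0, seed = 1)), k = 6)
  n2 <- kmer_score_table(spatial_detrend(
    simulate_intensities(d[[2]], fx$truth, affinity_scale = 0, seed = 2)), k = 6)
  s_null <- NULL
  expect_warning(s_null <- assess_success(n1, n2), "PWM")
  expect_false(s_null$pass)
})

test_that("bound k-mer counting applies the average-E, any-TF filter", {
  mk <- function(kmers, e1, e2) {
    list(
      pbmotif:::new_kmer_table(tibble::tibble(kmer = kmers, E = e1,
                                              n_probes = 2L), k = 8),
      pbmotif:::new_kmer_table(tibble::tibble(kmer = kmers, E = e2,
                                              n_probes = 2L), k = 8)
    )
  }
  pairs <- list(
    tf1 = mk(c("AAAAAAAA", "AAAAAAAC", "AAAAAACC"),
             c(0.50, 0.48, 0.10), c(0.46, 0.40, 0.20)),
    tf2 = mk(c("AAAAAAAA", "AAAAAACC", "AAAACCCC"),
             c(0.10, 0.50, 0.44), c(0.20, 0.46, 0.47))
  )
  # tf1: avg E .48, .44, .15 -> words 1; tf2: avg .15, .48, .455 -> words 2
  expect_equal(count_bound_kmers(pairs), 3)
  expect_equal(count_bound_kmers(pairs, cutoff = 0.47), 2)
})
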