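test_that("the exact score distribution equals brute-force enumeration", {
  for (seed in c(2, 3)) {
    for (len in c(2, 4, 5)) {
      pw <- random_pwm(len, seed = seed * 100 + len)
      dist <- pwm_score_distribution(pw)
      # enumerate all 4^len windows on the same grid
      grids <- expand.grid(rep(list(1:4), len))
      tot <- rowSums(vapply(seq_len(len), function(j)
        dist$K[j, grids[[j]]], numeric(nrow(grids))))
      uv <- sort(unique(tot))
      bf <- vapply(uv, function(t) mean(tot >= t), numeric(1))
      expect_equal(as.numeric(pbmotif:::grid_pvalue(dist, uv)), bf)
    }
  }
})

test_that("score p-values are monotone with a positive consensus mass", {
  pw <- random_pwm(8, seed = 11, min_ic = 8)
  dist <- pwm_score_distribution(pw)
  expect_true(all(diff(dist$upper_tail) <= 1e-15))
  # the maximal score retains positive probability
  expect_gt(pbmotif:::grid_pvalue(dist,
                                  round(dist$max_score / dist$delta)), 0)
  # non-uniform backgrounds are honoured; degenerate ones refused
  expect_error(pwm_score_distribution(pw, background = c(0.5, 0.5, 0, 0)),
               "positive")
})

test_that("promoter scanning includes planted genes and matches its own null rate", {
  p <- random_pwm(8, seed = 21, min_ic = 10, name = "p")
  cons <- consensus(p)
  promoters <- tibble::tibble(
    gene = sprintf("g%03d", 1:60),
    sequence = sample_background(60, 601, seed = 22))
  substr(promoters$sequence[5], 100, 107) <- cons
  hits <- scan_promoters(p, promoters)
  expect_true("g005" %in% hits)
  # empty promoter set
  expect_equal(scan_promoters(p, promoters[0, ]), character())
  # background-only hit rate matches the closed-form expectation from the
  # exact null: per-window pass probability p* over 2 x 594 windows
  dist <- pwm_score_distribution(p)
  thr <- score_threshold(dist, 1e-4)
  pstar <- pbmotif:::grid_pvalue(dist, thr)
  n <- 400
  bg <- tibble::tibble(gene = sprintf("b%04d", seq_len(n)),
                       sequence = sample_background(n, 601, seed = 23))
  rate <- length(scan_promoters(p, bg)) / n
  expected <- 1 - (1 - pstar)^(2 * 594)
  expect_lt(abs(rate - expected), 3 * sqrt(expected * (1 - expected) / n) + 0.01)
})

test_that("one-sided Fisher enrichment matches hypergeometric enumeration", {
  universe <- letters[1:6]
  r <- geneset_fisher(letters[1:3], letters[1:3], universe)
  expect_equal(r$p, 1 / choose(6, 3))  # 0.05
  expect_equal(r$p, fisher.test(matrix(c(3, 0, 0, 3), 2),
                                alternative = "greater")$p.value)
  # target = universe is degenerate: p = 1
  expect_equal(geneset_fisher(letters[1:3], universe, universe)$p, 1)
  expect_error(geneset_fisher("a", "a", character()), "empty universe")
  # independent hits give a roughly uniform p distribution
  ps <- vapply(1:100, function(i) {
    set.seed(i)
    u <- sprintf("g%02d", 1:40)
    geneset_fisher(sample(u, 15), sample(u, 10), u)$p
  }, numeric(1))
  expect_gt(median(ps), 0.25)
})

test_that("gene-set enrichment flags only the planted set", {
  p <- word_pwm("GATTACAT", name = "p")
  g <- generate_promoter_genesets(p, n_genes = 150, set_fraction = 0.2,
                                  planted_fraction_in_set = 0.8, seed = 31)
  res <- enrich_genesets(list(p = p), g$promoters, g$genesets)
  expect_true(all(res$q >= res$p - 1e-12))
  sig <- res$set_id[res$q < 0.05]
  expect_equal(sig, "focal")
  # BH monotonicity within the run
  ord <- order(res$p)
  expect_true(all(diff(cummin(rev(res$q[ord]))) <= 1e-12) ||
                all(diff(res$p[ord]) >= 0))
})

test_that("bait affinity scores are monotone in site count and match brute force", {
  p <- word_pwm("GATTACA", name = "p")
  base <- strrep("C", 520)
  plant <- function(s, at) { substr(s, at, at + 6) <- "GATTACA"; s }
  b0 <- base
  b1 <- plant(base, 10)
  b3 <- plant(plant(plant(base, 10), 100), 200)
  sc <- y1h_affinity_score(p, c(b0, b1, b3))
  expect_true(sc[1] < sc[2] && sc[2] < sc[3])
  # only the proximal 500 bases count
  distal <- plant(base, 510)
  expect_equal(y1h_affinity_score(p, distal), y1h_affinity_score(p, base))
  # uniform motif scores equal-length baits identically
  u <- pwm(matrix(0.25, 4, 4))
  su <- y1h_affinity_score(u, c(b0, b1))
  expect_equal(su[1], su[2])
  # 20-base bait: occupancy equals exhaustive placement enumeration
  expect_warning(
    s20 <- y1h_affinity_score(p, "ACGATTACAGGGATTACATG"),
    "shorter")
  expect_equal(s20, oracle_occupancy(p, "ACGATTACAGGGATTACATG"))
})

test_that("Y1H Mann-Whitney matches the exact permutation oracle and inclusion rule", {
  # scores {3,4,5} vs {0,1,2}: U = 9; exact two-tailed p by enumeration of
  # all C(6,3) labelings = 0.1
  labelings <- combn(6, 3)
  vals <- c(3, 4, 5, 0, 1, 2)
  u_of <- function(pos) {
    x <- vals[pos]; y <- vals[-pos]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(1:3)
  us <- apply(labelings, 2, u_of)
  p_exact <- mean(abs(us - 4.5) >= abs(u_obs - 4.5))
  wt <- suppressWarnings(wilcox.test(c(3, 4, 5), c(0, 1, 2)))
  expect_equal(unname(wt$statistic), u_obs)
  expect_equal(wt$p.value, p_exact)
  expect_equal(p_exact, 0.1)
  # end-to-end: planted positives enrich, small positive sets are refused
  p <- word_pwm("GATTACAT", name = "p")
  y <- generate_y1h_dataset(p, n_pos = 10, n_neg = 30, seed = 41)
  r <- y1h_mann_whitney(p, y$positives, y$negatives)
  expect_equal(r$status, "tested")
  expect_equal(r$direction, "enriched")
  expect_lt(r$p, 0.01)
  r4 <- y1h_mann_whitney(p, y$positives[1:4, ], y$negatives)
  expect_equal(r4$status, "not_tested")
  expect_true(is.na(r4$p))
  # panel wrapper applies BH over tested TFs only
  panel <- enrich_y1h(list(p = p, q = p),
                      list(p = y, q = list(positives = y$positives[1:3, ],
                                           negatives = y$negatives)))
  expect_equal(panel$status, c("tested", "not_tested"))
  expect_false(is.na(panel$q[1]))
  expect_true(is.na(panel$q[2]))
})

test_that("null Y1H datasets give well-calibrated Mann-Whitney p-values", {
  p <- word_pwm("GATTACAT", name = "p")
  ps <- vapply(1:30, function(i) {
    pos <- tibble::tibble(sequence = sample_background(6, 80, seed = 1000 + i))
    neg <- tibble::tibble(sequence = sample_background(12, 80, seed = 2000 + i))
    suppressWarnings(y1h_mann_whitney(p, pos, neg, scan_length = 80)$p)
  }, numeric(1))
  expect_gt(median(ps), 0.2)
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("central enrichment detects centred motifs and stays null otherwise", {
  p <- word_pwm("GATTACAT", name = "p")
  mk_peaks <- function(centered, seed) {
    seqs <- sample_background(80, 200, seed = seed)
    withr::with_seed(seed + 1, {
      for (i in seq_along(seqs)) {
        at <- if (centered) sample(93:101, 1) else sample(1:193, 1)
        substr(seqs[i], at, at + 7) <- "GATTACAT"
      }
    })
    out <- tibble::tibble(peak_id = sprintf("pk%02d", seq_along(seqs)),
                          sequence = seqs)
    class(out) <- c("peak_set", class(out))
    out
  }
  ctr <- central_enrichment(p, mk_peaks(TRUE, 51))
  expect_lt(ctr$p, 1e-4)
  expect_equal(ctr$method, "simplified-centrimo")
  unif <- central_enrichment(p, mk_peaks(FALSE, 53))
  expect_gt(unif$p, 0.05)
  # window covering the whole peak is degenerate: p = 1 by construction
  expect_equal(central_enrichment(p, mk_peaks(FALSE, 55),
                                  center_window = 400)$p, 1)
  # wrapper applies BH across motifs
  res <- enrich_central(list(a = p, b = p), mk_peaks(TRUE, 57))
  expect_true(all(res$q >= res$p - 1e-12))
})
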