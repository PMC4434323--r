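#' Log-likelihood motif match positions in a sequence
#'
#' Windows are scored as `sum_i log2((p(i, b) + pc) / 0.25)` and reported as
#' matches when the score reaches `threshold_frac * max_score`, where
#' `max_score` is the best attainable score (with the same pseudocount).
#' Both strands are scanned; minus-strand matches are reported at the
#' plus-strand coordinate of their leftmost base. Windows containing `N`
#' never match. Positions are 1-based.
#'
#' @param pwm A [pwm()].
#' @param seq Sequence (uppercase ACGTN) at least as long as the motif.
#' @param threshold_frac Fraction of `max_score` required (default 0.5).
#' @param pseudocount Probability pseudocount (default 0.01).
#' @return Tibble: position, strand (`"+"`/`"-"`), score.
#' @export
loglik_match_positions <- function(pwm, seq, threshold_frac = 0.5,
                                   pseudocount = 0.01) {
  sm <- loglik_score_matrix(pwm, pseudocount)
  sc <- window_scores(sm, seq)
  min_score <- threshold_frac * sm$max_score
  hits_f <- which(sc$fwd >= min_score)
  hits_r <- which(sc$rev >= min_score)
  tibble(
    position = c(hits_f, hits_r),
    strand = c(rep("+", length(hits_f)), rep("-", length(hits_r))),
    score = c(sc$fwd[hits_f], sc$rev[hits_r])
  ) |> arrange(.data$position, .data$strand)
}

# precompute the scoring tables for a motif (both strands); a motif whose
# best unpseudocounted score is <= 0 (e.g. uniform) cannot support a
# max-score-relative threshold
loglik_score_matrix <- function(pwm, pseudocount = 0.01) {
  if (sum(log2(matrixStats_rowMax(pwm$matrix) / 0.25)) <= 0) {
    abort(sprintf("motif '%s' is uninformative (max score <= 0)", pwm$name))
  }
  s_of <- function(m) {
    s <- cbind(log2((m + pseudocount) / 0.25), -Inf)
    dimnames(s) <- NULL
    s
  }
  list(
    w = pwm_length(pwm),
    fwd = s_of(pwm$matrix),
    rev = s_of(pwm_revcomp(pwm)$matrix),
    max_score = sum(log2((matrixStats_rowMax(pwm$matrix) + pseudocount) / 0.25))
  )
}

# raw window scores on both strands (minus strand indexed by leftmost plus
# coordinate)
window_scores <- function(sm, seq) {
  L <- nchar(seq)
  w <- sm$w
  if (L < w) abort("sequence shorter than the motif")
  idx <- .base_lookup[utf8ToInt(seq)]
  n_off <- L - w + 1L
  sf <- numeric(n_off); sr <- numeric(n_off)
  for (j in seq_len(w)) {
    b <- idx[j:(j + n_off - 1L)]
    sf <- sf + sm$fwd[j, ][b]
    sr <- sr + sm$rev[j, ][b]
  }
  list(fwd = sf, rev = sr)
}

# fast internal representation: plus-strand/minus-strand starts plus the
# same matches in the reverse-complemented sequence's frame, as bare vectors
scan_positions <- function(sm, seq, min_score) {
  sc <- window_scores(sm, seq)
  p <- which(sc$fwd >= min_score)
  m <- which(sc$rev >= min_score)
  L <- nchar(seq); w <- sm$w
  list(p = p, m = m, n = length(p) + length(m),
       f = list(p = L - m - w + 2L, m = L - p - w + 2L))
}

# matches of a motif set over all peaks, as a list of scan_positions results
scan_peakset <- function(sm, seqs, threshold_frac) {
  min_score <- threshold_frac * sm$max_score
  lapply(seqs, function(s) scan_positions(sm, s, min_score))
}

# coordinate frame of the reverse-complemented sequence
flip_positions <- function(m, seq_len, w) {
  list(p = seq_len - m$m - w + 2L, m = seq_len - m$p - w + 2L)
}

# upstream starts of configuration instances within one frame
frame_pair_starts <- function(m1, m2, arrangement, spacing, l1, l2) {
  pair <- function(up, lup, down) up[(up + lup + spacing) %in% down]
  switch(arrangement,
    "1F2F" = pair(m1$p, l1, m2$p),
    "1F2R" = pair(m1$p, l1, m2$m),
    "2R1F" = pair(m2$m, l2, m1$p),
    "2F1F" = pair(m2$p, l2, m1$p),
    abort(sprintf("unknown arrangement '%s'", arrangement))
  )
}

# count co-occurrences of the configuration in one peak (0/1 when
# unit = "peaks")
peak_config_count <- function(m1, m2, arrangement, spacing, l1, l2, seq_len,
                              unit = "peaks") {
  if (m1$n == 0L || m2$n == 0L) return(0L)
  n_plus <- length(frame_pair_starts(m1, m2, arrangement, spacing, l1, l2))
  if (unit == "peaks" && n_plus > 0) return(1L)
  n_minus <- length(frame_pair_starts(m1$f, m2$f, arrangement, spacing,
                                      l1, l2))
  if (unit == "peaks") as.integer(n_minus > 0) else n_plus + n_minus
}

count_config <- function(matches1, matches2, seq_lens, l1, l2,
                         arrangement, spacing, unit = "peaks") {
  total <- 0L
  for (i in seq_along(matches1)) {
    total <- total + peak_config_count(matches1[[i]], matches2[[i]],
                                       arrangement, spacing, l1, l2,
                                       seq_lens[i], unit)
  }
  total
}

#' Enumerate stereospecific pattern configurations for a motif pair
#'
#' The cross product of the four orientation arrangements (1F2F, 1F2R, 2R1F,
#' 2F1F) and the sixteen spacings -5..+10 inclusive: 64 configurations per
#' motif pair. Spacing is `start(downstream) - end(upstream) - 1`, so 0 means
#' abutting and negative values mean overlapping instances.
#'
#' @param spacing_min,spacing_max Spacing bounds (defaults -5 and +10).
#' @return Tibble with columns arrangement and spacing (64 rows at defaults).
#' @export
enumerate_patterns <- function(spacing_min = -5, spacing_max = 10) {
  crossing(
    arrangement = c("1F2F", "1F2R", "2R1F", "2F1F"),
    spacing = seq(spacing_min, spacing_max)
  )
}

#' Count peaks matching a composite-motif configuration
#'
#' A peak counts if it contains at least one co-occurrence of a motif-1 and a
#' motif-2 match in the requested arrangement at the exact spacing, on either
#' strand of the peak (the reverse complement of the whole cassette also
#' counts, mapped back to its canonical arrangement). Counting is
#' presence/absence per peak, so the >= 10% count filter reads directly
#' against the number of input peaks; set `unit = "occurrences"` to count
#' every co-occurrence instead.
#'
#' @param peaks A `peak_set` tibble (peak_id, sequence).
#' @param m1,m2 The ChIPed and partner [pwm()]s.
#' @param arrangement,spacing Configuration (see [enumerate_patterns()]).
#' @param threshold_frac,pseudocount Match-call parameters
#'   (see [loglik_match_positions()]).
#' @param unit `"peaks"` (default) or `"occurrences"`.
#' @return Integer count.
#' @export
count_pattern <- function(peaks, m1, m2, arrangement, spacing,
                          threshold_frac = 0.5, pseudocount = 0.01,
                          unit = c("peaks", "occurrences")) {
  unit <- match.arg(unit)
  sm1 <- loglik_score_matrix(m1, pseudocount)
  sm2 <- loglik_score_matrix(m2, pseudocount)
  matches1 <- scan_peakset(sm1, peaks$sequence, threshold_frac)
  matches2 <- scan_peakset(sm2, peaks$sequence, threshold_frac)
  count_config(matches1, matches2, nchar(peaks$sequence),
               pwm_length(m1), pwm_length(m2), arrangement, spacing, unit)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: a uniformly sampled Eulerian-path rearrangement
#' that preserves the exact dinucleotide multiset and the first and last
#' base of the sequence.
#'
#' @param seq Input sequence (length >= 2).
#' @param seed Optional integer seed.
#' @return A shuffled sequence with identical 16-bin dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  n <- nchar(seq)
  if (n < 2) abort("sequence must have length >= 2")
  with_seed_if(seed, {
    chars <- strsplit(seq, "")[[1]]
    verts <- unique(chars)
    if (length(verts) == 1) return(seq)
    edges <- split(chars[-1], factor(chars[-n], levels = verts))
    last_v <- chars[n]
    active <- names(edges)[lengths(edges) > 0]
    # sample "last edges" forming an arborescence toward the final vertex
    repeat {
      last_edge <- vapply(active, function(v) {
        if (v == last_v) NA_character_ else sample(edges[[v]], 1)
      }, character(1))
      ok <- TRUE
      for (v in active) {
        if (v == last_v) next
        seen <- character(); cur <- v
        while (!is.na(cur) && cur != last_v && !(cur %in% seen)) {
          seen <- c(seen, cur)
          cur <- if (cur %in% active) last_edge[[cur]] else NA_character_
        }
        if (is.na(cur) || cur != last_v) { ok <- FALSE; break }
      }
      if (ok) break
    }
    # permute remaining edges, appending the reserved last edge
    walk_edges <- lapply(setNames(active, active), function(v) {
      e <- edges[[v]]
      if (v != last_v) {
        drop_at <- match(last_edge[[v]], e)
        e <- e[-drop_at]
        c(sample(e), last_edge[[v]])
      } else {
        sample(e)
      }
    })
    ptr <- setNames(integer(length(active)), active)
    out <- character(n)
    out[1] <- chars[1]
    cur <- chars[1]
    for (i in 2:n) {
      ptr[cur] <- ptr[cur] + 1L
      nxt <- walk_edges[[cur]][ptr[cur]]
      out[i] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  })
}

#' Test composite-motif configurations against shuffle null models
#'
#' Scans every stereospecific configuration of a ChIPed motif and one or more
#' partner motifs across a peak set, and assesses each configuration's
#' observed match count against one of two null models: `"shuffle-seq"`
#' (default; ten dinucleotide-preserving shuffles of the peak sequences) or
#' `"shuffle-motif"` (ten column-shuffles of the partner motif scanned over
#' the original peaks). The motif-shuffle null is known to over-estimate the
#' significance of composite motifs whose constituent motifs overlap, because
#' shuffling disperses adjacent high-information "core" columns; the sequence
#' shuffle is therefore the reported default.
#'
#' For each configuration: `z = (observed - mean(null)) / sd(null)` with an
#' sd floor of 0.5 counts (noted when it engages), `p` is the upper-tail
#' normal probability, and the Bonferroni correction multiplies by the full
#' enumeration size of the run (`n_patterns_tested`, default: configurations
#' x partners in this call). A configuration passes when its count reaches
#' `count_filter` of the input peaks and the corrected p-value is at most
#' `alpha`.
#'
#' @param peaks A `peak_set` tibble (peak_id, sequence).
#' @param chiped The ChIPed TF's [pwm()] (motif 1).
#' @param partners A [pwm()] or list of partner motifs (motif 2).
#' @param null `"shuffle-seq"` or `"shuffle-motif"`.
#' @param n_shuffles Null replicates (default 10).
#' @param seed Integer seed for the null randomisation.
#' @param threshold_frac,pseudocount Match-call parameters.
#' @param count_filter Minimum observed count as a fraction of peaks
#'   (default 0.10).
#' @param alpha Bonferroni-adjusted significance level (default 0.05).
#' @param n_patterns_tested Bonferroni denominator; defaults to the number of
#'   patterns enumerated in this call. Supply the global enumeration size
#'   when the call is part of a larger scan.
#' @param unit Count peaks with >= 1 co-occurrence (default) or every
#'   co-occurrence.
#' @param spacing_min,spacing_max Spacing bounds (defaults -5, +10).
#' @return A `cm_scan` tibble: motif1, motif2, arrangement, spacing,
#'   observed, null_mean, null_sd, z, p, p_bonf, passes; attribute
#'   `null_counts` holds the per-pattern null replicate counts.
#' @export
cm_scan <- function(peaks, chiped, partners,
                    null = c("shuffle-seq", "shuffle-motif"),
                    n_shuffles = 10, seed = NULL, threshold_frac = 0.5,
                    pseudocount = 0.01, count_filter = 0.10, alpha = 0.05,
                    n_patterns_tested = NULL, unit = "peaks",
                    spacing_min = -5, spacing_max = 10) {
  null <- match.arg(null)
  if (inherits(partners, "pwm")) partners <- list(partners)
  configs <- enumerate_patterns(spacing_min, spacing_max)
  n_patterns <- nrow(configs) * length(partners)
  n_patterns_tested <- n_patterns_tested %||% n_patterns
  n_peaks <- nrow(peaks)
  seq_lens <- nchar(peaks$sequence)
  sm1 <- loglik_score_matrix(chiped, pseudocount)
  matches1 <- scan_peakset(sm1, peaks$sequence, threshold_frac)
  shuffled_sets <- NULL
  matches1_shuf <- NULL
  if (null == "shuffle-seq") {
    shuffled_sets <- with_seed_if(seed, {
      lapply(seq_len(n_shuffles), function(r)
        vapply(peaks$sequence, dinucleotide_shuffle, character(1),
               USE.NAMES = FALSE))
    })
    matches1_shuf <- lapply(shuffled_sets, function(seqs)
      scan_peakset(sm1, seqs, threshold_frac))
  }
  rows <- vector("list", n_patterns)
  null_counts_all <- vector("list", n_patterns)
  sd_floor_used <- FALSE
  ri <- 0L
  for (pi in seq_along(partners)) {
    m2 <- partners[[pi]]
    sm2 <- loglik_score_matrix(m2, pseudocount)
    matches2 <- scan_peakset(sm2, peaks$sequence, threshold_frac)
    l1 <- pwm_length(chiped); l2 <- pwm_length(m2)
    if (null == "shuffle-seq") {
      matches1_null <- matches1_shuf
      matches2_null <- lapply(shuffled_sets, function(seqs)
        scan_peakset(sm2, seqs, threshold_frac))
      null_lens <- lapply(shuffled_sets, nchar)
    } else {
      shuf_pwms <- with_seed_if(
        if (is.null(seed)) NULL else seed + pi,
        lapply(seq_len(n_shuffles), function(r) shuffle_pwm_columns(m2))
      )
      matches2_null <- lapply(shuf_pwms, function(sp) {
        sms <- loglik_score_matrix(sp, pseudocount)
        scan_peakset(sms, peaks$sequence, threshold_frac)
      })
      matches1_null <- replicate(n_shuffles, matches1, simplify = FALSE)
      null_lens <- replicate(n_shuffles, seq_lens, simplify = FALSE)
    }
    for (ci in seq_len(nrow(configs))) {
      arr <- configs$arrangement[ci]; sp <- configs$spacing[ci]
      obs <- count_config(matches1, matches2, seq_lens, l1, l2, arr, sp, unit)
      nulls <- vapply(seq_len(n_shuffles), function(r)
        count_config(matches1_null[[r]], matches2_null[[r]], null_lens[[r]],
                     l1, l2, arr, sp, unit), integer(1))
      mu <- mean(nulls); sdv <- sd(nulls)
      if (sdv < 0.5) { sdv <- 0.5; sd_floor_used <- TRUE }
      z <- (obs - mu) / sdv
      p <- pnorm(z, lower.tail = FALSE)
      p_bonf <- min(1, p * n_patterns_tested)
      ri <- ri + 1L
      rows[[ri]] <- tibble(
        motif1 = chiped$name, motif2 = m2$name, arrangement = arr,
        spacing = sp, observed = obs, null_mean = mu, null_sd = sdv,
        z = z, p = p, p_bonf = p_bonf,
        passes = obs >= count_filter * n_peaks && p_bonf <= alpha
      )
      null_counts_all[[ri]] <- nulls
    }
  }
  if (sd_floor_used) {
    inform("cm_scan: sd floor of 0.5 counts applied to >=1 null distribution")
  }
  out <- bind_rows(rows)
  ord <- order(-out$z)
  out <- out[ord, , drop = FALSE]
  attr(out, "null_counts") <- null_counts_all[ord]
  attr(out, "null_model") <- null
  attr(out, "n_patterns_tested") <- n_patterns_tested
  class(out) <- c("cm_scan", class(out))
  out
}

# permute motif columns (positions); the column multiset is preserved
shuffle_pwm_columns <- function(p) {
  out <- p
  out$matrix <- p$matrix[sample.int(nrow(p$matrix)), , drop = FALSE]
  out$name <- paste0(p$name, "_shuf")
  out
}

#' Test a single composite-motif configuration
#'
#' Convenience wrapper around [cm_scan()] restricted to one arrangement and
#' spacing (the Bonferroni denominator still defaults to the configuration
#' enumeration size of a full scan, 64).
#'
#' @inheritParams cm_scan
#' @param partner Partner [pwm()].
#' @param arrangement,spacing The configuration to test.
#' @param ... Passed to [cm_scan()].
#' @return One-row `cm_scan` tibble.
#' @export
test_pattern <- function(peaks, chiped, partner, arrangement, spacing,
                         null = "shuffle-seq", n_shuffles = 10, seed = NULL,
                         n_patterns_tested = 64, ...) {
  res <- cm_scan(peaks, chiped, partner, null = null, n_shuffles = n_shuffles,
                 seed = seed, n_patterns_tested = n_patterns_tested, ...)
  res[res$arrangement == arrangement & res$spacing == spacing, , drop = FALSE]
}

#' TF-family enrichment odds ratio among composite motifs
#'
#' `OR = (a/b) / (c/d)` where `a` is the number of TFs of the family involved
#' in a composite motif, `b` the remaining TFs involved in composite motifs,
#' `c` the family's TFs in the scanned motif list and `d` the rest of the
#' list. The standard error is `sqrt(1/a + 1/b + 1/c + 1/d)` and the 95%
#' confidence interval `exp(ln OR +/- 1.96 SE)`. Zero cells engage the
#' Haldane correction (+0.5 to every cell), flagged in the result.
#'
#' @param a,b,c,d Non-negative counts.
#' @param family Family label carried into the result.
#' @return One-row tibble: family, a, b, c, d, odds_ratio, se, ci_low,
#'   ci_high, haldane.
#' @export
family_odds_ratio <- function(a, b, c, d, family = "family") {
  if (any(c(a, b, c, d) < 0)) abort("counts must be non-negative")
  if (all(c(a, b, c, d) == 0)) abort("all-zero contingency table")
  haldane <- any(c(a, b, c, d) == 0)
  if (haldane) {
    inform("family_odds_ratio: zero cell; Haldane correction (+0.5) applied")
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble(
    family = family, a = a, b = b, c = c, d = d,
    odds_ratio = or, se = se,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se),
    haldane = haldane
  )
}

#' Base-count matrix of composite-motif matches
#'
#' Stacks every matching cassette (in canonical orientation: minus-strand
#' cassettes are reverse complemented) and returns per-column base counts
#' over the pattern footprint, suitable for rendering a sequence logo. The
#' footprint spans `len(m1) + len(m2) + spacing` columns (overlap shortens
#' it).
#'
#' @inheritParams count_pattern
#' @return 4 x footprint integer matrix with rownames A, C, G, T.
#' @export
build_cm_logo <- function(peaks, m1, m2, arrangement, spacing,
                          threshold_frac = 0.5, pseudocount = 0.01) {
  sm1 <- loglik_score_matrix(m1, pseudocount)
  sm2 <- loglik_score_matrix(m2, pseudocount)
  l1 <- pwm_length(m1); l2 <- pwm_length(m2)
  foot <- l1 + l2 + spacing
  matches1 <- scan_peakset(sm1, peaks$sequence, threshold_frac)
  matches2 <- scan_peakset(sm2, peaks$sequence, threshold_frac)
  cassettes <- character()
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$sequence[i]
    L <- nchar(s)
    starts <- frame_pair_starts(matches1[[i]], matches2[[i]], arrangement,
                                spacing, l1, l2)
    for (st in starts) cassettes <- c(cassettes, substr(s, st, st + foot - 1))
    f1 <- flip_positions(matches1[[i]], L, l1)
    f2 <- flip_positions(matches2[[i]], L, l2)
    starts_m <- frame_pair_starts(f1, f2, arrangement, spacing, l1, l2)
    for (st in starts_m) {
      plus_start <- L - (st + foot - 1) + 1
      cassettes <- c(cassettes,
                     revcomp(substr(s, plus_start, plus_start + foot - 1)))
    }
  }
  if (length(cassettes) == 0) abort("pattern has no observed matches")
  idx <- seq_to_int(cassettes)
  counts <- matrix(0L, nrow = 4, ncol = foot,
                   dimnames = list(DNA_BASES, NULL))
  for (b in 1:4) counts[b, ] <- colSums(idx == b)
  counts
}
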