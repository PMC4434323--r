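#' Exact null distribution of PWM log-odds scores
#'
#' Computes the exact distribution of the motif's log-odds score
#' (`sum_i log2((p(i, b) + pc) / bg_b)`) for a random background window by
#' position-wise convolution over a discretized score grid (granularity
#' 1/1000 of the total score range by default). The upper-tail mass gives a
#' p-value for any score; discretization only affects p-values below the
#' grid resolution.
#'
#' @param pwm A [pwm()] of length <= 25.
#' @param background Base frequencies (A, C, G, T), all positive.
#' @param pseudocount Probability pseudocount (default 0.01).
#' @param granularity Number of grid steps across the score range.
#' @return A `pwm_score_dist` object; see [score_pvalue()] and
#'   [score_threshold()].
#' @export
pwm_score_distribution <- function(pwm, background = rep(0.25, 4),
                                   pseudocount = 0.01, granularity = 1000) {
  if (pwm_length(pwm) > 25) abort("PWM longer than 25 positions")
  if (any(background <= 0)) abort("background frequencies must be positive")
  background <- background / sum(background)
  w <- pwm_length(pwm)
  S <- log2((pwm$matrix + pseudocount) / rep(background, each = w))
  smin <- sum(apply(S, 1, min)); smax <- sum(apply(S, 1, max))
  delta <- (smax - smin) / granularity
  if (delta <= 0) delta <- 1  # degenerate constant-score motif
  K <- round(S / delta)       # per-position integer scores (shared grid)
  probs <- 1
  offset <- 0L
  for (j in seq_len(w)) {
    kj <- K[j, ] - min(K[j, ])
    step <- numeric(max(kj) + 1L)
    for (b in 1:4) step[kj[b] + 1L] <- step[kj[b] + 1L] + background[b]
    probs <- convolve_dist(probs, step)
    offset <- offset + min(K[j, ])
  }
  structure(
    list(probs = probs, offset = as.integer(offset), delta = delta,
         upper_tail = rev(cumsum(rev(probs))),
         min_score = smin, max_score = smax,
         K = K, background = background),
    class = "pwm_score_dist"
  )
}

convolve_dist <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(q)) {
    if (q[i] > 0) {
      idx <- seq_along(p) + i - 1L
      out[idx] <- out[idx] + p * q[i]
    }
  }
  out
}

# integer window scores of a sequence on the distribution's grid (both
# strands); windows containing N get -Inf
window_grid_scores <- function(dist, seq) {
  K <- dist$K
  w <- nrow(K)
  Kf <- cbind(K, -Inf)
  Kr <- cbind(K[rev(seq_len(w)), c(4, 3, 2, 1), drop = FALSE], -Inf)
  L <- nchar(seq)
  if (L < w) return(list(fwd = numeric(0), rev = numeric(0)))
  idx <- .base_lookup[utf8ToInt(seq)]
  n_off <- L - w + 1L
  sf <- numeric(n_off); sr <- numeric(n_off)
  for (j in seq_len(w)) {
    b <- idx[j:(j + n_off - 1L)]
    sf <- sf + Kf[j, ][b]
    sr <- sr + Kr[j, ][b]
  }
  list(fwd = sf, rev = sr)
}

#' Exact p-value for a PWM window score
#'
#' @param dist A `pwm_score_dist` from [pwm_score_distribution()].
#' @param score Raw log-odds score(s); rounded onto the distribution's grid.
#' @return Upper-tail probability of scoring at least `score` in random
#'   background.
#' @export
score_pvalue <- function(dist, score) {
  idx <- round(score / dist$delta) - dist$offset + 1L
  idx <- pmax(1L, pmin(idx, length(dist$upper_tail) + 1L))
  c(dist$upper_tail, 0)[idx]
}

# p-value for an integer grid score (as returned by window_grid_scores)
grid_pvalue <- function(dist, k) {
  idx <- pmax(1L, pmin(k - dist$offset + 1L, length(dist$upper_tail) + 1L))
  out <- c(dist$upper_tail, 0)[idx]
  out[!is.finite(k)] <- 1
  out
}

#' Smallest grid score whose exact p-value is below a cutoff
#'
#' @inheritParams score_pvalue
#' @param p_cutoff Strict p-value cutoff.
#' @return Integer grid score threshold, or `Inf` when unattainable.
#' @export
score_threshold <- function(dist, p_cutoff) {
  ok <- which(dist$upper_tail < p_cutoff)
  if (length(ok) == 0) return(Inf)
  ok[1] - 1L + dist$offset
}

#' Genes whose promoter contains a strong motif match
#'
#' Scans each promoter (both strands) with the exact-p-value log-odds scanner
#' and reports the genes with at least one window below the p-value cutoff.
#' Promoters are expected to span -500..+100 around the TSS (601 bases);
#' records of other lengths are scanned as-is with a warning.
#'
#' @param pwm A [pwm()].
#' @param promoters Tibble with columns `gene` and `sequence`.
#' @param p_cutoff Per-window exact p-value cutoff (default 1e-4).
#' @param background Background base frequencies for the null.
#' @param pseudocount Probability pseudocount.
#' @return Character vector of gene ids with a match.
#' @export
scan_promoters <- function(pwm, promoters, p_cutoff = 1e-4,
                           background = rep(0.25, 4), pseudocount = 0.01) {
  if (nrow(promoters) == 0) return(character())
  if (any(nchar(promoters$sequence) != 601)) {
    warn("promoter record(s) not 601 bases; scanned as-is")
  }
  dist <- pwm_score_distribution(pwm, background, pseudocount)
  thr <- score_threshold(dist, p_cutoff)
  if (!is.finite(thr)) return(character())
  hit <- vapply(promoters$sequence, function(s) {
    g <- window_grid_scores(dist, s)
    any(g$fwd >= thr) || any(g$rev >= thr)
  }, logical(1), USE.NAMES = FALSE)
  promoters$gene[hit]
}

#' One-sided Fisher enrichment of motif hits in a gene set
#'
#' Hypergeometric (one-sided, enrichment) p-value for the overlap between the
#' genes hit by a motif and a target gene set within a universe.
#'
#' @param hits Character vector of genes with a motif match.
#' @param target Character vector: the gene set.
#' @param universe Character vector: all genes tested.
#' @return One-row tibble: overlap counts, odds ratio estimate and p.
#' @export
geneset_fisher <- function(hits, target, universe) {
  if (length(universe) == 0) abort("empty universe")
  hits <- intersect(hits, universe)
  target <- intersect(target, universe)
  a <- length(intersect(hits, target))
  b <- length(setdiff(target, hits))
  cc <- length(setdiff(hits, target))
  d <- length(universe) - a - b - cc
  p <- stats::phyper(a - 1, length(hits), length(universe) - length(hits),
                     length(target), lower.tail = FALSE)
  tibble(n_overlap = a, n_hits = length(hits), n_target = length(target),
         n_universe = length(universe),
         odds_ratio = (a * d) / max(1e-12, b * cc), p = p)
}

#' Motif x gene-set enrichment with FDR control
#'
#' Runs [scan_promoters()] + [geneset_fisher()] for every motif against every
#' gene set and applies Benjamini-Hochberg FDR across all tests in the run.
#'
#' @param pwms Named list of [pwm()]s.
#' @param promoters Tibble (gene, sequence).
#' @param genesets Tibble (set_id, gene_id).
#' @param p_cutoff Promoter-scan window p cutoff (default 1e-4).
#' @param ... Passed to [scan_promoters()].
#' @return Tibble: motif, set_id, counts, odds_ratio, p, q.
#' @export
enrich_genesets <- function(pwms, promoters, genesets, p_cutoff = 1e-4, ...) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(names(pwms))) {
    names(pwms) <- vapply(pwms, function(m) m$name, character(1))
  }
  universe <- promoters$gene
  out <- purrr::imap(pwms, function(m, nm) {
    hits <- scan_promoters(m, promoters, p_cutoff = p_cutoff, ...)
    genesets |>
      group_by(.data$set_id) |>
      summarise(res = list(geneset_fisher(hits, .data$gene_id, universe)),
                .groups = "drop") |>
      unnest("res") |>
      mutate(motif = nm, .before = 1)
  }) |> bind_rows()
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Energy-model affinity score of a bait sequence
#'
#' Occupancy sum (the [energy_score_probes()] model) over the
#' promoter-proximal first `scan_length` bases of the bait, both strands.
#' Baits shorter than `scan_length` are scored in full with a warning.
#'
#' @param pwm A [pwm()].
#' @param bait Bait sequence(s).
#' @param scan_length Proximal window (default 500 bases).
#' @param pseudocount,mu Energy-model parameters.
#' @return Numeric affinity score per bait.
#' @export
y1h_affinity_score <- function(pwm, bait, scan_length = 500,
                               pseudocount = 0.01, mu = 0) {
  if (any(nchar(bait) < scan_length)) {
    warn("bait(s) shorter than scan_length; scored in full")
  }
  prox <- substr(bait, 1, scan_length)
  energy_score_probes(pwm, prox, pseudocount = pseudocount, mu = mu)
}

#' Mann-Whitney enrichment of motif affinity in Y1H positives
#'
#' Two-tailed Mann-Whitney U test comparing energy-model affinity scores of
#' positive (interacting) baits against negative baits. TFs binding fewer
#' than `min_positives` baits are refused (`status = "not_tested"`) to avoid
#' the sampling error of tiny positive sets. Direction comes from the sign of
#' the rank-biserial correlation.
#'
#' @param pwm The TF's [pwm()].
#' @param positives,negatives Tibbles with a `sequence` column.
#' @param min_positives Inclusion rule (default 5).
#' @param scan_length Proximal scan window (default 500).
#' @return One-row tibble: statistic (U), p, direction, status, n_pos, n_neg.
#' @export
y1h_mann_whitney <- function(pwm, positives, negatives, min_positives = 5,
                             scan_length = 500) {
  n_pos <- nrow(positives); n_neg <- nrow(negatives)
  if (n_pos < min_positives) {
    return(tibble(statistic = NA_real_, p = NA_real_,
                  direction = NA_character_, status = "not_tested",
                  n_pos = n_pos, n_neg = n_neg))
  }
  xp <- y1h_affinity_score(pwm, positives$sequence, scan_length = scan_length)
  xn <- y1h_affinity_score(pwm, negatives$sequence, scan_length = scan_length)
  wt <- suppressWarnings(wilcox.test(xp, xn, alternative = "two.sided"))
  u <- unname(wt$statistic)
  rank_biserial <- 2 * u / (n_pos * n_neg) - 1
  tibble(
    statistic = u, p = wt$p.value,
    direction = ifelse(rank_biserial >= 0, "enriched", "depleted"),
    status = "tested", n_pos = n_pos, n_neg = n_neg
  )
}

#' Y1H enrichment across a panel of TFs with FDR control
#'
#' @param pwms Named list of [pwm()]s.
#' @param datasets Named list (same names) of lists with `positives` and
#'   `negatives` tibbles, e.g. from [generate_y1h_dataset()].
#' @param ... Passed to [y1h_mann_whitney()].
#' @return Tibble with one row per TF; q is BH-FDR over the tested TFs.
#' @export
enrich_y1h <- function(pwms, datasets, ...) {
  out <- purrr::imap(pwms, function(m, nm) {
    d <- datasets[[nm]]
    y1h_mann_whitney(m, d$positives, d$negatives, ...) |>
      mutate(motif = nm, .before = 1)
  }) |> bind_rows()
  out$q <- NA_real_
  tested <- out$status == "tested"
  out$q[tested] <- p.adjust(out$p[tested], method = "BH")
  out
}

#' Simplified central-enrichment test for peak sets
#'
#' A deliberately simplified stand-in for full central-enrichment analysis:
#' for each peak the best-scoring motif window (either strand; ties to the
#' leftmost) contributes its midpoint, and a one-sided binomial test asks
#' whether more midpoints fall within a central window than expected if best
#' matches were uniform over the attainable midpoint range. Unlike the full
#' CentriMo algorithm there is no likelihood-ratio optimisation over window
#' widths; results carry a `"simplified-centrimo"` method tag.
#'
#' @param pwm A [pwm()].
#' @param peaks A `peak_set` tibble; peaks should have uniform length
#'   (otherwise positions are normalised with a warning).
#' @param center_window Width of the central window in bases (default 100).
#' @param pseudocount Log-odds pseudocount for scoring.
#' @return One-row tibble: statistic (fraction central), expected fraction,
#'   p, method.
#' @export
central_enrichment <- function(pwm, peaks, center_window = 100,
                               pseudocount = 0.01) {
  lens <- nchar(peaks$sequence)
  uniform_len <- length(unique(lens)) == 1
  if (!uniform_len) {
    warn("variable peak lengths; midpoint positions normalised per peak")
  }
  w <- pwm_length(pwm)
  sm <- loglik_score_matrix(pwm, pseudocount)
  best_mid <- vapply(peaks$sequence, function(s) {
    L <- nchar(s)
    idx <- .base_lookup[utf8ToInt(s)]
    n_off <- L - w + 1L
    sf <- numeric(n_off); sr <- numeric(n_off)
    for (j in seq_len(w)) {
      b <- idx[j:(j + n_off - 1L)]
      sf <- sf + sm$fwd[j, ][b]
      sr <- sr + sm$rev[j, ][b]
    }
    sc <- pmax(sf, sr)
    pos <- which.max(sc)
    mid <- pos + (w - 1) / 2
    if (uniform_len) mid else mid / L * lens[1]
  }, numeric(1), USE.NAMES = FALSE)
  L <- lens[1]
  n_off <- L - w + 1L
  mids <- seq_len(n_off) + (w - 1) / 2
  center <- (L + 1) / 2
  in_window <- abs(mids - center) <= center_window / 2
  prob <- mean(in_window)
  k <- sum(abs(best_mid - center) <= center_window / 2)
  p <- if (prob >= 1) 1 else
    stats::binom.test(k, nrow(peaks), prob, alternative = "greater")$p.value
  tibble(
    statistic = k / nrow(peaks), expected = prob, n_central = k,
    n_peaks = nrow(peaks), p = p, method = "simplified-centrimo"
  )
}

#' Central enrichment across motifs with FDR control
#'
#' @param pwms Named list of [pwm()]s.
#' @param peaks A `peak_set`.
#' @param ... Passed to [central_enrichment()].
#' @return Tibble with q = BH-FDR across motifs.
#' @export
enrich_central <- function(pwms, peaks, ...) {
  out <- purrr::imap(pwms, function(m, nm) {
    central_enrichment(m, peaks, ...) |> mutate(motif = nm, .before = 1)
  }) |> bind_rows()
  out$q <- p.adjust(out$p, method = "BH")
  out
}
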