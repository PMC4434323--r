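#' Derive a PWM from top-scoring k-mers (alignment method)
#'
#' The top `top_n` k-mers by E-score are stacked: the best-scoring word seeds
#' the alignment, and each remaining word is placed at the ungapped offset and
#' orientation (overlap >= 6 bases) maximising identity to the seed, ties
#' broken toward smaller absolute offset and then the forward orientation.
#' Aligned base counts plus a pseudocount are normalised to probabilities;
#' flanking columns supported by fewer than `top_n / 2` words are trimmed
#' from the ends. Seed ties (equal top E) resolve to the lexicographically
#' smaller canonical word, so derivation is deterministic.
#'
#' @param table A `kmer_table` with an `E` column (>= `top_n` rows).
#' @param top_n Number of top k-mers stacked (default 10).
#' @param pseudocount Count added per base per column before normalisation.
#' @param min_overlap Minimum seed overlap for placing a word (default 6).
#' @param name,tf_id Labels for the returned [pwm()].
#' @return A `pwm` with source `"PBM"`, evidence `"experimental"`.
#' @export
derive_pwm_align <- function(table, top_n = 10, pseudocount = 0.5,
                             min_overlap = 6, name = "derived",
                             tf_id = name) {
  if (top_n < 2) abort("top_n must be at least 2")
  if (nrow(table) < top_n) abort("table has fewer than top_n rows")
  top <- table |> arrange(desc(.data$E), .data$kmer) |> head(top_n)
  words <- top$kmer
  k <- nchar(words[1])
  seed <- words[1]
  # candidate placements ordered by the tie-break rule
  offsets <- seq(-(k - min_overlap), k - min_overlap)
  offsets <- offsets[order(abs(offsets), offsets)]
  place <- function(word) {
    best <- NULL
    for (o in offsets) {
      for (orient in c("F", "R")) {
        w <- if (orient == "F") word else revcomp(word)
        # overlap columns in seed coordinates
        lo <- max(0L, o); hi <- min(k, o + k) - 1L
        seed_chars <- strsplit(seed, "")[[1]][(lo + 1L):(hi + 1L)]
        w_chars <- strsplit(w, "")[[1]][(lo - o + 1L):(hi - o + 1L)]
        ident <- sum(seed_chars == w_chars)
        if (is.null(best) || ident > best$ident) {
          best <- list(offset = o, word = w, ident = ident)
        }
      }
    }
    best
  }
  placements <- c(list(list(offset = 0L, word = seed, ident = k)),
                  lapply(words[-1], place))
  offs <- vapply(placements, function(p) as.integer(p$offset), integer(1))
  lo <- min(offs); hi <- max(offs) + k - 1L
  width <- hi - lo + 1L
  counts <- matrix(0, nrow = width, ncol = 4)
  support <- integer(width)
  for (p in placements) {
    idx <- .base_lookup[utf8ToInt(p$word)]
    cols <- (p$offset - lo + 1L):(p$offset - lo + k)
    counts[cbind(cols, idx)] <- counts[cbind(cols, idx)] + 1
    support[cols] <- support[cols] + 1L
  }
  ok <- support >= top_n / 2
  first <- which(ok)[1]; last <- rev(which(ok))[1]
  if (is.na(first)) abort("no columns meet the support threshold")
  counts <- counts[first:last, , drop = FALSE]
  pwm(counts + pseudocount, name = name, tf_id = tf_id,
      source = "PBM", evidence = "experimental")
}

#' Boltzmann occupancy scores for probe sequences
#'
#' Energy-model scoring: per-position mismatch energies are
#' `eps(i, b) = -ln(p(i, b) + pc) + ln(max_b p(i, b) + pc)` (zero for the
#' optimal base), and a probe's predicted score is the occupancy sum over
#' both strands and all offsets of `1 / (1 + exp(E_site - mu))`, with
#' chemical potential `mu`. Windows containing non-ACGT characters contribute
#' nothing. Scores are strand-symmetric: a probe and its reverse complement
#' score identically.
#'
#' @param pwm A [pwm()].
#' @param probes Character vector of sequences, each at least as long as the
#'   motif (lengths may differ between probes).
#' @param pseudocount Probability pseudocount `pc` (default 0.01).
#' @param mu Chemical-potential offset (default 0).
#' @return Numeric vector of occupancy scores, one per probe.
#' @export
energy_score_probes <- function(pwm, probes, pseudocount = 0.01, mu = 0) {
  w <- pwm_length(pwm)
  if (any(nchar(probes) < w)) abort("all probes must be at least PWM length")
  eps_of <- function(p) {
    e <- -log(p$matrix + pseudocount) +
      log(matrixStats_rowMax(p$matrix) + pseudocount)
    cbind(e, Inf)  # 5th column: N never binds
  }
  eps_f <- eps_of(pwm)
  eps_r <- eps_of(pwm_revcomp(pwm))
  out <- numeric(length(probes))
  for (L in unique(nchar(probes))) {
    sel <- which(nchar(probes) == L)
    M <- seq_to_int(probes[sel])
    occ <- numeric(length(sel))
    for (o in seq_len(L - w + 1L)) {
      ef <- numeric(length(sel)); er <- numeric(length(sel))
      for (j in seq_len(w)) {
        b <- M[, o + j - 1L]
        ef <- ef + eps_f[j, ][b]
        er <- er + eps_r[j, ][b]
      }
      occ <- occ + 1 / (1 + exp(ef - mu)) + 1 / (1 + exp(er - mu))
    }
    out[sel] <- occ
  }
  out
}

# rowMaxs without a matrixStats dependency
matrixStats_rowMax <- function(m) do.call(pmax, as.data.frame(m))

#' Evaluate a candidate PWM on a held-out array
#'
#' Scores the held-out probes under the energy model and reports (1) the
#' Pearson correlation of predicted scores with observed (log) intensities
#' and (2) the AUROC with which predicted scores separate "bright" probes
#' (probe-level intensity Z >= `bright_z`) from the rest.
#'
#' @param pwm Candidate [pwm()].
#' @param heldout A detrended `pbm_experiment` from the complementary design.
#' @param bright_z Probe Z-score cutoff defining bright probes (default 4).
#' @param log_intensity Correlate against log intensities (default) or raw.
#' @return One-row tibble: pearson_r, bright_auroc, n_bright, heldout_design.
#' @export
evaluate_pwm <- function(pwm, heldout, bright_z = 4, log_intensity = TRUE) {
  if (!is_detrended(heldout)) {
    warn("held-out experiment not marked detrended")
  }
  heldout <- heldout[heldout$flag == "ok", , drop = FALSE]
  pred <- energy_score_probes(pwm, heldout$sequence)
  obs <- if (log_intensity) log(heldout$intensity) else heldout$intensity
  r <- suppressWarnings(cor(pred, obs))
  if (is.na(r)) r <- 0
  z <- (obs - mean(obs)) / sd(obs)
  bright <- z >= bright_z
  nb <- sum(bright); nn <- sum(!bright)
  if (nb == 0 || nn == 0) {
    warn("no bright/non-bright split; bright_auroc undefined")
    auroc <- NA_real_
  } else {
    if (nb < 10) warn(sprintf("only %d bright probes; AUROC is low-confidence", nb))
    rk <- rank(pred)  # average ranks: constant predictions give AUROC 0.5
    auroc <- (sum(rk[bright]) - nb * (nb + 1) / 2) / (nb * nn)
  }
  tibble(pearson_r = r, bright_auroc = auroc, n_bright = nb,
         heldout_design = attr(heldout, "design_id") %||% "heldout")
}

#' Select the best candidate PWM by mean rank of two criteria
#'
#' Candidates are ranked separately by held-out Pearson correlation and by
#' bright-probe AUROC; the candidate with the best (lowest) mean rank wins.
#' Ties break toward higher bright-probe AUROC, then toward the shorter
#' motif.
#'
#' @param candidates List of [pwm()]s.
#' @param evaluations Tibble from [evaluate_pwm()], one row per candidate in
#'   the same order.
#' @return The selected `pwm`.
#' @export
select_best_pwm <- function(candidates, evaluations) {
  if (length(candidates) == 0) abort("no candidate PWMs")
  if (length(candidates) != nrow(evaluations)) {
    abort("candidates and evaluations must match in length")
  }
  r1 <- rank(-evaluations$pearson_r, ties.method = "average")
  r2 <- rank(-evaluations$bright_auroc, ties.method = "average")
  mean_rank <- (r1 + r2) / 2
  len <- vapply(candidates, pwm_length, integer(1))
  ord <- order(mean_rank, -evaluations$bright_auroc, len)
  candidates[[ord[1]]]
}
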