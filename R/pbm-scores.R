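#' Remove flagged array spots
#'
#' Drops probes whose QC flag is `"bad"` or `"suspect"` (anything other than
#' `"ok"`), keeping downstream statistics blind to them.
#'
#' @param exp A `pbm_experiment`.
#' @return The experiment restricted to `flag == "ok"` probes.
#' @export
filter_probes <- function(exp) {
  keep <- exp$flag == "ok"
  if (!any(keep)) abort("no probes remain after flag filtering")
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    inform(sprintf("filter_probes: removed %d flagged probe(s)", n_removed))
  }
  out <- exp[keep, , drop = FALSE]
  new_pbm_experiment(out, attr(exp, "design_id") %||% "exp",
                     detrended = is_detrended(exp))
}

#' Spatial de-trending of array intensities
#'
#' Divides each spot's intensity by the ratio of the median intensity in the
#' `window` x `window` grid neighbourhood centred on the spot to the global
#' median, removing smooth spatial bias while leaving isolated bright spots
#' (true signal) intact. Neighbourhoods are truncated at grid edges.
#'
#' @param exp A `pbm_experiment` with grid coordinates.
#' @param window Odd window size >= 3; default 7 (a 7 x 7 neighbourhood).
#' @return The experiment with adjusted intensities, marked detrended.
#' @export
spatial_detrend <- function(exp, window = 7) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    abort("window must be an odd integer >= 3")
  }
  nr <- max(exp$row); nc <- max(exp$col)
  M <- matrix(NA_real_, nr, nc)
  M[cbind(exp$row, exp$col)] <- exp$intensity
  h <- (window - 1L) %/% 2L
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  stack <- matrix(NA_real_, nrow = nr * nc, ncol = nrow(offs))
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    src_r <- intersect(seq_len(nr), seq_len(nr) - dr)
    src_c <- intersect(seq_len(nc), seq_len(nc) - dc)
    sh <- matrix(NA_real_, nr, nc)
    sh[src_r, src_c] <- M[src_r + dr, src_c + dc]
    stack[, i] <- as.vector(sh)
  }
  local_med <- apply(stack, 1, median, na.rm = TRUE)
  global_med <- median(exp$intensity)
  ratio <- local_med[(exp$col - 1L) * nr + exp$row] / global_med
  out <- exp
  out$intensity <- exp$intensity / ratio
  new_pbm_experiment(out, attr(exp, "design_id") %||% "exp", detrended = TRUE)
}

# distinct (canonical k-mer, probe index) pairs: probe contains the k-mer on
# either strand
kmer_probe_pairs <- function(seqs, k) {
  L <- nchar(seqs[1])
  n_off <- L - k + 1L
  n <- length(seqs)
  words <- character(n * n_off)
  for (o in seq_len(n_off)) {
    words[((o - 1L) * n + 1L):(o * n)] <- substring(seqs, o, o + k - 1L)
  }
  tibble(
    kmer = canonical_kmer(words),
    probe = rep(seq_len(n), times = n_off)
  ) |> distinct()
}

#' 8-mer E-scores from probe intensities
#'
#' E-scores are a modified AUROC over the intensity ranking: for each
#' canonical k-mer (a word and its reverse complement share a key), the
#' foreground is the set of probes containing the k-mer on either strand, and
#' E is the Wilcoxon-Mann-Whitney AUROC computed between the top half of the
#' foreground and the top half of the background (by intensity rank), minus
#' 0.5. E is bounded in \[-0.5, +0.5\]; values above 0.45 indicate highly
#' significant binding preference. Rank ties are resolved by probe order
#' (stable); with continuous intensities ties do not occur.
#'
#' @param exp A detrended, filtered `pbm_experiment`.
#' @param k Word length (default 8).
#' @param variant `"berger"` (top-half convention, default) or `"full"`
#'   (plain AUROC over all foreground and background probes, minus 0.5).
#' @return A `kmer_table` tibble (kmer, E, n_probes) over canonical k-mers,
#'   sorted by decreasing E.
#' @export
compute_escores <- function(exp, k = 8, variant = c("berger", "full")) {
  variant <- match.arg(variant)
  if (!is_detrended(exp)) {
    warn("experiment not marked detrended; E-scores assume detrended input")
  }
  exp <- exp[exp$flag == "ok", , drop = FALSE]
  N <- nrow(exp)
  pos_in_order <- integer(N)
  pos_in_order[order(-exp$intensity)] <- seq_len(N)
  pairs <- kmer_probe_pairs(exp$sequence, k)
  pairs$pos <- pos_in_order[pairs$probe]
  scores <- pairs |>
    arrange(.data$kmer, .data$pos) |>
    group_by(.data$kmer) |>
    mutate(i = dplyr::row_number(), f = dplyr::n()) |>
    ungroup() |>
    mutate(
      half_f = if (variant == "berger") ceiling(.data$f / 2) else .data$f,
      K2 = if (variant == "berger") ceiling((N - .data$f) / 2) else N - .data$f,
      win = pmax(0, .data$K2 - pmin(.data$pos - .data$i, .data$K2))
    ) |>
    filter(.data$i <= .data$half_f) |>
    group_by(.data$kmer) |>
    summarise(
      E = sum(.data$win) / (.data$half_f[1] * .data$K2[1]) - 0.5,
      n_probes = .data$f[1],
      .groups = "drop"
    ) |>
    mutate(E = pmin(0.5, pmax(-0.5, .data$E))) |>
    arrange(desc(.data$E), .data$kmer)
  new_kmer_table(scores, k = k)
}

new_kmer_table <- function(x, k) {
  attr(x, "k") <- k
  attr(x, "canonicalized") <- TRUE
  class(x) <- unique(c("kmer_table", class(x)))
  x
}

#' 8-mer Z-scores from probe intensities
#'
#' For each canonical k-mer the statistic is the mean (log-transformed) spot
#' intensity over probes containing the word on either strand; Z subtracts
#' the median of these statistics across all k-mers and divides by their
#' standard deviation, yielding a distribution with median 0 and sd 1.
#' Z-scores scale approximately with binding affinity.
#'
#' @inheritParams compute_escores
#' @param log_transform Average log intensities (default) or raw intensities.
#' @param aggregate `"mean"` (default) or `"median"` per-k-mer aggregation.
#' @return A `kmer_table` tibble (kmer, Z, n_probes).
#' @export
compute_zscores <- function(exp, k = 8, log_transform = TRUE,
                            aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (!is_detrended(exp)) {
    warn("experiment not marked detrended; Z-scores assume detrended input")
  }
  exp <- exp[exp$flag == "ok", , drop = FALSE]
  vals <- if (log_transform) log(exp$intensity) else exp$intensity
  pairs <- kmer_probe_pairs(exp$sequence, k)
  pairs$val <- vals[pairs$probe]
  agg_fun <- if (aggregate == "mean") mean else median
  stats <- pairs |>
    group_by(.data$kmer) |>
    summarise(x = agg_fun(.data$val), n_probes = dplyr::n(), .groups = "drop")
  if (nrow(stats) < 2) abort("need at least 2 distinct k-mers for Z-scores")
  s <- sd(stats$x)
  if (!is.finite(s) || s == 0) {
    abort("k-mer statistics have zero spread; Z-scores undefined")
  }
  out <- stats |>
    mutate(Z = (.data$x - median(.data$x)) / s) |>
    select("kmer", "Z", "n_probes") |>
    arrange(desc(.data$Z), .data$kmer)
  new_kmer_table(out, k = k)
}

#' Combined E/Z score table for one experiment
#'
#' @inheritParams compute_escores
#' @inheritParams compute_zscores
#' @return A `kmer_table` with columns kmer, E, Z, n_probes.
#' @export
kmer_score_table <- function(exp, k = 8, variant = "berger",
                             log_transform = TRUE) {
  e <- compute_escores(exp, k = k, variant = variant)
  z <- compute_zscores(exp, k = k, log_transform = log_transform)
  out <- left_join(e, select(z, "kmer", "Z"), by = "kmer") |>
    select("kmer", "E", "Z", "n_probes")
  new_kmer_table(out, k = k)
}

#' Call experiment success from two complementary arrays
#'
#' An experiment is deemed successful when (i) at least one k-mer has an
#' E-score above `e_cutoff` on both arrays, (ii) the two arrays' E- and
#' Z-scores are highly correlated, and (iii) the two arrays yield similar
#' PWMs (information-content-weighted aligned correlation).
#'
#' @param table_a,table_b `kmer_table`s (with E and Z columns) from the two
#'   array designs, canonicalized identically.
#' @param pwm_a,pwm_b Optional PWMs derived from each array; if either is
#'   missing the PWM-similarity criterion is skipped with a warning.
#' @param tf_id Label carried into the report.
#' @param e_cutoff Joint E-score threshold (default 0.45).
#' @param r_e,r_z Minimum cross-array Pearson correlations of E and Z
#'   (defaults 0.6; "highly correlated" has no printed value, so these are
#'   explicit configuration).
#' @param r_p Minimum aligned-PWM correlation (default 0.8).
#' @return One-row tibble: tf_id, pass, max_joint_E, cross-array E/Z
#'   correlations and PWM similarity.
#' @export
assess_success <- function(table_a, table_b, pwm_a = NULL, pwm_b = NULL,
                           tf_id = "tf", e_cutoff = 0.45, r_e = 0.6,
                           r_z = 0.6, r_p = 0.8) {
  j <- inner_join(table_a, table_b, by = "kmer", suffix = c("_a", "_b"))
  if (nrow(j) < 2) abort("score tables share fewer than 2 k-mers")
  max_joint_e <- max(pmin(j$E_a, j$E_b))
  cor_e <- cor(j$E_a, j$E_b)
  cor_z <- if ("Z_a" %in% names(j)) cor(j$Z_a, j$Z_b) else NA_real_
  if (is.null(pwm_a) || is.null(pwm_b)) {
    warn("PWM(s) missing; PWM-similarity criterion skipped")
    pwm_sim <- NA_real_
    pwm_ok <- TRUE
  } else {
    pwm_sim <- align_pwms(pwm_a, pwm_b)$ic_weighted_r
    pwm_ok <- pwm_sim >= r_p
  }
  z_ok <- is.na(cor_z) || cor_z >= r_z
  tibble(
    tf_id = tf_id,
    pass = max_joint_e > e_cutoff && cor_e >= r_e && z_ok && pwm_ok,
    max_joint_E = max_joint_e,
    cross_array_E_correlation = cor_e,
    cross_array_Z_correlation = cor_z,
    pwm_similarity = pwm_sim
  )
}

#' Count k-mers bound by at least one TF
#'
#' Applies the bound-word filter used when summarising a PBM compendium:
#' a k-mer counts as bound if its E-score, averaged between the two replicate
#' array designs, exceeds `cutoff` for at least one TF.
#'
#' @param pairs Named list (one element per TF) of two-element lists of
#'   `kmer_table`s, one per array design.
#' @param cutoff Average-E threshold (default 0.45).
#' @return Integer: number of distinct canonical k-mers bound by >= 1 TF.
#' @export
count_bound_kmers <- function(pairs, cutoff = 0.45) {
  bound <- purrr::map(pairs, function(p) {
    j <- inner_join(p[[1]], p[[2]], by = "kmer", suffix = c("_a", "_b"))
    j$kmer[(j$E_a + j$E_b) / 2 > cutoff]
  })
  length(unique(unlist(bound)))
}
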