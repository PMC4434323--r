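#' Percent identity between DNA-binding-domain sequences
#'
#' Global alignment (BLOSUM62, gap open 11 / extend 1) of two amino-acid
#' sequences; percent identity is 100 x identities over aligned columns,
#' excluding terminal gaps. Multi-domain proteins are handled by passing the
#' domains as a character vector, which is concatenated in order before
#' alignment.
#'
#' @param seq_a,seq_b Amino-acid sequence(s); vectors are concatenated.
#' @return Percent identity in \[0, 100\].
#' @examples
#' dbd_percent_identity("ACDEF", "ACDEY")  # 80
#' @export
dbd_percent_identity <- function(seq_a, seq_b) {
  seq_a <- paste(seq_a, collapse = "")
  seq_b <- paste(seq_b, collapse = "")
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) abort("empty DBD sequence")
  ok <- "^[ACDEFGHIKLMNPQRSTVWY]+$"
  if (!grepl(ok, seq_a) || !grepl(ok, seq_b)) {
    abort("DBD sequences must use the 20 standard amino-acid letters")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global"
  )
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  term_gap <- function(x) {
    lead <- match(FALSE, x == "-", nomatch = length(x) + 1L) - 1L
    trail <- match(FALSE, rev(x) == "-", nomatch = length(x) + 1L) - 1L
    c(lead, trail)
  }
  ta <- term_gap(a); tb <- term_gap(b)
  from <- max(ta[1], tb[1]) + 1L
  to <- length(a) - max(ta[2], tb[2])
  if (to < from) return(0)
  100 * sum(a[from:to] == b[from:to]) / (to - from + 1L)
}

#' Default per-family homology thresholds
#'
#' Percent-identity thresholds above which a characterised TF's motif may be
#' transferred to an uncharacterised family member. Values are supplied for
#' the families with documented thresholds (NHR 70, DM 85); all other classes
#' fall back to a conservative default of 70.
#'
#' @param ... Named overrides, e.g. `Homeodomain = 70`.
#' @param default Fallback threshold for unlisted classes.
#' @return Named numeric vector with a `.default` entry.
#' @export
family_thresholds <- function(..., default = 70) {
  out <- c(NHR = 70, DM = 85, .default = default)
  dots <- c(...)
  out[names(dots)] <- dots
  out
}

#' Transfer motifs to uncharacterised TFs by DBD homology
#'
#' Each target TF is assigned the motif of its best-matching source TF of the
#' same DBD class, provided the percent identity meets the class threshold.
#' Transfers are direct only (never chained through intermediates), never
#' cross class boundaries, and skip targets that already carry an
#' experimental motif.
#'
#' @param targets Tibble with `tf_id`, `dbd_class`, `dbd_sequence` and
#'   optionally a `motif` list-column (targets with a motif are skipped).
#' @param sources Tibble with `tf_id`, `dbd_class`, `dbd_sequence` and a
#'   `motif` list-column of [pwm()]s.
#' @param thresholds Named thresholds from [family_thresholds()].
#' @return Tibble: target_tf, source_tf, pct_id, motif (list-column; copies
#'   of the source motifs marked `evidence = "inferred"`).
#' @export
infer_motifs_by_homology <- function(targets, sources,
                                     thresholds = family_thresholds()) {
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    tgt <- targets[i, ]
    if ("motif" %in% names(targets) && !is.null(tgt$motif[[1]])) next
    thr <- thresholds[tgt$dbd_class]
    if (is.na(thr)) thr <- thresholds[".default"]
    if (is.na(thr)) {
      warn(sprintf("no threshold for class '%s'; target %s skipped",
                   tgt$dbd_class, tgt$tf_id))
      next
    }
    cand <- sources[sources$dbd_class == tgt$dbd_class &
                      sources$tf_id != tgt$tf_id, , drop = FALSE]
    if (nrow(cand) == 0) next
    ids <- vapply(cand$dbd_sequence, function(s)
      dbd_percent_identity(tgt$dbd_sequence, s), numeric(1),
      USE.NAMES = FALSE)
    best <- which.max(ids)
    if (ids[best] >= thr) {
      m <- cand$motif[[best]]
      m$evidence <- "inferred"
      m$tf_id <- tgt$tf_id
      m$notes <- sprintf("inferred from %s at %.1f%% DBD identity",
                         cand$tf_id[best], ids[best])
      rows[[length(rows) + 1]] <- tibble(
        target_tf = tgt$tf_id, source_tf = cand$tf_id[best],
        pct_id = ids[best], motif = list(m)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(target_tf = character(), source_tf = character(),
                  pct_id = numeric(), motif = list()))
  }
  bind_rows(rows)
}

#' Fraction of shared high-scoring k-mers between two experiments
#'
#' Overlap coefficient of the two top sets (k-mers with E above `cutoff`):
#' `100 * |A intersect B| / min(|A|, |B|)`.
#'
#' @param table_a,table_b `kmer_table`s canonicalized identically.
#' @param cutoff E-score threshold defining the top sets (default 0.45).
#' @return Percentage in \[0, 100\], or `NA` when either top set is empty.
#' @export
shared_8mer_fraction <- function(table_a, table_b, cutoff = 0.45) {
  top_a <- table_a$kmer[table_a$E > cutoff]
  top_b <- table_b$kmer[table_b$E > cutoff]
  if (length(top_a) == 0 || length(top_b) == 0) {
    warn("empty top set; shared fraction undefined")
    return(NA_real_)
  }
  100 * length(intersect(top_a, top_b)) / min(length(top_a), length(top_b))
}

# weighted Pearson correlation; returns NA on zero variance
weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  if (sw == 0) return(NA_real_)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Align two PWMs by information-content weighted correlation
#'
#' Slides `b` against `a` over all ungapped offsets with at least
#' `min_overlap` overlapping columns, in both orientations, and computes the
#' Pearson correlation between the flattened overlapping probability columns,
#' weighting each column pair by the mean of the two columns' information
#' content (`IC = 2 + sum(p log2 p)`). Returns the maximising configuration.
#' If every admissible configuration has zero total IC weight (e.g. a uniform
#' motif), the similarity is reported as 0 with a warning.
#'
#' @param a,b [pwm()]s.
#' @param min_overlap Minimum overlapping columns (default 4).
#' @param ic_weight `"mean"` (default) or `"product"` combination of the two
#'   columns' IC into a weight.
#' @return One-row tibble: `offset` (of b's first column relative to a's,
#'   after orienting), `orientation` (`"F"`/`"R"`), `ic_weighted_r`.
#' @export
align_pwms <- function(a, b, min_overlap = 4, ic_weight = c("mean", "product")) {
  ic_weight <- match.arg(ic_weight)
  la <- pwm_length(a); lb <- pwm_length(b)
  if (min(la, lb) < min_overlap) abort("no offset satisfies min_overlap")
  ic_a <- pwm_ic(a)
  best <- NULL
  any_weight <- FALSE
  for (orient in c("F", "R")) {
    bb <- if (orient == "F") b else pwm_revcomp(b)
    ic_b <- pwm_ic(bb)
    for (o in seq(-(lb - min_overlap), la - min_overlap)) {
      lo <- max(0L, o); hi <- min(la, o + lb) - 1L
      cols_a <- (lo + 1L):(hi + 1L)
      cols_b <- (lo - o + 1L):(hi - o + 1L)
      wcol <- if (ic_weight == "mean") {
        (ic_a[cols_a] + ic_b[cols_b]) / 2
      } else {
        ic_a[cols_a] * ic_b[cols_b]
      }
      if (sum(wcol) > 0) any_weight <- TRUE
      r <- weighted_pearson(
        as.vector(t(a$matrix[cols_a, , drop = FALSE])),
        as.vector(t(bb$matrix[cols_b, , drop = FALSE])),
        rep(wcol, each = 4)
      )
      if (is.na(r)) r <- 0
      if (is.null(best) || r > best$ic_weighted_r) {
        best <- list(offset = o, orientation = orient, ic_weighted_r = r)
      }
    }
  }
  if (!any_weight) {
    warn("all column weights are zero (uniform motif?); similarity set to 0")
    best$ic_weighted_r <- 0
  }
  tibble(offset = best$offset, orientation = best$orientation,
         ic_weighted_r = best$ic_weighted_r)
}

#' Cluster a motif collection by aligned similarity
#'
#' Average-linkage hierarchical clustering on distance
#' `1 - ic_weighted_r`, cut at the deepest (closest-to-root) branches whose
#' average pairwise internal correlation meets `r_threshold`. Each emitted
#' cluster carries a centroid: the position-wise mean of the members after
#' aligning each to the member with the greatest summed similarity.
#'
#' @param motifs List of [pwm()]s (names taken from the motifs).
#' @param r_threshold Internal-correlation cut (default 0.8).
#' @param min_overlap Passed to [align_pwms()].
#' @return A `motif_clusters` tibble: cluster_id, members (list of names),
#'   n_members, mean_internal_r, centroid (list of `pwm`).
#' @export
cluster_pwms <- function(motifs, r_threshold = 0.8, min_overlap = 4) {
  n <- length(motifs)
  if (n == 0) abort("need at least one motif")
  nms <- vapply(motifs, function(m) m$name, character(1))
  nms <- make.unique(nms)
  if (n == 1) {
    out <- tibble(cluster_id = "c1", members = list(nms), n_members = 1L,
                  mean_internal_r = 1, centroid = motifs[1])
    class(out) <- c("motif_clusters", class(out))
    return(out)
  }
  R <- diag(1, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- align_pwms(motifs[[i]], motifs[[j]], min_overlap = min_overlap)$ic_weighted_r
    R[i, j] <- r; R[j, i] <- r
  }
  hc <- hclust(as.dist(1 - R), method = "average")
  # members of each internal node of the merge tree
  node_members <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    get <- function(x) if (x < 0) -x else node_members[[x]]
    node_members[[m]] <- c(get(hc$merge[m, 1]), get(hc$merge[m, 2]))
  }
  mean_r <- function(idx) {
    if (length(idx) == 1) return(1)
    sub <- R[idx, idx]
    mean(sub[upper.tri(sub)])
  }
  clusters <- list()
  descend <- function(node) {
    idx <- if (node < 0) -node else node_members[[node]]
    if (length(idx) == 1 || mean_r(idx) >= r_threshold) {
      clusters[[length(clusters) + 1]] <<- idx
    } else {
      descend(hc$merge[node, 1])
      descend(hc$merge[node, 2])
    }
  }
  descend(n - 1)
  # deterministic order: by smallest member index
  clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  out <- purrr::imap(clusters, function(idx, ci) {
    tibble(
      cluster_id = sprintf("c%d", ci),
      members = list(nms[idx]),
      n_members = length(idx),
      mean_internal_r = mean_r(idx),
      centroid = list(cluster_centroid(motifs[idx], R[idx, idx, drop = FALSE],
                                       min_overlap = min_overlap))
    )
  }) |> bind_rows()
  class(out) <- c("motif_clusters", class(out))
  out
}

# centroid: align all members to the medoid and average probabilities
cluster_centroid <- function(motifs, R, min_overlap = 4) {
  if (length(motifs) == 1) return(motifs[[1]])
  medoid <- which.max(rowSums(R))
  ref <- motifs[[medoid]]
  placed <- purrr::map(motifs, function(m) {
    al <- align_pwms(ref, m, min_overlap = min_overlap)
    mm <- if (al$orientation == "R") pwm_revcomp(m) else m
    list(offset = al$offset, matrix = mm$matrix)
  })
  lo <- min(vapply(placed, function(p) p$offset, numeric(1)))
  hi <- max(vapply(placed, function(p) p$offset + nrow(p$matrix), numeric(1)))
  width <- hi - lo
  acc <- matrix(0, width, 4); cnt <- numeric(width)
  for (p in placed) {
    rows <- (p$offset - lo + 1):(p$offset - lo + nrow(p$matrix))
    acc[rows, ] <- acc[rows, ] + p$matrix
    cnt[rows] <- cnt[rows] + 1
  }
  pwm(acc / cnt, name = paste0(ref$name, "_centroid"), tf_id = ref$tf_id,
      source = ref$source, evidence = ref$evidence)
}

#' Rule-based curation of a TF's candidate motifs
#'
#' Deterministic cascade choosing representative motif(s) for one TF:
#' (1) experimental evidence beats inferred; (2) in-vitro assays beat
#' in-vivo; (3) method rank PBM > B1H > SELEX (then databases/predictions);
#' (4) prefer candidates in the cluster holding the majority of the TF's
#' motifs; (5) prefer candidates with positive enrichment support, when
#' supplied. Multiple motifs are returned only when the surviving candidates
#' fall in different clusters, reflecting distinct binding modes (e.g.
#' monomer and dimer forms). The decision trace is attached as attribute
#' `"trace"`.
#'
#' @param candidates List of [pwm()]s for one TF (source/evidence metadata on
#'   the motifs drives rules 1-3).
#' @param clusters Optional `motif_clusters` over the candidates (from
#'   [cluster_pwms()]); enables rules 4 and the multi-mode emission.
#' @param support Optional logical vector, one per candidate: positive
#'   enrichment support in independent data.
#' @return List of selected `pwm`s (>= 1), with a character `"trace"`
#'   attribute describing each applied rule.
#' @export
curate_motifs <- function(candidates, clusters = NULL, support = NULL) {
  if (length(candidates) == 0) abort("no candidate motifs to curate")
  nms <- make.unique(vapply(candidates, function(m) m$name, character(1)))
  meta <- tibble(
    idx = seq_along(candidates),
    name = nms,
    evidence = vapply(candidates, function(m) m$evidence, character(1)),
    source = vapply(candidates, function(m) m$source, character(1))
  ) |>
    mutate(
      ev_rank = ifelse(.data$evidence == "experimental", 0L, 1L),
      vitro_rank = dplyr::case_when(
        .data$source %in% c("PBM", "B1H", "SELEX") ~ 0L,
        .data$source %in% c("ChIP-seq", "ChIP-chip") ~ 1L,
        TRUE ~ 2L
      ),
      method_rank = dplyr::recode(.data$source, PBM = 1L, B1H = 2L,
                                  SELEX = 3L, .default = 4L)
    )
  if (!is.null(clusters)) {
    memb <- setNames(
      rep(clusters$cluster_id, clusters$n_members),
      unlist(clusters$members)
    )
    meta$cluster <- unname(memb[meta$name])
    counts <- sort(table(meta$cluster), decreasing = TRUE)
    # a strict majority cluster is preferred; ties give no preference
    if (length(counts) > 1 && counts[1] == counts[2]) {
      meta$cluster_rank <- 0L
    } else {
      majority <- names(counts)[1]
      meta$cluster_rank <- ifelse(!is.na(meta$cluster) &
                                    meta$cluster == majority, 0L, 1L)
    }
  } else {
    meta$cluster <- NA_character_
    meta$cluster_rank <- 0L
  }
  meta$support_rank <- if (!is.null(support)) ifelse(support, 0L, 1L) else 0L
  trace <- character()
  step <- function(df, col, label) {
    kept <- df[df[[col]] == min(df[[col]]), , drop = FALSE]
    if (nrow(kept) < nrow(df)) {
      trace <<- c(trace, sprintf("%s: %d -> %d candidates", label,
                                 nrow(df), nrow(kept)))
    }
    kept
  }
  surv <- meta
  surv <- step(surv, "ev_rank", "experimental over inferred")
  surv <- step(surv, "vitro_rank", "in vitro over in vivo")
  surv <- step(surv, "method_rank", "method rank PBM > B1H > SELEX")
  surv <- step(surv, "cluster_rank", "majority cluster preferred")
  surv <- step(surv, "support_rank", "enrichment support preferred")
  surv <- arrange(surv, .data$method_rank, .data$name)
  if (!is.null(clusters) && length(unique(stats::na.omit(surv$cluster))) > 1) {
    picks <- surv |> group_by(.data$cluster) |> slice(1) |> ungroup()
    trace <- c(trace, sprintf(
      "survivors span %d clusters: emitting one motif per cluster (multiple binding modes)",
      nrow(picks)))
  } else {
    picks <- surv[1, , drop = FALSE]
    trace <- c(trace, sprintf("selected %s", picks$name[1]))
  }
  out <- candidates[picks$idx]
  attr(out, "trace") <- trace
  out
}
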