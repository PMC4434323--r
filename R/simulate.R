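#' Simulate PBM probe intensities for a design
#'
#' Forward model used to exercise the scoring pipeline: each probe's intensity
#' is `baseline * (1 + affinity_scale * occupancy) * spatial_bias * noise`,
#' where occupancy is the Boltzmann occupancy of the truth PWM summed over
#' both strands and all probe offsets (the same energy model used by
#' [energy_score_probes()]), the spatial bias is a smooth planar gradient of
#' peak relative amplitude `spatial_amplitude` across the grid, and noise is
#' multiplicative lognormal with log-sd `noise_sd`. QC flags are copied from
#' the design.
#'
#' @param design An `array_design` from [generate_design()].
#' @param truth_pwm The planted binding model (a [pwm()]).
#' @param affinity_scale Signal amplitude; 0 gives pure noise. Default 20
#'   emulates a strong, clearly successful PBM experiment.
#' @param noise_sd Log-intensity noise sd. Default 0.1 (~10% CV), typical of
#'   replicate array spots.
#' @param spatial_amplitude Peak relative amplitude of the planar bias field;
#'   1 yields a 2x corner-to-corner gradient, 0 disables it.
#' @param baseline Baseline intensity units.
#' @param seed Optional integer seed.
#' @return A `pbm_experiment` tibble (probe_id, row, col, sequence, intensity,
#'   flag) with attributes `design_id` and `detrended = FALSE`.
#' @export
simulate_intensities <- function(design, truth_pwm, affinity_scale = 20,
                                 noise_sd = 0.1, spatial_amplitude = 0,
                                 baseline = 1000, seed = NULL) {
  stopifnot(affinity_scale >= 0, noise_sd >= 0, spatial_amplitude >= 0)
  with_seed_if(seed, {
    occ <- if (affinity_scale > 0) {
      energy_score_probes(truth_pwm, design$sequence)
    } else {
      numeric(nrow(design))
    }
    rf <- (design$row - 1) / max(1, max(design$row) - 1)
    cf <- (design$col - 1) / max(1, max(design$col) - 1)
    bias <- 1 + spatial_amplitude * (rf + cf) / 2
    noise <- exp(rnorm(nrow(design), 0, noise_sd))
    out <- tibble(
      probe_id = design$probe_id, row = design$row, col = design$col,
      sequence = design$sequence,
      intensity = baseline * (1 + affinity_scale * occ) * bias * noise,
      flag = design$flag
    )
    new_pbm_experiment(out, design_id = attr(design, "design_id") %||% "sim",
                       detrended = FALSE)
  })
}

new_pbm_experiment <- function(x, design_id, detrended) {
  attr(x, "design_id") <- design_id
  attr(x, "detrended") <- detrended
  class(x) <- unique(c("pbm_experiment", class(x)))
  x
}

is_detrended <- function(exp) isTRUE(attr(exp, "detrended"))

#' Sample sequences from a first-order Markov (dinucleotide) model
#'
#' @param n Number of sequences.
#' @param length Length of each sequence.
#' @param trans 4x4 transition matrix (rows = previous base, A C G T order),
#'   rows summing to 1. `NULL` means uniform i.i.d. bases.
#' @param seed Optional integer seed.
#' @return Character vector of `n` sequences.
#' @export
sample_background <- function(n, length, trans = NULL, seed = NULL) {
  if (is.null(trans)) trans <- matrix(0.25, 4, 4)
  trans <- as.matrix(trans) / rowSums(trans)
  cum <- t(apply(trans, 1, cumsum))
  with_seed_if(seed, {
    m <- matrix(0L, nrow = n, ncol = length)
    m[, 1] <- sample.int(4, n, replace = TRUE)
    if (length > 1) {
      for (j in 2:length) {
        u <- runif(n)
        m[, j] <- 1L + rowSums(u > cum[m[, j - 1], , drop = FALSE])
      }
    }
    apply(m, 1, function(r) paste(DNA_BASES[r], collapse = ""))
  })
}

# assemble the two motif instances into one cassette string.
# arrangement encodes (upstream, downstream) identity and orientation of the
# ChIPed motif (1) and partner (2); negative spacing overlaps the instances
# with the downstream instance's bases taking precedence.
build_cassette <- function(s1, s2, arrangement, spacing, spacer = "") {
  pieces <- switch(arrangement,
    "1F2F" = c(s1, s2),
    "1F2R" = c(s1, revcomp(s2)),
    "2R1F" = c(revcomp(s2), s1),
    "2F1F" = c(s2, s1),
    abort(sprintf("unknown arrangement '%s'", arrangement))
  )
  if (spacing >= 0) {
    if (nchar(spacer) != spacing) abort("spacer length must equal spacing")
    paste0(pieces[1], spacer, pieces[2])
  } else {
    keep <- nchar(pieces[1]) + spacing
    if (keep < 0) abort("overlap exceeds upstream instance length")
    paste0(substr(pieces[1], 1, keep), pieces[2])
  }
}

#' Generate peak sets with planted composite motifs
#'
#' A fraction of peaks carries one embedded composite cassette: an instance
#' sampled from each PWM, arranged and spaced per the requested stereospecific
#' configuration (`1F2F`, `1F2R`, `2R1F` or `2F1F`; spacing -5..+10, negative
#' meaning overlap with the downstream instance's bases winning). The cassette
#' is embedded at a uniform position and on a uniform strand; all remaining
#' sequence is drawn from a first-order Markov dinucleotide model.
#'
#' @param motif1,motif2 The two planted [pwm()]s (motif1 plays the ChIPed TF).
#' @param arrangement One of `"1F2F"`, `"1F2R"`, `"2R1F"`, `"2F1F"`.
#' @param spacing Integer in -5..+10 (bases between the instances; negative
#'   overlaps them).
#' @param planted_fraction Fraction of peaks carrying the cassette.
#' @param n_peaks,peak_length Peak set geometry. Defaults mirror a top-250
#'   ChIP-seq peak analysis.
#' @param dinuc_model Optional 4x4 transition matrix for the background.
#' @param seed Optional integer seed.
#' @return A `peak_set` tibble (peak_id, sequence) with attribute
#'   `experiment_id`.
#' @export
plant_composite_peaks <- function(motif1, motif2, arrangement = "1F2F",
                                  spacing = 3, planted_fraction = 0.5,
                                  n_peaks = 250, peak_length = 150,
                                  dinuc_model = NULL, seed = NULL) {
  stopifnot(planted_fraction >= 0, planted_fraction <= 1)
  if (spacing < -5 || spacing > 10) abort("spacing must be in [-5, 10]")
  foot <- pwm_length(motif1) + pwm_length(motif2) + spacing
  if (foot > peak_length) abort("cassette longer than peak_length")
  with_seed_if(seed, {
    seqs <- sample_background(n_peaks, peak_length, trans = dinuc_model)
    n_plant <- round(planted_fraction * n_peaks)
    if (n_plant > 0) {
      planted <- sample.int(n_peaks, n_plant)
      for (i in planted) {
        s1 <- pwm_sample(motif1)
        s2 <- pwm_sample(motif2)
        spacer <- if (spacing > 0)
          sample_background(1, spacing, trans = dinuc_model) else ""
        cas <- build_cassette(s1, s2, arrangement, spacing, spacer)
        if (runif(1) < 0.5) cas <- revcomp(cas)
        pos <- sample.int(peak_length - nchar(cas) + 1, 1)
        substr(seqs[i], pos, pos + nchar(cas) - 1) <- cas
      }
    }
    out <- tibble(peak_id = sprintf("peak_%04d", seq_len(n_peaks)),
                  sequence = seqs)
    attr(out, "experiment_id") <- "synthetic"
    class(out) <- c("peak_set", class(out))
    out
  })
}

#' Generate a yeast one-hybrid style bait dataset
#'
#' Positives carry planted motif instances within the promoter-proximal first
#' 500 bases (where the downstream affinity scoring looks); negatives are
#' background only. Default bait length is 2 kb, matching typical cloned
#' promoter baits.
#'
#' @param pwm Planting motif.
#' @param n_pos,n_neg Numbers of positive / negative baits.
#' @param bait_length Bait length in bases.
#' @param sites_per_positive Motif instances planted per positive bait.
#' @param dinuc_model Optional 4x4 background transition matrix.
#' @param seed Optional integer seed.
#' @return List with tibbles `positives` and `negatives` (name, sequence).
#' @export
generate_y1h_dataset <- function(pwm, n_pos, n_neg, bait_length = 2000,
                                 sites_per_positive = 2, dinuc_model = NULL,
                                 seed = NULL) {
  with_seed_if(seed, {
    w <- pwm_length(pwm)
    proximal <- min(500, bait_length)
    pos <- sample_background(n_pos, bait_length, trans = dinuc_model)
    for (i in seq_len(n_pos)) {
      for (s in seq_len(sites_per_positive)) {
        inst <- pwm_sample(pwm)
        if (runif(1) < 0.5) inst <- revcomp(inst)
        at <- sample.int(proximal - w + 1, 1)
        substr(pos[i], at, at + w - 1) <- inst
      }
    }
    neg <- sample_background(n_neg, bait_length, trans = dinuc_model)
    list(
      positives = tibble(name = sprintf("pos_%03d", seq_len(n_pos)),
                         sequence = pos),
      negatives = tibble(name = sprintf("neg_%03d", seq_len(n_neg)),
                         sequence = neg)
    )
  })
}

#' Generate promoter collections with planted gene-set structure
#'
#' Emits one 601-base promoter per gene (representing -500..+100 around a
#' nominal TSS) and a gene-set table containing one focal set plus optional
#' random null sets. Genes in the focal set carry a planted motif instance at
#' rate `planted_fraction_in_set`; all other sequence is background.
#'
#' @param pwm Planting motif.
#' @param n_genes Universe size.
#' @param set_fraction Fraction of the universe in the focal set.
#' @param planted_fraction_in_set Planting rate within the focal set.
#' @param n_null_sets Additional random gene sets of the same size.
#' @param dinuc_model Optional 4x4 background transition matrix.
#' @param seed Optional integer seed.
#' @return List with `promoters` (tibble gene, sequence) and `genesets`
#'   (tibble set_id, gene_id; focal set is `"focal"`).
#' @export
generate_promoter_genesets <- function(pwm, n_genes = 200, set_fraction = 0.2,
                                       planted_fraction_in_set = 0.8,
                                       n_null_sets = 4, dinuc_model = NULL,
                                       seed = NULL) {
  stopifnot(set_fraction > 0, set_fraction <= 1)
  with_seed_if(seed, {
    len <- 601L
    w <- pwm_length(pwm)
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    seqs <- sample_background(n_genes, len, trans = dinuc_model)
    n_set <- max(1, round(set_fraction * n_genes))
    focal <- sample(genes, n_set)
    planted <- sample(focal, round(planted_fraction_in_set * n_set))
    for (g in planted) {
      i <- match(g, genes)
      inst <- pwm_sample(pwm)
      if (runif(1) < 0.5) inst <- revcomp(inst)
      at <- sample.int(len - w + 1, 1)
      substr(seqs[i], at, at + w - 1) <- inst
    }
    sets <- tibble(set_id = "focal", gene_id = focal)
    if (n_null_sets > 0) {
      null_sets <- purrr::map_dfr(seq_len(n_null_sets), function(k) {
        tibble(set_id = sprintf("null_%02d", k),
               gene_id = sample(genes, n_set))
      })
      sets <- bind_rows(sets, null_sets)
    }
    list(promoters = tibble(gene = genes, sequence = seqs), genesets = sets)
  })
}
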