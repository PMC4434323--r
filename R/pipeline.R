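#' Pipeline run configuration
#'
#' Collects every tunable constant of the analysis chain under documented
#' names, with the standard defaults: E-score significance cutoff 0.45,
#' bright-probe Z 4, match threshold 0.50 of max score, composite-motif
#' spacing -5..+10, 10 null shuffles, 10% count filter, alpha 0.05, cluster
#' correlation cut 0.8, promoter-scan p cutoff 1e-4, promoter window
#' -500..+100, Y1H minimum positives 5 and proximal scan length 500, top-250
#' peak sets, and the per-family homology thresholds of
#' [family_thresholds()]. Override any entry by name.
#'
#' @param seed Master integer seed for the run.
#' @param ... Named overrides of the defaults.
#' @return A named list of class `pbm_config`.
#' @export
pbm_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    e_cutoff = 0.45,
    bright_z = 4,
    match_threshold_frac = 0.50,
    spacing_min = -5, spacing_max = 10,
    n_shuffles = 10,
    count_filter = 0.10,
    alpha = 0.05,
    cluster_r = 0.8,
    fimo_p_cutoff = 1e-4,
    promoter_window = c(-500, 100),
    y1h_min_positives = 5,
    y1h_scan_length = 500,
    top_peaks = 250,
    detrend_window = 7,
    pwm_top_n = 10,
    homology_thresholds = family_thresholds(),
    # synthetic study conditions
    design_order = 8, probe_length = 25,
    affinity_scale = 20, noise_sd = 0.1, spatial_amplitude = 0.5,
    n_peaks = 250, peak_length = 150, planted_fraction = 0.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- c("pbm_config", class(cfg))
  cfg
}

#' Run the synthetic end-to-end pipeline
#'
#' Orchestrates the demonstration analysis on fully synthetic data: simulate
#' a two-design PBM experiment for a random truth motif, score 8-mers, derive
#' and evaluate a PWM, scan planted composite-motif peaks, and test Y1H and
#' promoter/gene-set enrichment. Every stage draws its randomness from seeds
#' derived from `config$seed`, artifacts are written as TSV/FASTA/JSON under
#' `out_dir`, and a manifest captures the full configuration, so repeated
#' runs are byte-identical.
#'
#' @param config A [pbm_config()].
#' @param stages Subset of `c("simulate", "score", "derive", "cm", "enrich")`
#'   to execute (prerequisites are checked; a missing upstream stage is a
#'   fail-fast error naming the producing stage).
#' @param out_dir Artifact directory (created if needed).
#' @return Invisibly, a named list of stage results and artifact paths.
#' @export
run_pipeline <- function(config = pbm_config(),
                         stages = c("simulate", "score", "derive", "cm",
                                    "enrich"),
                         out_dir = tempfile("pbmotif_run_")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(out_dir = out_dir)
  seed <- as.integer(config$seed)
  truth <- random_pwm(length = 8, min_ic = 10, seed = seed + 101,
                      name = "truth_tf", tf_id = "truth_tf")
  res$truth <- truth
  if ("simulate" %in% stages) {
    designs <- generate_design(config$design_order, config$probe_length,
                               n_designs = 2, seed = seed + 1)
    res$experiments <- purrr::imap(designs, function(d, i) {
      simulate_intensities(d, truth, affinity_scale = config$affinity_scale,
                           noise_sd = config$noise_sd,
                           spatial_amplitude = config$spatial_amplitude,
                           seed = seed + 10 + i)
    })
    for (i in seq_along(res$experiments)) {
      write_array_tsv(res$experiments[[i]],
                      file.path(out_dir, sprintf("array_%d.tsv", i)))
    }
    write_meme(truth, file.path(out_dir, "truth_motif.meme"))
  }
  if ("score" %in% stages) {
    if (is.null(res$experiments)) {
      abort("score stage requires experiments; run the simulate stage first")
    }
    res$tables <- purrr::map(res$experiments, function(e) {
      e |> filter_probes() |>
        spatial_detrend(window = config$detrend_window) |>
        kmer_score_table()
    })
    readr::write_tsv(res$tables[[1]], file.path(out_dir, "kmer_table_1.tsv"))
    readr::write_tsv(res$tables[[2]], file.path(out_dir, "kmer_table_2.tsv"))
  }
  if ("derive" %in% stages) {
    if (is.null(res$tables)) {
      abort("derive stage requires k-mer tables; run the score stage first")
    }
    res$pwms <- purrr::imap(res$tables, function(tb, i) {
      derive_pwm_align(tb, top_n = config$pwm_top_n,
                       name = sprintf("derived_%d", i), tf_id = "truth_tf")
    })
    heldout <- spatial_detrend(filter_probes(res$experiments[[2]]),
                               window = config$detrend_window)
    res$evaluation <- bind_rows(
      purrr::map(res$pwms, evaluate_pwm, heldout = heldout)
    )
    res$best_pwm <- select_best_pwm(res$pwms, res$evaluation)
    res$success <- assess_success(res$tables[[1]], res$tables[[2]],
                                  res$pwms[[1]], res$pwms[[2]],
                                  tf_id = "truth_tf",
                                  e_cutoff = config$e_cutoff)
    write_meme(res$pwms, file.path(out_dir, "derived_motifs.meme"))
    readr::write_tsv(res$evaluation, file.path(out_dir, "pwm_evaluation.tsv"))
  }
  if ("cm" %in% stages) {
    if (is.null(res$best_pwm)) {
      abort("cm stage requires a derived PWM; run the derive stage first")
    }
    partner <- random_pwm(length = 8, min_ic = 10, seed = seed + 202,
                          name = "partner_tf", tf_id = "partner_tf")
    peaks <- plant_composite_peaks(
      res$best_pwm, partner, arrangement = "1F2F", spacing = 3,
      planted_fraction = config$planted_fraction, n_peaks = config$n_peaks,
      peak_length = config$peak_length, seed = seed + 21)
    res$cm <- cm_scan(peaks, res$best_pwm, partner,
                      n_shuffles = config$n_shuffles, seed = seed + 22,
                      threshold_frac = config$match_threshold_frac,
                      count_filter = config$count_filter,
                      alpha = config$alpha)
    write_fasta(peaks, file.path(out_dir, "peaks.fasta"))
    readr::write_tsv(res$cm, file.path(out_dir, "cm_patterns.tsv"))
  }
  if ("enrich" %in% stages) {
    if (is.null(res$best_pwm)) {
      abort("enrich stage requires a derived PWM; run the derive stage first")
    }
    y1h <- generate_y1h_dataset(res$best_pwm, n_pos = 12, n_neg = 40,
                                seed = seed + 31)
    res$y1h <- y1h_mann_whitney(res$best_pwm, y1h$positives, y1h$negatives,
                                min_positives = config$y1h_min_positives,
                                scan_length = config$y1h_scan_length)
    promo <- generate_promoter_genesets(res$best_pwm, seed = seed + 32)
    res$genesets <- enrich_genesets(
      list(best = res$best_pwm), promo$promoters, promo$genesets,
      p_cutoff = config$fimo_p_cutoff)
    write_fasta(y1h$positives, file.path(out_dir, "y1h_positives.fasta"))
    write_fasta(y1h$negatives, file.path(out_dir, "y1h_negatives.fasta"))
    readr::write_tsv(res$genesets, file.path(out_dir, "geneset_enrichment.tsv"))
  }
  write_manifest(file.path(out_dir, "manifest.json"),
                 params = c(unclass(config)[
                   !vapply(unclass(config), is.function, logical(1))],
                   list(stages = stages)))
  invisible(res)
}
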