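# Independent oracles used across the suite. These deliberately take the
# slow, literal route (string matching, exhaustive enumeration) so they stay
# independent of the package's vectorised implementations.

DNA <- c("A", "C", "G", "T")

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# naive Berger-convention E-score for one canonical k-mer over a probe table
oracle_escore <- function(seqs, intensities, kmer) {
  rc <- oracle_revcomp(kmer)
  fg <- which(grepl(kmer, seqs, fixed = TRUE) | grepl(rc, seqs, fixed = TRUE))
  if (length(fg) == 0) return(NA_real_)
  bg <- setdiff(seq_along(seqs), fg)
  ord <- order(-intensities)  # stable: ties broken by probe order
  pos <- match(seq_along(seqs), ord)
  fg_pos <- sort(pos[fg])[seq_len(ceiling(length(fg) / 2))]
  bg_pos <- sort(pos[bg])[seq_len(ceiling(length(bg) / 2))]
  wins <- 0
  for (a in fg_pos) for (b in bg_pos) wins <- wins + (a < b)
  wins / (length(fg_pos) * length(bg_pos)) - 0.5
}

# all k-mers of a string (forward strand), by brute substring extraction
oracle_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  vapply(seq_len(n - k + 1), function(i) substr(s, i, i + k - 1), character(1))
}

# exhaustive occupancy: sum over both strands and all offsets of the logistic
# Boltzmann weight
oracle_occupancy <- function(pwm_obj, probe, pc = 0.01, mu = 0) {
  m <- pwm_matrix(pwm_obj)
  w <- nrow(m)
  eps <- -log(m + pc) + log(apply(m, 1, max) + pc)
  total <- 0
  for (s in c(probe, oracle_revcomp(probe))) {
    chars <- strsplit(s, "")[[1]]
    for (o in seq_len(nchar(s) - w + 1)) {
      e <- 0
      for (j in seq_len(w)) e <- e + unname(eps[j, match(chars[o + j - 1], DNA)])
      total <- total + 1 / (1 + exp(e - mu))
    }
  }
  total
}

# 16-bin dinucleotide count vector
dinuc_counts <- function(s) {
  n <- nchar(s)
  di <- substring(s, seq_len(n - 1), 2:n)
  table(factor(di, levels = as.vector(outer(DNA, DNA, paste0))))
}

# a sharp, fixed-consensus motif pair used by composite tests
cm_motif_pair <- function() {
  list(m1 = word_pwm("TGATTCAG", name = "chiped"),
       m2 = word_pwm("CCAGTGGA", name = "partner"))
}

# small detrended experiment with strong planted signal (order-8 design,
# scored at k = 6 so each word is covered by ~32 probes)
strong_signal_fixture <- function(seed = 7) {
  truth <- random_pwm(6, min_ic = 8, seed = seed + 1000, name = "truth",
                      tf_id = "truth")
  designs <- generate_design(8, 23, n_designs = 2, seed = seed)
  exps <- lapply(seq_along(designs), function(i) {
    spatial_detrend(simulate_intensities(designs[[i]], truth,
                                         seed = seed + i))
  })
  list(truth = truth, designs = designs, exps = exps)
}
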