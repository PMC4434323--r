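#' Position weight matrices
#'
#' A `pwm` is a light S3 object holding a positions-by-4 probability matrix
#' (columns `A`, `C`, `G`, `T`) plus provenance metadata. "Motif" throughout
#' this package always means a PWM. Provenance distinguishes the assay the
#' matrix came from (`source`) from whether it was measured for this TF or
#' transferred by homology (`evidence`); both drive the curation rules in
#' [curate_motifs()].
#'
#' @param matrix Numeric matrix, one row per motif position, columns in
#'   A, C, G, T order. Rows are normalised to sum to one.
#' @param name Motif label.
#' @param tf_id Transcription-factor identifier the motif belongs to.
#' @param source Assay or database of origin: one of `"PBM"`, `"ChIP-seq"`,
#'   `"ChIP-chip"`, `"B1H"`, `"SELEX"`, `"Transfac"`, `"predicted"`.
#' @param evidence `"experimental"` (measured for this TF) or `"inferred"`
#'   (transferred by homology).
#' @param notes Free-text annotation.
#'
#' @return An object of class `pwm`.
#' @examples
#' m <- pwm(rbind(c(.97, .01, .01, .01), c(.01, .01, .97, .01)), name = "AG")
#' consensus(m)
#' @export
pwm <- function(matrix, name = "motif", tf_id = name, source = "PBM",
                evidence = "experimental", notes = "") {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) abort("PWM matrix must have 4 columns (A, C, G, T)")
  if (any(matrix < 0) || any(!is.finite(matrix))) {
    abort("PWM entries must be finite and non-negative")
  }
  rs <- rowSums(matrix)
  if (any(rs <= 0)) abort("every PWM position needs positive total mass")
  matrix <- matrix / rs
  colnames(matrix) <- DNA_BASES
  rownames(matrix) <- NULL
  source <- match.arg(source, c("PBM", "ChIP-seq", "ChIP-chip", "B1H",
                                "SELEX", "Transfac", "predicted"))
  evidence <- match.arg(evidence, c("experimental", "inferred"))
  structure(
    list(matrix = matrix, name = name, tf_id = tf_id, source = source,
         evidence = evidence, notes = notes),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (tf %s, %s/%s), %d positions, consensus %s\n",
              x$name, x$tf_id, x$source, x$evidence,
              pwm_length(x), consensus(x)))
  invisible(x)
}

#' @rdname pwm
#' @param x A `pwm`.
#' @export
pwm_length <- function(x) nrow(x$matrix)

#' @rdname pwm
#' @export
pwm_matrix <- function(x) x$matrix

#' Reverse complement of a PWM
#'
#' Reverses the positions and complements the bases (A<->T, C<->G).
#'
#' @param x A `pwm`.
#' @return A `pwm` modelling the motif on the opposite strand.
#' @export
pwm_revcomp <- function(x) {
  m <- x$matrix[rev(seq_len(nrow(x$matrix))), c(4, 3, 2, 1), drop = FALSE]
  colnames(m) <- DNA_BASES
  out <- x
  out$matrix <- m
  out
}

#' Per-position information content
#'
#' IC of a column is `2 + sum(p * log2(p))` bits, i.e. 2 bits for a
#' deterministic position and 0 for a uniform one.
#'
#' @param x A `pwm`.
#' @return Numeric vector of length `pwm_length(x)`, in bits.
#' @export
pwm_ic <- function(x) {
  p <- x$matrix
  lp <- ifelse(p > 0, log2(p), 0)
  2 + rowSums(p * lp)
}

#' @rdname pwm
#' @export
consensus <- function(x) {
  paste(DNA_BASES[max.col(x$matrix, ties.method = "first")], collapse = "")
}

#' Sample a sequence from a PWM
#'
#' Draws one base per position from the position's probability vector.
#' Used by the synthetic-data generators when planting motif instances.
#'
#' @param x A `pwm`.
#' @param seed Optional integer seed.
#' @return A character scalar of length `pwm_length(x)`.
#' @export
pwm_sample <- function(x, seed = NULL) {
  with_seed_if(seed, {
    idx <- apply(x$matrix, 1, function(p) sample.int(4, 1, prob = p))
    paste(DNA_BASES[idx], collapse = "")
  })
}

#' Random PWM generator
#'
#' Generates a motif with controllable sharpness by drawing each column from
#' a Dirichlet centred on a random dominant base. With `concentration` well
#' below 1 the columns are near-deterministic (high information content).
#'
#' @param length Number of positions.
#' @param concentration Dirichlet spread; smaller is sharper. Default 0.3
#'   yields mostly 1-2 plausible bases per position, like typical PBM motifs.
#' @param min_ic Minimum total information content (bits); redrawn until met.
#' @param seed Optional integer seed.
#' @param name,tf_id Labels passed to [pwm()].
#' @return A `pwm`.
#' @export
random_pwm <- function(length = 8, concentration = 0.3, min_ic = 0,
                       seed = NULL, name = "random", tf_id = name) {
  with_seed_if(seed, {
    repeat {
      m <- t(vapply(seq_len(length), function(i) {
        g <- stats::rgamma(4, shape = concentration)
        g[sample.int(4, 1)] <- stats::rgamma(1, shape = 4)
        g / sum(g)
      }, numeric(4)))
      cand <- pwm(m, name = name, tf_id = tf_id)
      if (sum(pwm_ic(cand)) >= min_ic) return(cand)
    }
  })
}

#' Indicator PWM for a fixed word
#'
#' @param word DNA string.
#' @param eps Probability mass left on the three non-consensus bases.
#' @param ... Passed to [pwm()].
#' @return A `pwm` whose consensus is `word`.
#' @export
word_pwm <- function(word, eps = 0.003, ...) {
  idx <- .base_lookup[utf8ToInt(word)]
  if (any(idx > 4)) abort("word must be over ACGT")
  m <- matrix(eps, nrow = nchar(word), ncol = 4)
  m[cbind(seq_along(idx), idx)] <- 1 - 3 * eps
  pwm(m, ...)
}

#' @export
tidy.pwm <- function(x, ...) {
  as_tibble(x$matrix) |>
    mutate(position = dplyr::row_number(), .before = 1) |>
    pivot_longer(-"position", names_to = "base", values_to = "prob")
}

#' @export
glance.pwm <- function(x, ...) {
  tibble(
    name = x$name, tf_id = x$tf_id, source = x$source, evidence = x$evidence,
    length = pwm_length(x), total_ic = sum(pwm_ic(x)), consensus = consensus(x)
  )
}

#' Read and write motifs in MEME minimal format
#'
#' The writer records `source`/`evidence` provenance on the `MOTIF` header
#' comment line; the reader restores it when present. Background letter
#' frequencies are written as uniform 0.25.
#'
#' @param pwms A `pwm` or list of `pwm`s.
#' @param path File path.
#' @param nsites Value recorded in the `letter-probability matrix` header.
#' @return `write_meme` returns `path` invisibly; `read_meme` returns a list
#'   of `pwm`s.
#' @export
write_meme <- function(pwms, path, nsites = 10) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25000 C 0.25000 G 0.25000 T 0.25000", ""
  )
  for (p in pwms) {
    lines <- c(
      lines,
      sprintf("MOTIF %s %s", p$name, p$tf_id),
      sprintf("# source=%s evidence=%s", p$source, p$evidence),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
              pwm_length(p), nsites),
      apply(p$matrix, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
      ""
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    hdr <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]]
    name <- hdr[2]
    tf_id <- if (length(hdr) >= 3) hdr[3] else name
    source <- "PBM"; evidence <- "experimental"
    j <- starts[i] + 1
    while (j <= length(lines) && !grepl("^letter-probability", lines[j])) {
      meta <- regmatches(lines[j],
                         regexec("source=(\\S+) evidence=(\\S+)", lines[j]))[[1]]
      if (length(meta) == 3) { source <- meta[2]; evidence <- meta[3] }
      j <- j + 1
    }
    if (j > length(lines)) abort("malformed MEME file: missing matrix header")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1):(j + w)]
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    out[[i]] <- pwm(m, name = name, tf_id = tf_id, source = source,
                    evidence = evidence)
  }
  out
}
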