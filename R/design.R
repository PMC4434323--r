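#' Generate complete-coverage k-mer array designs
#'
#' Builds universal PBM-style array designs: each design's probe cores are a
#' randomized de Bruijn cycle of the requested order chopped into probes that
#' overlap by `order - 1` bases, so every `order`-mer over ACGT appears
#' exactly once (single strand) across the design and no word is lost at probe
#' junctions. Consequently every k-mer with k <= order appears exactly
#' `4^(order - k)` times per strand; in an order-10 design a non-palindromic
#' 8-mer therefore occurs 32 times counting both strands, and a palindromic
#' 8-mer 16 times. Each design uses an independently randomized Euler cycle,
#' and grid coordinates are assigned row-major on a near-square grid.
#'
#' @param order de Bruijn order m (2..10). Every m-mer appears once per design.
#' @param probe_length Length of each probe. `probe_length - (order - 1)` must
#'   divide `4^order`.
#' @param n_designs Number of independent designs (e.g. 2 for an ME/HK pair).
#' @param seed Integer seed; designs are reproducible given the seed.
#' @return A list of `array_design` tibbles (columns `probe_id`, `row`, `col`,
#'   `sequence`, `flag`), each carrying attributes `design_id`, `order`,
#'   `probe_length` and `cycle` (the underlying de Bruijn cycle string).
#' @examples
#' d <- generate_design(order = 3, probe_length = 10, n_designs = 1, seed = 1)[[1]]
#' count_kmer_occurrences(d, "ACG", both_strands = FALSE)
#' @export
generate_design <- function(order, probe_length, n_designs = 2, seed = NULL) {
  order <- as.integer(order)
  if (order < 2 || order > 10) abort("order must be between 2 and 10")
  if (probe_length <= order) abort("probe_length must exceed order")
  step <- probe_length - (order - 1L)
  n_kmers <- 4^order
  if (n_kmers %% step != 0) {
    abort(sprintf(
      "probe_length - (order - 1) = %d must divide the cycle length 4^%d = %d",
      step, order, n_kmers))
  }
  with_seed_if(seed, {
    labels <- if (n_designs <= 2) c("ME", "HK")[seq_len(n_designs)] else
      paste0("D", seq_len(n_designs))
    lapply(seq_len(n_designs), function(i) {
      cycle <- debruijn_cycle(order)
      chop_design(cycle, order, probe_length, design_id = labels[i])
    })
  })
}

# randomized de Bruijn cycle over ACGT via a random Euler circuit of the
# (order-1)-mer transition graph (iterative Hierholzer, randomized edge order)
debruijn_cycle <- function(order) {
  if (order == 1) return(paste(sample(DNA_BASES), collapse = ""))
  n_nodes <- as.integer(4^(order - 1))
  n_edges <- as.integer(4^order)
  # per-node random order over the 4 outgoing symbols
  r <- matrix(runif(4 * n_nodes), nrow = 4)
  perms <- apply(r, 2, order)
  used <- integer(n_nodes)
  stack <- integer(n_edges + 1L)
  circuit <- integer(n_edges + 1L)
  sp <- 1L; cp <- 0L
  stack[1L] <- 1L
  base_mod <- n_nodes %/% 4L  # suffix length 4^(order-2)
  while (sp > 0L) {
    v <- stack[sp]
    if (used[v] < 4L) {
      used[v] <- used[v] + 1L
      s <- perms[used[v], v]              # symbol 1..4
      v0 <- v - 1L
      w0 <- (v0 %% base_mod) * 4L + (s - 1L)
      sp <- sp + 1L
      stack[sp] <- w0 + 1L
    } else {
      cp <- cp + 1L
      circuit[cp] <- v
      sp <- sp - 1L
    }
  }
  tour <- rev(circuit[seq_len(cp)])       # n_edges + 1 nodes, first == last
  symbols <- (tour[-1L] - 1L) %% 4L + 1L  # edge labels along the tour
  paste(DNA_BASES[symbols], collapse = "")
}

chop_design <- function(cycle, order, probe_length, design_id) {
  step <- probe_length - (order - 1L)
  n_probes <- nchar(cycle) %/% step
  ext <- paste0(cycle, substr(cycle, 1L, probe_length - 1L))  # cyclic wrap
  starts <- (seq_len(n_probes) - 1L) * step + 1L
  seqs <- substring(ext, starts, starts + probe_length - 1L)
  ncol_grid <- ceiling(sqrt(n_probes))
  idx <- seq_len(n_probes) - 1L
  out <- tibble(
    probe_id = sprintf("%s_%05d", design_id, seq_len(n_probes)),
    row = idx %/% ncol_grid + 1L,
    col = idx %% ncol_grid + 1L,
    sequence = seqs,
    flag = "ok"
  )
  attr(out, "design_id") <- design_id
  attr(out, "order") <- order
  attr(out, "probe_length") <- probe_length
  attr(out, "cycle") <- cycle
  class(out) <- c("array_design", class(out))
  out
}

#' Count occurrences of a k-mer in a complete-coverage design
#'
#' Counts double-stranded site occurrences of `kmer` over the design's probe
#' cores (equivalently, over the underlying circular de Bruijn cycle, so
#' junction overlaps are not double-counted). A double-stranded site matches
#' if the k-mer reads on either strand; for a reverse-complement-palindromic
#' k-mer both strands read the same word, so its plus-strand occurrences are
#' counted once.
#'
#' @param design An `array_design` from [generate_design()].
#' @param kmer DNA word with `nchar(kmer) <= order`.
#' @param both_strands Count sites on both strands (default) or forward only.
#' @return Integer occurrence count.
#' @export
count_kmer_occurrences <- function(design, kmer, both_strands = TRUE) {
  cycle <- attr(design, "cycle")
  if (is.null(cycle)) abort("design lacks a cycle attribute; use generate_design()")
  k <- nchar(kmer)
  circ <- paste0(cycle, substr(cycle, 1L, k - 1L))
  subj <- Biostrings::DNAString(circ)
  n <- Biostrings::countPattern(Biostrings::DNAString(kmer), subj)
  if (both_strands && !is_palindromic(kmer)) {
    n <- n + Biostrings::countPattern(Biostrings::DNAString(revcomp(kmer)), subj)
  }
  as.integer(n)
}
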