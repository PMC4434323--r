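#' Read and write array intensity tables
#'
#' Tab-separated probe tables with columns probe_id, row, col, sequence,
#' intensity, flag.
#'
#' @param exp A `pbm_experiment`.
#' @param path File path.
#' @param design_id Label restored onto the experiment when reading.
#' @param detrended Whether the stored intensities were detrended.
#' @return `write_array_tsv` returns `path` invisibly; `read_array_tsv`
#'   returns a `pbm_experiment`.
#' @export
write_array_tsv <- function(exp, path) {
  readr::write_tsv(as_tibble(exp), path)
  invisible(path)
}

#' @rdname write_array_tsv
#' @export
read_array_tsv <- function(path, design_id = "array", detrended = FALSE) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         probe_id = "c", row = "i", col = "i",
                         sequence = "c", intensity = "d", flag = "c"))
  new_pbm_experiment(x, design_id = design_id, detrended = detrended)
}

#' Read and write FASTA sequence tables
#'
#' Thin wrappers mapping between FASTA files and two-column tibbles.
#'
#' @param x Tibble whose first column is the record name and whose
#'   `sequence` column holds the sequence.
#' @param path File path.
#' @return `write_fasta` returns `path` invisibly; `read_fasta` returns a
#'   tibble (name, sequence).
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(x$sequence)
  names(set) <- x[[1]]
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  tibble(name = names(set), sequence = unname(as.character(set)))
}

#' Write a run manifest
#'
#' Records parameters, seeds and input file checksums alongside pipeline
#' outputs so a run can be reproduced.
#'
#' @param path Output JSON path.
#' @param params Named list of parameters (must be JSON-serialisable).
#' @param inputs Character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, inputs = character()) {
  manifest <- list(
    package = "pbmotif",
    version = as.character(utils::packageVersion("pbmotif")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    params = params,
    inputs = if (length(inputs)) {
      list(paths = inputs, md5 = unname(tools::md5sum(inputs)))
    } else {
      NULL
    }
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
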