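#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows bind_cols group_by
#'   summarise ungroup n distinct left_join rename relocate pull slice
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
NULL

# One-letter codes for the 20 natural amino acids, in the row order of the
# packaged scale.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Residues carrying a formal side-chain charge at physiological pH.  His is
# counted as +1, consistent with the packaged scale's charge annotation.
AA_POSITIVE <- c("R", "K", "H")
AA_NEGATIVE <- c("D", "E")

# Default hydrophilic residue set used for the hydrophilic-ratio descriptor.
# Chosen as the minimal standard set consistent with the reference peptides;
# note His and Thr are excluded (see the methods vignette).
AA_HYDROPHILIC <- c("R", "K", "D", "E", "N", "Q", "S")

# Arithmetic half-up rounding (round() in R rounds half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "pepqsar", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  path
}

read_packaged_csv <- function(file) {
  as_tibble(utils::read.csv(extdata(file), stringsAsFactors = FALSE))
}

#' Validate peptide sequences against the 20-residue alphabet
#'
#' Uppercases sequences and errors on the first character outside the
#' 20-letter amino-acid alphabet, reporting the offending character and its
#' position.
#'
#' @param sequences Character vector of one-letter peptide sequences.
#' @return The validated (uppercased) character vector, invisibly usable.
#' @export
validate_sequences <- function(sequences) {
  if (!is.character(sequences)) {
    abort("`sequences` must be a character vector.")
  }
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) {
    abort("Empty peptide sequence (length >= 1 required).")
  }
  for (i in seq_along(sequences)) {
    chars <- strsplit(sequences[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% AA_ALPHABET)
    if (length(bad)) {
      abort(sprintf(
        "Invalid residue '%s' at position %d of sequence %d ('%s').",
        chars[bad[1]], bad[1], i, sequences[[i]]
      ))
    }
  }
  sequences
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

# Append an entry to a tibble's seed audit log (attribute "seed_log").
log_seed <- function(data, operation, seed) {
  log <- attr(data, "seed_log") %||% list()
  log[[length(log) + 1L]] <- list(operation = operation, seed = seed)
  attr(data, "seed_log") <- log
  data
}

#' Retrieve the seed audit log of a peptide set
#'
#' Seeded operations ([balance_classes()], [split_peptides()],
#' [generate_corpus()]) record the seed they consumed so any derived dataset
#' can be regenerated from its provenance alone.
#'
#' @param data A peptide tibble produced by this package.
#' @return A list of `list(operation =, seed =)` records (possibly empty).
#' @export
seed_log <- function(data) attr(data, "seed_log") %||% list()
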