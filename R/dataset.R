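#' Labeled peptide set assembly
#'
#' A labeled peptide set is a tibble with columns `id`, `sequence` and
#' `label` (1 = cell-penetrating, 0 = not).  The functions here perform the
#' corpus-construction steps of the classification workflow: exact-sequence
#' deduplication, class balancing by seeded random deletion, terminal
#' truncation variants and a random train/test split.  Seeded operations
#' append to the set's audit trail (see [seed_log()]).
#'
#' @name peptide_sets
NULL

as_peptide_set <- function(data) {
  data <- as_tibble(data)
  if (!all(c("sequence", "label") %in% names(data))) {
    abort("A labeled peptide set needs `sequence` and `label` columns.")
  }
  if (!all(data$label %in% c(0, 1))) {
    abort("Labels must be binary (0 = non-CPP, 1 = CPP).")
  }
  if (!"id" %in% names(data)) data$id <- paste0("pep", seq_len(nrow(data)))
  data$sequence <- toupper(data$sequence)
  relocate(data, "id", "sequence", "label")
}

#' Remove duplicate sequences from a labeled peptide set
#'
#' Sequences are compared exactly after uppercasing.  The first occurrence of
#' each sequence is kept; when the same sequence appears with *conflicting*
#' labels, every copy is removed and the conflict is recorded (attribute
#' `"conflicts"`) — a peptide cannot be both active and inactive.
#'
#' @param data Labeled peptide tibble (`sequence`, `label`, optional `id`).
#' @return Deduplicated tibble; conflicting sequences in
#'   `attr(result, "conflicts")`.
#' @export
dedup_peptides <- function(data) {
  data <- as_peptide_set(data)
  conflict_seqs <- data |>
    distinct(.data$sequence, .data$label) |>
    dplyr::count(.data$sequence) |>
    filter(.data$n > 1) |>
    pull(.data$sequence)
  out <- data |>
    filter(!.data$sequence %in% conflict_seqs) |>
    distinct(.data$sequence, .keep_all = TRUE)
  if (length(conflict_seqs)) {
    rlang::inform(sprintf(
      "Removed %d sequence(s) with conflicting labels.", length(conflict_seqs)
    ))
  }
  attr(out, "conflicts") <- conflict_seqs
  attr(out, "seed_log") <- attr(data, "seed_log")
  out
}

#' Balance classes by random deletion from the majority class
#'
#' Down-samples the majority class uniformly at random (seeded) to the size
#' of the minority class; minority members are never touched.  This mirrors
#' the standard remedy for label imbalance in peptide activity corpora,
#' where validated inactive sequences outnumber validated active ones.
#'
#' @param data Labeled peptide tibble.
#' @param seed Integer seed controlling which majority members are deleted.
#' @return Balanced tibble (original row order preserved); the number of
#'   deletions equals the initial class-size difference.  The seed is
#'   appended to the audit trail.
#' @export
balance_classes <- function(data, seed) {
  data <- as_peptide_set(data)
  n1 <- sum(data$label == 1)
  n0 <- sum(data$label == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be non-empty.")
  if (n1 == n0) return(log_seed(data, "balance_classes", seed))
  maj <- if (n0 > n1) 0 else 1
  excess <- abs(n0 - n1)
  maj_idx <- which(data$label == maj)
  drop_idx <- withr::with_seed(seed, sample(maj_idx, excess))
  out <- data[-drop_idx, ]
  log_seed(out, "balance_classes", seed)
}

#' Truncate a peptide sequence
#'
#' Terminal truncation rules used to build the six terminal-focused dataset
#' variants: `n_half` keeps the first `ceiling(N/2)` residues (odd lengths
#' give the N-terminal half the extra residue), `c_half` the remaining
#' `floor(N/2)`; `first_5`/`last_5`/`first_10`/`last_10` keep
#' `min(k, N)` residues from the respective end.
#'
#' @param sequence Character vector of sequences.
#' @param mode One of `"n_half"`, `"c_half"`, `"first_5"`, `"last_5"`,
#'   `"first_10"`, `"last_10"`.
#' @return Character vector of truncated sequences.
#' @examples
#' truncate_sequence("CRQIKIWFQNRRMKWKK", "n_half")  # first 9 residues
#' @export
truncate_sequence <- function(sequence,
                              mode = c("n_half", "c_half", "first_5",
                                       "last_5", "first_10", "last_10")) {
  mode <- match.arg(mode)
  n <- nchar(sequence)
  switch(mode,
    n_half = substr(sequence, 1L, ceiling(n / 2)),
    c_half = substr(sequence, ceiling(n / 2) + 1L, n),
    first_5 = substr(sequence, 1L, pmin(5L, n)),
    last_5 = substr(sequence, pmax(1L, n - pmin(5L, n) + 1L), n),
    first_10 = substr(sequence, 1L, pmin(10L, n)),
    last_10 = substr(sequence, pmax(1L, n - pmin(10L, n) + 1L), n)
  )
}

#' Build the six terminal-truncation dataset variants
#'
#' Applies each [truncate_sequence()] mode to every member of a labeled set,
#' preserving ids and labels, so the discriminative contribution of the
#' peptide termini can be modeled separately from the full sequences.
#'
#' @param data Labeled peptide tibble.
#' @return Named list of six tibbles (one per mode), each tagged with a
#'   `provenance` attribute naming the mode.
#' @export
truncation_datasets <- function(data) {
  data <- as_peptide_set(data)
  modes <- c("n_half", "c_half", "first_5", "last_5", "first_10", "last_10")
  out <- lapply(modes, function(m) {
    d <- mutate(data, sequence = truncate_sequence(.data$sequence, m))
    attr(d, "provenance") <- paste0("truncation:", m)
    attr(d, "seed_log") <- attr(data, "seed_log")
    d
  })
  stats::setNames(out, modes)
}

#' Random train/test split of a labeled peptide set
#'
#' Extracts a seeded uniform random fraction of the set as the test side.
#' The draw is over the whole set, not stratified by class, unless
#' `stratify = TRUE` (class proportions then preserved on both sides).
#'
#' @param data Labeled peptide tibble.
#' @param fraction Fraction assigned to the *test* side (default 0.5).
#' @param seed Integer seed.
#' @param stratify Stratify the draw by label? Default `FALSE`.
#' @return List with `train` and `test` tibbles forming a disjoint,
#'   exhaustive partition; both sides inherit the audit trail.
#' @export
split_peptides <- function(data, fraction = 0.5, seed, stratify = FALSE) {
  data <- as_peptide_set(data)
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  n <- nrow(data)
  test_idx <- withr::with_seed(seed, {
    if (stratify) {
      unlist(lapply(split(seq_len(n), data$label), function(idx) {
        sample(idx, round(length(idx) * fraction))
      }), use.names = FALSE)
    } else {
      sample(n, round(n * fraction))
    }
  })
  if (length(test_idx) == 0 || length(test_idx) == n) {
    abort("Split produced an empty side; adjust `fraction`.")
  }
  train <- log_seed(data[-sort(test_idx), ], "split_peptides", seed)
  test <- log_seed(data[sort(test_idx), ], "split_peptides", seed)
  list(train = train, test = test)
}
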