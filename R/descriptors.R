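#' Global peptide descriptors on an amino-acid z-scale
#'
#' Every peptide is encoded as the sequence of its residues' z-scores and
#' summarised by global descriptors: per-component means, helical-wheel
#' z-scale moments, absolute terminal differences, steric bulk, hydrogen-bond
#' balance, charge composition and hydrophilic ratio.  [peptide_descriptors()]
#' computes the full fixed-order descriptor table for a set of peptides; the
#' individual functions below expose each descriptor for a single sequence.
#'
#' @name descriptors
NULL

#' Encode a peptide as a sequence of z-scores
#'
#' @param sequence A single peptide sequence (one-letter codes).
#' @param scale An [aa_zscale]; defaults to the packaged scale.
#' @return A tibble with one row per residue: `pos`, `residue` and the
#'   scale's score columns.
#' @examples
#' encode_peptide("RQIKIWFQNRRMKWKK")
#' @export
encode_peptide <- function(sequence, scale = zscale()) {
  sequence <- validate_sequences(sequence)
  stopifnot(length(sequence) == 1L)
  chars <- seq_chars(sequence)
  z <- lookup_z(scale, chars)
  bind_cols(tibble(pos = seq_along(chars)), rename(z, residue = "residue"))
}

# internal: length-N x k score matrix for one sequence (no validation)
encode_matrix <- function(sequence, zmat) {
  zmat[seq_chars(sequence), , drop = FALSE]
}

#' Mean z-scores of a peptide
#'
#' Component-wise arithmetic mean of the encoded sequence.
#'
#' @inheritParams encode_peptide
#' @return Named numeric vector (`z1`, `z2`, `z3`, ...).
#' @examples
#' mean_z("RQIKIWFQNRRMKWKK")["z1"]  # 2.1898
#' @export
mean_z <- function(sequence, scale = zscale()) {
  sequence <- validate_sequences(sequence)
  colMeans(encode_matrix(sequence, zscale_matrix(scale)))
}

#' Helical-wheel z-scale moment
#'
#' Generalisation of the Eisenberg hydrophobic moment in which the selected
#' z-scale component plays the role of the hydrophilicity scale: residue n
#' contributes a vector of magnitude `H_n` at angle `n * delta`, and the
#' moment is the modulus of the vector sum,
#' \deqn{\mu = \sqrt{\left(\sum_n H_n \sin n\delta\right)^2 +
#'                  \left(\sum_n H_n \cos n\delta\right)^2}.}
#' With `delta = 100` degrees (the ideal alpha-helix twist) a large moment
#' signals amphipathicity: one helix face enriched in high-`H` residues.
#'
#' @inheritParams encode_peptide
#' @param component Which z component supplies the magnitudes (1, 2 or 3).
#' @param delta_deg Angle between successive residues, in degrees.
#' @return Non-negative scalar moment.
#' @examples
#' z_moment("RQIKIWFQNRRMKWKK", component = 2)
#' @export
z_moment <- function(sequence, scale = zscale(), component = 1,
                     delta_deg = 100) {
  sequence <- validate_sequences(sequence)
  z <- encode_matrix(sequence, zscale_matrix(scale))
  stopifnot(component >= 1, component <= ncol(z))
  h <- z[, component]
  ang <- seq_along(h) * delta_deg * pi / 180
  sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2)
}

# internal: abs difference of fragment mean z between N- and C-terminal
# fragments for one mode pair; no warnings (aggregated by caller)
terminal_diff_one <- function(sequence, zmat, n_frag, c_frag) {
  abs(colMeans(encode_matrix(n_frag, zmat)) -
      colMeans(encode_matrix(c_frag, zmat)))
}

#' Absolute terminal difference of mean z-scores
#'
#' Splits the peptide into an N-terminal and a C-terminal fragment (matching
#' the truncation rules of [truncate_sequence()]) and returns the
#' component-wise absolute difference of the fragment mean z-scores,
#' `|Nt - Ct|`.
#'
#' @inheritParams encode_peptide
#' @param mode `"halves"` (N-half vs C-half; odd lengths give the N-terminal
#'   the extra residue), `"first_last_5"` or `"first_last_10"`.
#' @return Named numeric vector of absolute differences per component.
#'   Sequences shorter than the cut use the whole sequence for both
#'   fragments (difference 0), with a warning.
#' @examples
#' terminal_difference("RRRAAA", mode = "halves")
#' @export
terminal_difference <- function(sequence, scale = zscale(),
                                mode = c("halves", "first_last_5",
                                         "first_last_10")) {
  mode <- match.arg(mode)
  sequence <- validate_sequences(sequence)
  cut <- c(halves = NA, first_last_5 = 5L, first_last_10 = 10L)[[mode]]
  if (!is.na(cut) && nchar(sequence) < cut) {
    warn(sprintf(
      "Sequence length %d < %d: whole sequence used for both terminals.",
      nchar(sequence), cut
    ))
  }
  frags <- switch(mode,
    halves = c(truncate_sequence(sequence, "n_half"),
               truncate_sequence(sequence, "c_half")),
    first_last_5 = c(truncate_sequence(sequence, "first_5"),
                     truncate_sequence(sequence, "last_5")),
    first_last_10 = c(truncate_sequence(sequence, "first_10"),
                      truncate_sequence(sequence, "last_10"))
  )
  terminal_diff_one(sequence, zscale_matrix(scale), frags[1], frags[2])
}

#' Charge composition of a peptide
#'
#' Counts Arg, His, Lys, Asp and Glu residues and derives the charge
#' descriptors: positives are \{R, K, H\} at +1, negatives \{D, E\} at -1
#' (termini are treated as capped and contribute no charge).
#'
#' @inheritParams encode_peptide
#' @return One-row tibble: `n_arg`, `n_his`, `n_lys`, `n_asp`, `n_glu`,
#'   `n_positive`, `n_negative`, `total_charge`, `mean_net_charge` and
#'   `pos_neg_ratio` (`NA` when there are no negative residues, since the
#'   ratio is then undefined).
#' @examples
#' charge_descriptors("RQIKIWFQNRRMKWKK")
#' @export
charge_descriptors <- function(sequence) {
  sequence <- validate_sequences(sequence)
  chars <- seq_chars(sequence)
  cnt <- function(res) sum(chars == res)
  n_arg <- cnt("R"); n_his <- cnt("H"); n_lys <- cnt("K")
  n_asp <- cnt("D"); n_glu <- cnt("E")
  n_pos <- n_arg + n_lys + n_his
  n_neg <- n_asp + n_glu
  tibble(
    n_arg = n_arg, n_his = n_his, n_lys = n_lys,
    n_asp = n_asp, n_glu = n_glu,
    n_positive = n_pos, n_negative = n_neg,
    total_charge = n_pos - n_neg,
    mean_net_charge = (n_pos - n_neg) / length(chars),
    pos_neg_ratio = if (n_neg == 0) NA_real_ else n_pos / n_neg
  )
}

#' Hydrophilic ratio of a peptide
#'
#' Percentage of residues belonging to a hydrophilic set, rounded half-up to
#' the nearest integer percent.  The default set \{R, K, D, E, N, Q, S\}
#' excludes His and Thr (see the methods vignette for the calibration).
#'
#' @inheritParams encode_peptide
#' @param hydrophilic_set Character vector of residues counted as
#'   hydrophilic.
#' @return Integer percentage in \[0, 100\].
#' @examples
#' hydrophilic_ratio("RQIKIWFQNRRMKWKK")  # 63
#' @export
hydrophilic_ratio <- function(sequence, hydrophilic_set = AA_HYDROPHILIC) {
  sequence <- validate_sequences(sequence)
  chars <- seq_chars(sequence)
  round_half_up(100 * sum(chars %in% hydrophilic_set) / length(chars))
}

sidechain_atoms_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_packaged_csv("sidechain_heavy_atoms.csv")
    cache
  }
})

sidechain_hbond_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_packaged_csv("sidechain_hbonds.csv")
    cache
  }
})

#' Steric bulk: mean side-chain heavy-atom count
#'
#' Mean over residues of the number of non-hydrogen atoms in the side chain
#' (packaged table; glycine counts 0, tryptophan 10).
#'
#' @inheritParams encode_peptide
#' @return Non-negative scalar.
#' @examples
#' steric_bulk("RW")  # 8.5
#' @export
steric_bulk <- function(sequence) {
  sequence <- validate_sequences(sequence)
  tab <- sidechain_atoms_table()
  counts <- tab$heavy_atoms[match(seq_chars(sequence), tab$residue)]
  mean(counts)
}

#' Mean net hydrogen-bond donation
#'
#' Mean over residues of (side-chain donor hydrogens - side-chain acceptor
#' sites), using the packaged donor/acceptor table.  Positive values indicate
#' a donor-rich sequence (e.g. Arg/Lys heavy), negative an acceptor-rich one
#' (Asp/Glu heavy).
#'
#' @inheritParams encode_peptide
#' @return Scalar mean net donation.
#' @export
net_hbond_donation <- function(sequence) {
  sequence <- validate_sequences(sequence)
  tab <- sidechain_hbond_table()
  idx <- match(seq_chars(sequence), tab$residue)
  mean(tab$donors[idx] - tab$acceptors[idx])
}

#' Full descriptor table for a set of peptides
#'
#' Computes every global descriptor in a fixed, documented column order, one
#' row per peptide.  This is the modeling matrix builder: its output feeds
#' [plsda_fit()] via [descriptor_matrix()].
#'
#' @param data A tibble/data frame with a `sequence` column (optionally `id`
#'   and `label`), or a character vector of sequences.
#' @param scale An [aa_zscale].
#' @param delta_deg Helical angle for the z-scale moments, degrees.
#' @param hydrophilic_set Residues counted by [hydrophilic_ratio()].
#' @return A tibble with identifier columns (`id`, `sequence`, and `label` if
#'   present) followed by, in fixed order: `length`; `mean_z1..z3`;
#'   `mu_z1..z3` (moments); `dhalf_z1..z3`, `d5_z1..z3`, `d10_z1..z3`
#'   (terminal differences for halves / first-last 5 / first-last 10);
#'   `steric_bulk`; `net_hbond_donation`; the charge block of
#'   [charge_descriptors()]; and `hydrophilic_ratio`.  Sequences shorter than
#'   a terminal cut contribute zero difference for that mode; one aggregate
#'   warning is emitted if any such sequence is present.
#' @examples
#' peptide_descriptors(c(Pen = "RQIKIWFQNRRMKWKK"))
#' @export
peptide_descriptors <- function(data, scale = zscale(), delta_deg = 100,
                                hydrophilic_set = AA_HYDROPHILIC) {
  if (is.character(data)) {
    ids <- names(data) %||% paste0("pep", seq_along(data))
    data <- tibble(id = ids, sequence = unname(data))
  }
  data <- as_tibble(data)
  if (!"sequence" %in% names(data)) {
    abort("`data` must contain a `sequence` column.")
  }
  if (!"id" %in% names(data)) {
    data$id <- paste0("pep", seq_len(nrow(data)))
  }
  seqs <- validate_sequences(data$sequence)
  zmat <- zscale_matrix(scale)
  k <- ncol(zmat)
  comp <- paste0("z", seq_len(k))

  n_short5 <- sum(nchar(seqs) < 5)
  n_short10 <- sum(nchar(seqs) < 10)
  if (n_short5 + n_short10 > 0) {
    warn(sprintf(
      "%d sequence(s) shorter than a terminal cut: whole sequence used for both fragments there.",
      max(n_short5, n_short10)
    ))
  }

  one <- function(s) {
    z <- encode_matrix(s, zmat)
    ang <- seq_len(nrow(z)) * delta_deg * pi / 180
    mu <- vapply(seq_len(k), function(j) {
      sqrt(sum(z[, j] * sin(ang))^2 + sum(z[, j] * cos(ang))^2)
    }, numeric(1))
    dh <- terminal_diff_one(s, zmat, truncate_sequence(s, "n_half"),
                            truncate_sequence(s, "c_half"))
    d5 <- terminal_diff_one(s, zmat, truncate_sequence(s, "first_5"),
                            truncate_sequence(s, "last_5"))
    d10 <- terminal_diff_one(s, zmat, truncate_sequence(s, "first_10"),
                             truncate_sequence(s, "last_10"))
    c(nchar(s), colMeans(z), mu, dh, d5, d10)
  }
  num <- t(vapply(seqs, one, numeric(1 + 4 * k + k), USE.NAMES = FALSE))
  colnames(num) <- c("length", paste0("mean_", comp), paste0("mu_", comp),
                     paste0("dhalf_", comp), paste0("d5_", comp),
                     paste0("d10_", comp))

  tab_atoms <- sidechain_atoms_table()
  tab_hb <- sidechain_hbond_table()
  extra <- t(vapply(seqs, function(s) {
    idx <- match(seq_chars(s), tab_atoms$residue)
    c(mean(tab_atoms$heavy_atoms[idx]),
      mean(tab_hb$donors[idx] - tab_hb$acceptors[idx]))
  }, numeric(2), USE.NAMES = FALSE))
  colnames(extra) <- c("steric_bulk", "net_hbond_donation")

  charge <- bind_rows(lapply(seqs, charge_descriptors))
  hr <- vapply(seqs, function(s) {
    chars <- seq_chars(s)
    round_half_up(100 * sum(chars %in% hydrophilic_set) / length(chars))
  }, numeric(1), USE.NAMES = FALSE)

  id_cols <- data[, intersect(c("id", "sequence", "label"), names(data))]
  out <- bind_cols(id_cols, as_tibble(num), as_tibble(extra), charge,
                   tibble(hydrophilic_ratio = hr))
  out$length <- as.integer(out$length)
  out
}

#' Extract the numeric modeling matrix from a descriptor table
#'
#' Drops identifier columns and (by default) the positive/negative charge
#' ratio, whose undefined value for anion-free peptides would otherwise
#' introduce missing values into the model.
#'
#' @param desc Output of [peptide_descriptors()].
#' @param drop Descriptor columns to exclude.
#' @return Numeric matrix, rows named by peptide id.
#' @export
descriptor_matrix <- function(desc, drop = "pos_neg_ratio") {
  keep <- setdiff(names(desc), c("id", "sequence", "label", drop))
  m <- as.matrix(desc[, keep])
  storage.mode(m) <- "double"
  if ("id" %in% names(desc)) rownames(m) <- desc$id
  m
}
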