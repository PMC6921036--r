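#' Synthetic peptide corpora and property tables
#'
#' Seeded generators producing (a) labeled peptide sets with the
#' compositional structure cell-penetrating peptides exhibit — cationic
#' (Arg/Lys-rich) and optionally amphipathic positives against
#' compositionally near-uniform negatives — and (b) low-rank-plus-noise
#' amino-acid property tables with known generating scores, so scale
#' construction, descriptor calculation, dataset assembly and classification
#' are all testable without any external corpus.
#'
#' @name synthetic_data
NULL

#' Configuration for the synthetic peptide generator
#'
#' @param n_per_class Number of peptides per class (>= 2).
#' @param length_range Two-element integer range of peptide lengths
#'   (minimum at least 5).
#' @param cationic_fraction_pos Target Arg+Lys composition fraction of the
#'   positive class.
#' @param cationic_fraction_neg Same for the negative class.
#' @param amphipathic Impose apolar residues (L/I/F/W) on one helical face
#'   of the positives, so the helical-wheel moment separates the classes?
#' @param separation Optional preset overriding the composition arguments:
#'   `"strong"` (0.35 vs 0.10, amphipathic), `"moderate"` (0.25 vs 0.10,
#'   amphipathic), `"weak"` (0.18 vs 0.10, not amphipathic) or `"null"`
#'   (identical composition, not amphipathic — classes indistinguishable by
#'   construction).
#' @param seed Integer seed; positive and negative classes consume disjoint
#'   random streams derived from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 450, length_range = c(5L, 30L),
                         cationic_fraction_pos = 0.35,
                         cationic_fraction_neg = 0.10,
                         amphipathic = TRUE, separation = NULL, seed = 1) {
  if (!is.null(separation)) {
    separation <- match.arg(separation,
                            c("strong", "moderate", "weak", "null"))
    preset <- switch(separation,
      strong = list(pos = 0.35, neg = 0.10, amph = TRUE),
      moderate = list(pos = 0.25, neg = 0.10, amph = TRUE),
      weak = list(pos = 0.18, neg = 0.10, amph = FALSE),
      null = list(pos = 0.10, neg = 0.10, amph = FALSE)
    )
    cationic_fraction_pos <- preset$pos
    cationic_fraction_neg <- preset$neg
    amphipathic <- preset$amph
  }
  if (n_per_class < 2) abort("`n_per_class` must be at least 2.")
  if (length(length_range) != 2 || length_range[1] < 5 ||
      length_range[2] < length_range[1]) {
    abort("`length_range` must be (min, max) with min >= 5.")
  }
  for (fr in c(cationic_fraction_pos, cationic_fraction_neg)) {
    if (fr < 0 || fr > 1) abort("Cationic fractions must lie in [0, 1].")
  }
  structure(list(
    n_per_class = as.integer(n_per_class),
    length_range = as.integer(length_range),
    cationic_fraction_pos = cationic_fraction_pos,
    cationic_fraction_neg = cationic_fraction_neg,
    amphipathic = isTRUE(amphipathic),
    separation = separation,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# class residue-frequency vector: `cationic` mass split 60/40 over R/K,
# remainder uniform over the other 18 residues
class_freqs <- function(cationic) {
  p <- stats::setNames(rep((1 - cationic) / 18, 20), AA_ALPHABET)
  p["R"] <- cationic * 0.6
  p["K"] <- cationic * 0.4
  p
}

APOLAR_FACE <- c("L", "I", "F", "W")

# draw one class of peptides; assumes the RNG state is already seeded
draw_class <- function(n, cfg, freqs, amphipathic) {
  lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]), n,
                 replace = TRUE)
  vapply(lens, function(len) {
    # per-peptide Dirichlet-style jitter of the class composition
    g <- stats::rgamma(20, shape = freqs * 60)
    p <- g / sum(g)
    chars <- sample(AA_ALPHABET, len, replace = TRUE, prob = p)
    if (amphipathic) {
      # apolar sector of the helical wheel: phases within 60 deg of 0;
      # cationic residues are left in place so amphipathicity does not
      # dilute the designed charge composition
      phase_cos <- cos(seq_len(len) * 100 * pi / 180)
      face <- which(phase_cos > 0.5 & !chars %in% c("R", "K"))
      if (length(face)) {
        chars[face] <- sample(APOLAR_FACE, length(face), replace = TRUE)
      }
    }
    paste(chars, collapse = "")
  }, character(1))
}

#' Generate a labeled synthetic peptide corpus
#'
#' Positives are drawn from a composition with boosted Arg/Lys mass
#' (optionally with an apolar helical face); negatives from a near-uniform
#' composition.  Duplicate sequences within and across classes are removed
#' and redrawn until both classes reach their target size, so the output is
#' deduplicated and the classes share no sequence.
#'
#' @param config A [synth_config()].
#' @return Labeled peptide tibble (`id`, `sequence`, `label`) of
#'   `2 * n_per_class` rows with a `manifest` attribute (config echo) and a
#'   seed audit entry.
#' @examples
#' corpus <- generate_corpus(synth_config(n_per_class = 25, seed = 7))
#' dplyr::count(corpus, label)
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_per_class
  pos_seed <- (config$seed * 2L + 1L) %% .Machine$integer.max
  neg_seed <- (config$seed * 2L + 2L) %% .Machine$integer.max

  draw_unique <- function(seed, freqs, amph, exclude) {
    seqs <- character(0)
    withr::with_seed(seed, {
      for (round in 1:25) {
        need <- n - length(seqs)
        if (need == 0) break
        new <- draw_class(need + ceiling(need / 4) + 2L, config, freqs, amph)
        seqs <- setdiff(unique(c(seqs, setdiff(new, exclude))), exclude)
        if (length(seqs) >= n) seqs <- seqs[seq_len(n)]
      }
    })
    if (length(seqs) < n) {
      abort("Could not generate enough unique sequences; widen length_range.")
    }
    seqs
  }

  pos <- draw_unique(pos_seed, class_freqs(config$cationic_fraction_pos),
                     config$amphipathic, character(0))
  neg <- draw_unique(neg_seed, class_freqs(config$cationic_fraction_neg),
                     FALSE, pos)

  out <- tibble(
    id = c(sprintf("cpp%04d", seq_len(n)), sprintf("neg%04d", seq_len(n))),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), each = n)
  )
  attr(out, "manifest") <- c(unclass(config), list(generator = "pepqsar"))
  attr(out, "provenance") <- "synthetic"
  log_seed(out, "generate_corpus", config$seed)
}

#' Generate a synthetic amino-acid property table
#'
#' Low-rank signal plus Gaussian noise: `values = scores %*% t(loadings) +
#' noise`.  Scores and loadings have random orthonormal columns and the
#' per-component signal strengths decrease (ratios `latent_rank : ... : 1`),
#' so the generating components are identifiable and ordered — recovered
#' principal components can be compared to them one-to-one.  Signal entries
#' are scaled to unit average variance, making `noise_sd` directly
#' interpretable as a relative noise level.
#'
#' @param n_residues,n_properties Table dimensions (residue codes are taken
#'   from the 20-letter alphabet, recycled with suffixes beyond 20).
#' @param latent_rank Rank of the signal part (at most
#'   `min(n_residues, n_properties)`).
#' @param noise_sd Standard deviation of the additive noise.
#' @param seed Integer seed.
#' @return List with `table` (tibble: `residue` + property columns),
#'   `scores` (n_residues x latent_rank generating score matrix, component
#'   variance decreasing) and `loadings`.
#' @export
generate_property_table <- function(n_residues = 20, n_properties = 12,
                                    latent_rank = 3, noise_sd = 0.05,
                                    seed = 1) {
  if (latent_rank > min(n_residues, n_properties)) {
    abort("`latent_rank` must not exceed min(n_residues, n_properties).")
  }
  withr::with_seed(seed, {
    qs <- qr.Q(qr(matrix(stats::rnorm(n_residues * latent_rank),
                         n_residues, latent_rank)))
    ql <- qr.Q(qr(matrix(stats::rnorm(n_properties * latent_rank),
                         n_properties, latent_rank)))
    noise <- matrix(stats::rnorm(n_residues * n_properties, sd = noise_sd),
                    n_residues, n_properties)
  })
  d <- seq(latent_rank, 1)
  d <- d / sqrt(sum(d^2)) * sqrt(n_residues * n_properties)
  signal <- qs %*% diag(d, nrow = latent_rank) %*% t(ql)
  # generating scores are defined on the autoscaled noiseless signal (the
  # representation scale construction works in), via the generator's own
  # SVD, so recovery is identified up to per-component sign
  sv <- svd(scale(signal))
  scores <- sv$u[, seq_len(latent_rank), drop = FALSE] %*%
    diag(sv$d[seq_len(latent_rank)], nrow = latent_rank)
  loadings <- ql
  values <- signal + noise
  residues <- make.unique(rep(AA_ALPHABET, length.out = n_residues))
  tab <- tibble(residue = residues)
  for (j in seq_len(n_properties)) {
    tab[[sprintf("p%02d", j)]] <- values[, j]
  }
  list(table = tab, scores = scores, loadings = loadings)
}
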