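#' Amino-acid z-scales by principal component analysis
#'
#' An amino-acid z-scale is a low-dimensional "principal property" encoding:
#' each residue is summarised by its scores on the leading principal
#' components of a table of physicochemical properties.  With three
#' components the axes are conventionally interpreted as size/shape (z1),
#' polarity/lipophilicity (z2) and charge (z3).  [build_zscale()] constructs
#' such a scale from any residues-by-properties table; [zscale()] returns the
#' packaged published 20-residue, 3-component scale used as the default
#' quantitative alphabet throughout the package.
#'
#' @name aa_zscale
NULL

new_aa_zscale <- function(scores, loadings = NULL, explained_variance = NULL) {
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance = explained_variance),
    class = "aa_zscale"
  )
}

#' Packaged three-component amino-acid z-scale
#'
#' Returns the package's reference z-scale: one (z1, z2, z3) triple per
#' natural amino acid, derived by PCA of 12 physicochemical properties of the
#' capped residues.  Values are shipped verbatim as packaged data; downstream
#' descriptor arithmetic never depends on how the PCA was configured.
#'
#' @return An `aa_zscale` object whose `scores` field is a 20-row tibble with
#'   columns `residue`, `z1`, `z2`, `z3`.
#' @examples
#' zscale()
#' lookup_z(zscale(), "R")
#' @export
zscale <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- new_aa_zscale(read_packaged_csv("zscale3.csv"))
    }
    cache
  }
})

validate_property_table <- function(props) {
  if (is.matrix(props)) {
    if (is.null(rownames(props))) {
      abort("A property matrix needs residue rownames.")
    }
    props <- tibble(residue = rownames(props), as_tibble(props))
  }
  props <- as_tibble(props)
  if (ncol(props) < 3L || nrow(props) < 2L) {
    abort("Need at least 2 residues and 2 properties for PCA.")
  }
  residues <- as.character(props[[1]])
  if (anyDuplicated(residues)) {
    abort(sprintf("Duplicate residue code: '%s'.",
                  residues[duplicated(residues)][1]))
  }
  prop_names <- names(props)[-1]
  if (anyDuplicated(prop_names)) {
    abort(sprintf("Duplicate property name: '%s'.",
                  prop_names[duplicated(prop_names)][1]))
  }
  x <- as.matrix(props[, -1])
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    abort("Property table contains non-finite entries.")
  }
  rownames(x) <- residues
  x
}

# Components are sign-anchored so that interpretation is stable: z1 on a
# positive volume loading, z2 on the octanol/water partition coefficient,
# z3 on net charge.  If the anchor property is absent, the largest-magnitude
# loading is made positive.
ZSCALE_SIGN_ANCHORS <- c("volume", "QPlogPo/w", "Tot Q")

orient_component_signs <- function(loadings, prop_names) {
  flip <- rep(1, ncol(loadings))
  anchors <- tolower(ZSCALE_SIGN_ANCHORS)
  lowered <- tolower(prop_names)
  for (j in seq_len(ncol(loadings))) {
    anchor_idx <- if (j <= length(anchors)) match(anchors[j], lowered) else NA
    ref <- if (!is.na(anchor_idx)) {
      loadings[anchor_idx, j]
    } else {
      loadings[which.max(abs(loadings[, j])), j]
    }
    if (ref < 0) flip[j] <- -1
  }
  flip
}

#' Build an amino-acid z-scale from a physicochemical property table
#'
#' Autoscales the property table (each column mean-centered and divided by
#' its standard deviation), then extracts the leading principal components by
#' singular value decomposition.  Scores are projections onto the unit-norm
#' right singular vectors; loadings are the singular vectors themselves, with
#' signs anchored as described under Details.
#'
#' @details Component signs (arbitrary in any PCA) are oriented so that the
#'   loading of molecular volume is positive on component 1, the
#'   octanol/water partition coefficient on component 2 and net charge on
#'   component 3; when the anchor property is not in the table the
#'   largest-magnitude loading of that component is made positive.
#'
#' @param props Data frame or tibble whose first column holds one-letter
#'   residue codes and whose remaining columns are numeric properties; or a
#'   numeric matrix with residue rownames.
#' @param n_components Number of components to extract (default 3); must not
#'   exceed `min(n_residues - 1, n_properties)`.
#' @return An `aa_zscale` with per-residue `scores` (tibble: `residue`,
#'   `z1`..`zk`), the properties-by-components `loadings` matrix, and
#'   `explained_variance` fractions (non-increasing, summing to at most 1).
#' @examples
#' tab <- generate_property_table(n_residues = 8, n_properties = 5,
#'                                latent_rank = 2, noise_sd = 0.1, seed = 4)
#' build_zscale(tab$table, n_components = 2)
#' @export
build_zscale <- function(props, n_components = 3) {
  x <- validate_property_table(props)
  n <- nrow(x)
  p <- ncol(x)
  if (n_components < 1 || n_components > min(n - 1L, p)) {
    abort(sprintf(
      "n_components must be between 1 and min(n_residues - 1, n_properties) = %d.",
      min(n - 1L, p)
    ))
  }
  sds <- apply(x, 2, stats::sd)
  zero_var <- sds < .Machine$double.eps^0.5
  if (any(zero_var)) {
    abort(sprintf("Property column(s) with zero variance: %s.",
                  paste(colnames(x)[zero_var], collapse = ", ")))
  }
  xs <- scale(x, center = TRUE, scale = sds)
  sv <- svd(xs)
  k <- n_components
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  flip <- orient_component_signs(loadings, colnames(x))
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- xs %*% loadings
  ev <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  dimnames(loadings) <- list(colnames(x), paste0("z", seq_len(k)))
  score_tbl <- tibble(residue = rownames(x))
  for (j in seq_len(k)) score_tbl[[paste0("z", j)]] <- unname(scores[, j])
  new_aa_zscale(score_tbl, loadings = loadings, explained_variance = ev)
}

#' Look up the z-scores of residues
#'
#' @param scale An `aa_zscale`.
#' @param residues Character vector of one-letter residue codes
#'   (case-insensitive).
#' @return A tibble with one row per requested residue and the scale's score
#'   columns.
#' @examples
#' lookup_z(zscale(), c("R", "G"))
#' @export
lookup_z <- function(scale, residues) {
  stopifnot(inherits(scale, "aa_zscale"))
  residues <- toupper(residues)
  idx <- match(residues, scale$scores$residue)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(sprintf("Unknown residue '%s' (position %d): not in the scale.",
                  residues[bad], bad))
  }
  scale$scores[idx, ]
}

# internal: residues x components numeric matrix keyed by residue code
zscale_matrix <- function(scale) {
  m <- as.matrix(scale$scores[, -1])
  rownames(m) <- scale$scores$residue
  m
}

#' @export
print.aa_zscale <- function(x, ...) {
  k <- ncol(x$scores) - 1L
  cat(sprintf("<aa_zscale: %d residues, %d components>\n", nrow(x$scores), k))
  if (!is.null(x$explained_variance)) {
    cat("explained variance:",
        paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  }
  print(x$scores, ...)
  invisible(x)
}

#' @describeIn aa_zscale Per-residue scores as a tibble.
#' @param x An `aa_zscale` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.aa_zscale <- function(x, ...) x$scores

#' @describeIn aa_zscale One-row summary (residue count, component count,
#'   cumulative explained variance).
#' @exportS3Method generics::glance
glance.aa_zscale <- function(x, ...) {
  tibble(
    n_residues = nrow(x$scores),
    n_components = ncol(x$scores) - 1L,
    cum_explained_variance = if (is.null(x$explained_variance)) NA_real_
                             else sum(x$explained_variance)
  )
}

#' Write / read an amino-acid scale as CSV
#'
#' The on-disk form is a plain CSV with a `residue` column followed by the
#' score columns, matching the packaged scale's layout.  Loadings, when
#' present, can be written alongside.
#'
#' @param scale An `aa_zscale`.
#' @param path Output CSV path for the scores.
#' @param loadings_path Optional path for a properties-by-components loadings
#'   CSV.
#' @return `path`, invisibly.
#' @export
write_zscale <- function(scale, path, loadings_path = NULL) {
  utils::write.csv(scale$scores, path, row.names = FALSE)
  if (!is.null(loadings_path) && !is.null(scale$loadings)) {
    utils::write.csv(
      data.frame(property = rownames(scale$loadings), scale$loadings,
                 check.names = FALSE),
      loadings_path, row.names = FALSE
    )
  }
  invisible(path)
}

#' @rdname write_zscale
#' @export
read_zscale <- function(path) {
  new_aa_zscale(as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)))
}
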