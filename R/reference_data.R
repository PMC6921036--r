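#' Packaged reference tables
#'
#' Small reference tables shipped with the package.
#'
#' `pk_parameter_table()` returns the printed simulation inputs for
#' gemcitabine, the two carrier peptides (penetratin and pVEC, plus their
#' Cys-extended variants) and the two drug-peptide conjugates: dose,
#' infusion duration, clearance, per-kg central volume, body weight and
#' bioavailable fraction, with plasma-protein-binding and blood/plasma-ratio
#' annotations carried along (annotation only; no tissue model is fitted).
#'
#' `peptide_zscore_reference()` returns published per-peptide z-scores for
#' the four carrier peptides.  These derive from a peptide-level PCA whose
#' descriptor matrix is not public, so they are reference data only: they do
#' not equal the per-residue mean z-scores that [mean_z()] computes, and no
#' package computation reproduces them (see the methods vignette).
#'
#' @return A tibble.
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
pk_parameter_table <- function() read_packaged_csv("pk_parameters.csv")

#' @rdname reference_tables
#' @export
peptide_zscore_reference <- function() {
  read_packaged_csv("peptide_zscores_reference.csv")
}

#' Parameters for one compound from the packaged PK table
#'
#' @param compound Compound name as in `pk_parameter_table()$compound`
#'   (e.g. `"Gem"`, `"Gem-Cys-pVEC"`).
#' @param sim_duration_h Simulation window, h.
#' @return A [pk_params()] object.
#' @examples
#' pk_auc_inf(pk_params_for("Gem"))
#' @export
pk_params_for <- function(compound, sim_duration_h = 24) {
  tab <- pk_parameter_table()
  row <- tab[tab$compound == compound, ]
  if (nrow(row) != 1) {
    abort(sprintf("Unknown compound '%s'; see pk_parameter_table().",
                  compound))
  }
  pk_params(
    dose_mg = row$dose_mg, infusion_h = row$infusion_h,
    clearance_L_h = row$clearance_L_h, vc_L_kg = row$vc_L_kg,
    body_weight_kg = row$body_weight_kg, f = row$f_percent / 100,
    sim_duration_h = sim_duration_h
  )
}
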