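# Summary statistics of the public SIDER/PubChem benchmark that this
# method was designed for. Only the published counts are recorded here (the
# underlying matrices require the external databases); they document the
# data regime the method targets and support consistency checks.

#' Summary counts of the SIDER/PubChem benchmark dataset
#'
#' Published characteristics of the reference data: 888 approved drugs
#' described by the 881 PubChem substructure keys and 1385 SIDER
#' side-effect keywords, with the total number of recorded drug/feature
#' associations and the resulting per-drug averages (as printed, one
#' decimal).
#'
#' @return named list with `n_drugs`, `n_substructures`, `n_side_effects`,
#'   `side_effect_associations`, `substructure_associations`,
#'   `side_effects_per_drug`, `substructures_per_drug`.
#' @export
sider_benchmark_summary <- function() {
  list(n_drugs = 888L,
       n_substructures = 881L,
       n_side_effects = 1385L,
       side_effect_associations = 61102L,
       substructure_associations = 107292L,
       side_effects_per_drug = 68.8,
       substructures_per_drug = 120.8)
}
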