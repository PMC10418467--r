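# End-to-end prediction pipeline: SMILES -> descriptors -> discriminant
# score, activity class, predicted potency and screening verdict.

#' Score compounds through the shipped QSAR models
#'
#' Runs the full pipeline on a table of compounds: descriptors from each
#' SMILES, the discriminant function (activity class via its bands), the
#' regression-predicted pIC50, and the screening rule (score in the open
#' window (1, 5) and predicted pIC50 above 9).
#'
#' @param data A data frame with a SMILES column.
#' @param smiles Column holding SMILES strings (tidy-eval; default
#'   `smiles`).
#' @param discriminant,regression The models to apply; default the shipped
#'   equations [eq1_model()] and [eq2_model()].
#' @param volume_table Volume table for `Mv` (see [vdw_volume_table()]).
#' @return The input columns plus `df`, `pred_class`, `pic50_pred` and
#'   `candidate`, as a tibble.
#' @export
#' @examples
#' qsar_predict(load_table1()[1:2, ])
qsar_predict <- function(data, smiles = smiles,
                         discriminant = eq1_model(),
                         regression = eq2_model(),
                         volume_table = vdw_volume_table()) {
  desc <- compute_descriptors(data, smiles = {{ smiles }},
                              volume_table = volume_table)
  scored <- screen(
    df = evaluate_linear_model(discriminant, desc),
    pic50_pred = evaluate_linear_model(regression, desc)
  )
  dplyr::bind_cols(tibble::as_tibble(data), scored)
}
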