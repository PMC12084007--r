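# End-to-end orchestration over well-level profiles: normalize -> select
# features -> consensus -> toxicity -> induction -> percent replicating ->
# accounting. The numbered scripts under analysis/ are thin drivers over
# this function and the stage functions it calls.

#' Run the profile-level pipeline end to end
#'
#' Fixed stage order: plate-wise DMSO normalization ([mad_robustize()]),
#' staged feature selection ([select_features()]), consensus over replicates
#' ([consensus_profiles()]), toxicity filter, induction/activity filter on
#' the non-toxic compounds, percent replicating on the compounds surviving
#' both filters, and the sequential filter accounting.
#'
#' @param profiles A raw well-level profile tibble (e.g. from
#'   [simulate_profiles()] or aggregated single-cell tables).
#' @param config A [pipeline_config()].
#' @return A list with `normalized`, `selection_report`, `consensus`
#'   (test compounds, selected features), `flags` ([compound_flags()]),
#'   `replicating` (`metric_result`), `accounting` (one-row tibble) and
#'   `normalization_stats`.
#' @export
run_pipeline <- function(profiles, config = pipeline_config()) {
  norm <- mad_robustize(profiles, config)
  sel <- select_features(norm$profiles, config)
  cons_all <- consensus_profiles(sel$profiles, include_controls = FALSE)
  flags <- compound_flags(cons_all, config)

  surviving <- flags$compound_id[!flags$is_toxic & !flags$is_low_active]
  eval_profiles <- sel$profiles[
    !is.na(sel$profiles$compound_id) &
      sel$profiles$compound_id %in% surviving &
      sel$profiles$role == "test", ]
  replicating <- percent_replicating(eval_profiles, config)

  n_total <- nrow(flags)
  n_toxic <- sum(flags$is_toxic)
  n_low <- sum(flags$is_low_active)
  eval_ok <- !is.na(replicating$scores$score)
  n_nonrep <- replicating$n_evaluated - replicating$n_passing
  accounting <- filter_accounting(n_total, n_toxic, n_low, n_nonrep)

  list(
    normalized = norm$profiles,
    normalization_stats = norm$stats,
    selection_report = sel$report,
    selected_profiles = sel$profiles,
    consensus = cons_all,
    flags = flags,
    replicating = replicating,
    accounting = accounting
  )
}
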