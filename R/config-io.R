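#' Load a run configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]; a nested `cohort:` map
#' mirrors [cohort_config()], whose `effect_spec:` entries mirror
#' [injected_effect()].
#'
#' @param path YAML file.
#' @param out_dir Optional override for the run directory.
#' @return A [run_config()].
#' @export
load_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(y$cohort)) {
    cc <- y$cohort
    if (!is.null(cc$effect_spec)) {
      cc$effect_spec <- lapply(cc$effect_spec, function(e) do.call(injected_effect, e))
    }
    cohort <- do.call(cohort_config, cc)
  }
  y$cohort <- NULL
  if (!is.null(out_dir)) y$out_dir <- out_dir
  y$groupings <- unlist(y$groupings)
  y$metric_names <- unlist(y$metric_names)
  do.call(run_config, c(y, list(cohort = cohort)))
}
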