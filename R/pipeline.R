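#' Run the full methylation-expression pipeline on a synthetic study
#'
#' DMC calling, DEG calling, global methylation-shift test and the
#' integration report, end to end. Deterministic given the study (whose
#' generator is itself a pure function of its master seed).
#'
#' @param study a `synthetic_study` from [simulate_study()].
#' @param fdr q threshold for DMCs and DEGs.
#' @param min_coverage per-sample coverage filter for CpG sites.
#' @param tss_half_width,meth_threshold,k integration settings.
#' @return list of class `pipeline_result`: `dmc_fits`, `deg_fits`,
#'   `shift` (KS test), `report` (an `integration_report`).
#' @export
run_pipeline <- function(study, fdr = 0.05, min_coverage = 5,
                         tss_half_width = 2000, meth_threshold = 0.25, k = 2) {
  stopifnot(inherits(study, "synthetic_study"))
  dmc_fits <- dmc_fit(study$meth$table, min_coverage = min_coverage)
  deg_fits <- deg_test(study$expr$table)
  shift <- global_methylation_shift(study$meth$table)
  report <- integration_report(dmc_fits, deg_fits, study$genome,
                               study$expr$table, fdr = fdr,
                               tss_half_width = tss_half_width,
                               meth_threshold = meth_threshold, k = k,
                               seed = study$config$seed)
  structure(list(dmc_fits = dmc_fits, deg_fits = deg_fits,
                 shift = shift, report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: KS D = %.3f (p = %.3g)\n",
              x$shift$statistic, x$shift$p.value))
  print(x$report)
  invisible(x)
}
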