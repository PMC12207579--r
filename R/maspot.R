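#' Published summary tables of the MASPOT potato diallel study
#'
#' Returns the published summary statistics of the MASPOT experimental
#' population (an 18-parent incomplete diallel of elite tetraploid potato,
#' 5013 F1 clones, 10 agronomic traits), bundled as plain-text inputs for
#' the package's arithmetic cross-checks:
#' \describe{
#'   \item{`trait_summary`}{per-trait range, mean, SE, phenotypic variance,
#'     CV, observation and replicate counts}
#'   \item{`variance_components`}{pedigree-BLUP additive, family (SCA) and
#'     line variance components with SEs, their variance-explained
#'     percentages, and the published SCA/GCA ratio}
#'   \item{`cytoplasm_contrasts`}{fixed-effect contrasts of the T/beta and D
#'     cytoplasm types relative to W/gamma, with SEs and the published
#'     percent-of-mean effect sizes}
#'   \item{`cv_metrics`}{single-step GBLUP cross-validation summaries: mean
#'     prediction correlation with SD, dispersion slope, plot and design
#'     heritabilities, and the published prediction accuracy}
#' }
#'
#' These tables are inputs (e.g. [sca_gca_ratio()] on the published
#' components reproduces the published ratio); they are not computed by this
#' package.
#'
#' @return Named list of four data frames.
#' @export
maspot_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "tetrablup", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(trait_summary = rd("maspot_trait_summary.csv"),
       variance_components = rd("maspot_variance_components.csv"),
       cytoplasm_contrasts = rd("maspot_cytoplasm_contrasts.csv"),
       cv_metrics = rd("maspot_cv_metrics.csv"))
}
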