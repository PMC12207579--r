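#' Plot and design heritability from variance components
#'
#' Plot heritability is the additive fraction of the single-plot phenotypic
#' variance, \eqn{h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_f+\sigma^2_l+
#' \sigma^2_e)}; the design heritability replaces the residual by
#' \eqn{\sigma^2_e/n_{rep}}, i.e. the heritability of a clone's
#' replicate-averaged corrected phenotype.
#'
#' @param vc Named variance components (`sigma2_a`, `sigma2_l`, `sigma2_f`,
#'   `sigma2_e`); missing terms enter as 0. A `diallel_blup` fit is accepted.
#' @param n_rep Number of replicates per clone for the design heritability
#'   (default 1, in which case both heritabilities coincide).
#' @return List with `h2_plot`, `h2_design` and `n_rep`.
#' @export
heritability <- function(vc, n_rep = 1) {
  if (inherits(vc, "diallel_blup")) vc <- vc$vc
  g <- function(nm) if (nm %in% names(vc)) unname(vc[nm]) else 0
  a <- g("sigma2_a"); l <- g("sigma2_l"); f <- g("sigma2_f"); e <- g("sigma2_e")
  tot <- a + l + f + e
  if (tot <= 0) stop("undefined heritability: zero total variance", call. = FALSE)
  list(h2_plot = a / tot, h2_design = a / (a + l + f + e / n_rep),
       n_rep = n_rep)
}

#' SCA/GCA variance ratio
#'
#' The ratio of the family (specific combining ability) variance to the
#' general combining ability variance, the latter being a quarter of the
#' additive variance: \eqn{\sigma^2_f / (\sigma^2_a/4)}.
#'
#' @param vc Named variance components or a `diallel_blup` fit.
#' @return The ratio, or `NA` when the additive variance is zero.
#' @export
sca_gca_ratio <- function(vc) {
  if (inherits(vc, "diallel_blup")) vc <- vc$vc
  a <- unname(vc["sigma2_a"])
  f <- if ("sigma2_f" %in% names(vc)) unname(vc["sigma2_f"]) else 0
  if (is.na(a) || a <= 0) return(NA_real_)
  f / (a / 4)
}

#' Cytoplasm-type contrasts and their size relative to the trait mean
#'
#' Extracts the cytoplasm fixed-effect contrasts from a fitted model (the
#' reference type, by construction the W/gamma type when present, has
#' contrast 0) together with standard errors, a 95% CI significance flag and
#' the absolute contrast as a percentage of the population trait mean.
#'
#' @param fit A [diallel_blup()] fit whose fixed part includes `cytoplasm`.
#' @param trait_mean Population mean used for the percentage (default: mean
#'   of the observations in the fit).
#' @return Data frame with one row per cytoplasm type.
#' @export
cytoplasm_contrasts <- function(fit, trait_mean = NULL) {
  stopifnot(inherits(fit, "diallel_blup"))
  if (!"cytoplasm" %in% names(fit$obs))
    stop("model was fitted without cytoplasm information", call. = FALSE)
  trait_mean <- trait_mean %||% mean(fit$obs$value)
  lev <- levels(fit$obs$cytoplasm)
  cn <- paste0("cytoplasm", lev)
  est <- se <- stats::setNames(numeric(length(lev)), lev)
  for (i in seq_along(lev)) {
    if (cn[i] %in% names(fit$beta)) {
      est[i] <- fit$beta[cn[i]]
      se[i] <- sqrt(fit$beta_vcov[cn[i], cn[i]])
    } else { est[i] <- 0; se[i] <- 0 }  # reference level
  }
  present <- lev %in% unique(as.character(fit$obs$cytoplasm))
  if (any(!present)) warning("cytoplasm types without observations dropped: ",
                             paste(lev[!present], collapse = ", "))
  data.frame(cytoplasm = lev,
             contrast = unname(est), se = unname(se),
             percent_of_mean = 100 * abs(unname(est)) / trait_mean,
             significant = abs(unname(est)) > 1.96 * unname(se) & se > 0,
             reference = se == 0,
             stringsAsFactors = FALSE)[present, , drop = FALSE]
}

#' Profile the model fit over the double-reduction rate
#'
#' Rebuilds the tetrasomic pedigree relationship matrix on a grid of
#' double-reduction rates, refits the REML model at each grid point and
#' returns the -2 log likelihood profile with its minimiser.
#'
#' @param pheno,pedigree,trait,... Passed to [diallel_blup()].
#' @param grid Double-reduction rates to profile (default
#'   `seq(0, 0.25, by = 0.05)`).
#' @return Data frame `(double_reduction, m2ll, converged)` with attribute
#'   `argmin`; non-converged grid points are excluded from the argmin.
#' @export
profile_double_reduction <- function(pheno, pedigree, trait = NULL,
                                     grid = seq(0, 0.25, by = 0.05), ...) {
  if (any(grid < 0 | grid > 1))
    stop("double-reduction grid must lie in [0, 1]", call. = FALSE)
  res <- lapply(grid, function(w) {
    A <- amat_tetra(pedigree, double_reduction = w)
    fit <- tryCatch(
      diallel_blup(pheno, A, trait = trait, pedigree = pedigree, ...),
      error = function(e) NULL)
    if (is.null(fit)) return(data.frame(double_reduction = w, m2ll = NA_real_,
                                        converged = FALSE))
    data.frame(double_reduction = w, m2ll = fit$m2ll,
               converged = isTRUE(fit$converged))
  })
  out <- do.call(rbind, res)
  ok <- out$converged & !is.na(out$m2ll)
  attr(out, "argmin") <- if (any(ok))
    out$double_reduction[ok][which.min(out$m2ll[ok])] else NA_real_
  out
}
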