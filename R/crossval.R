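#' Repeated random k-fold partitions of a clone set
#'
#' Each repeat partitions the clones into k folds whose sizes differ by at
#' most one. The plan is reproducible: repeat r uses the sub-seed
#' `(seed + 7919 * r) mod 2^31 - 1` (a documented counter scheme), so any
#' repeat can be regenerated independently.
#'
#' @param clone_ids Clones to partition.
#' @param k Number of folds (default 8).
#' @param repeats Number of repeats (default 30).
#' @param seed Base seed of the plan.
#' @return Data frame `(rep, fold, clone)` of class `"cv_plan"`.
#' @export
cv_folds <- function(clone_ids, k = 8, repeats = 30, seed = 1) {
  n <- length(clone_ids)
  if (n < k) stop("configuration error: fewer clones than folds", call. = FALSE)
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed((seed + 7919 * r) %% (2^31 - 1))
    ord <- sample(clone_ids)
    ## sizes differ by <= 1: folds fill cyclically over the permutation
    out[[r]] <- data.frame(rep = r,
                           fold = sort(rep(seq_len(k), length.out = n)),
                           clone = ord, stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, out)
  class(plan) <- c("cv_plan", "data.frame")
  plan
}

#' Mean corrected phenotype per clone
#'
#' Adjusts each observation for the estimated fixed effects of a fitted model
#' and averages per clone: \eqn{\bar{y}^c_i = \mathrm{mean}(y - x'\hat b)}.
#' Clones without records are excluded.
#'
#' @param fit A [diallel_blup()] fit (its own fixed-effect estimates are
#'   used, matching the model being validated).
#' @return Named vector of corrected means.
#' @export
corrected_means <- function(fit) {
  stopifnot(inherits(fit, "diallel_blup"))
  yc <- fit$obs$value - as.numeric(fit$X %*% fit$beta)
  tapply(yc, fit$obs$clone, mean)
}

#' Prediction accuracy from a prediction correlation
#'
#' \eqn{PA = r / \sqrt{h^2_{design}}}: the correlation between EBVs and mean
#' corrected phenotypes, scaled by the accuracy of the corrected means
#' themselves.
#'
#' @param r Prediction correlation.
#' @param h2_design Design heritability in (0, 1].
#' @return The prediction accuracy.
#' @export
prediction_accuracy <- function(r, h2_design) {
  if (any(h2_design <= 0)) stop("undefined: design heritability must be > 0",
                                call. = FALSE)
  r / sqrt(h2_design)
}

#' Dispersion bias of predicted breeding values
#'
#' Ordinary least-squares slope of the mean corrected phenotypes on the EBVs.
#' A slope of 1 indicates correctly scaled predictions; above 1, extreme EBVs
#' are deflated (under-dispersed); below 1, inflated.
#'
#' @param ebv Predicted breeding values.
#' @param ybar_c Mean corrected phenotypes, same clones and order.
#' @return The regression slope.
#' @export
dispersion_bias <- function(ebv, ybar_c) {
  ok <- is.finite(ebv) & is.finite(ybar_c)
  if (sum(ok) < 3 || stats::var(ebv[ok]) == 0) return(NA_real_)
  unname(stats::cov(ebv[ok], ybar_c[ok]) / stats::var(ebv[ok]))
}

#' Repeated k-fold cross-validation of breeding-value prediction
#'
#' Estimates variance components once on the full data (unless `vc` is
#' given), then for every fold of every repeat re-solves the mixed-model
#' equations with the validation clones' phenotype records removed (their
#' pedigree/genomic links remain, mirroring the single-step use case) and
#' correlates their predicted breeding values with their mean corrected
#' phenotypes from the full-data fixed effects. Reports the per-repeat
#' Pearson correlation, its mean and SD, the prediction accuracy
#' r / sqrt(design h2), and the dispersion slope.
#'
#' @inheritParams diallel_blup
#' @param k,repeats,seed Fold plan (see [cv_folds()]).
#' @param validate Clones to validate. Default `"offspring"`: clones with
#'   both parents known (F1 generation); alternatively a character vector.
#' @param vc Optional named variance components used as priors; default:
#'   REML on the full data.
#' @param n_rep Replicates per clone used in the design heritability
#'   (default: the median number of records per validated clone).
#' @return Object of class `"diallel_cv"`: per-repeat metrics, their summary,
#'   the fold plan and the full-data fit.
#' @export
cross_validate <- function(pheno, kinship, trait = NULL, pedigree = NULL,
                           k = 8, repeats = 30, seed = 1,
                           validate = "offspring", vc = NULL, n_rep = NULL,
                           ...) {
  full <- diallel_blup(pheno, kinship, trait = trait, pedigree = pedigree,
                       vc = vc, ...)
  trait <- full$trait
  vc_full <- full$vc
  ybar <- corrected_means(full)

  phen_clones <- unique(full$obs$clone)
  if (identical(validate, "offspring")) {
    if (is.null(pedigree)) {
      validate <- phen_clones
    } else {
      sp <- sort_pedigree(pedigree, check_cytoplasm = FALSE)
      off <- sp$clone[!is.na(sp$sire) & !is.na(sp$dam)]
      validate <- intersect(phen_clones, off)
    }
  }
  validate <- intersect(validate, phen_clones)
  plan <- cv_folds(validate, k = k, repeats = repeats, seed = seed)

  ## rebuild the design once; per fold only rows are dropped
  d <- .build_design(pheno, trait, kinship, pedigree,
                     fixed = full$fixed,
                     line = !is.null(full$line_effects),
                     line_by_year = any(grepl(":", names(full$line_effects) %||% "")),
                     family = !is.null(full$family_effects))
  labels <- vapply(d$terms, `[[`, "", "label")
  theta <- unname(vc_full[c(paste0("sigma2_", substr(labels, 1, 1)), "sigma2_e")])
  ia <- which(labels == "additive")

  per_rep <- data.frame(rep = seq_len(repeats), r = NA_real_, beta = NA_real_)
  ebv_store <- matrix(NA_real_, length(validate), repeats,
                      dimnames = list(validate, NULL))
  for (r in seq_len(repeats)) {
    pr <- plan[plan$rep == r, , drop = FALSE]
    for (f in sort(unique(pr$fold))) {
      val <- pr$clone[pr$fold == f]
      keep <- !(d$obs$clone %in% val)
      terms_f <- lapply(d$terms, function(tm) {
        tm$Z <- tm$Z[keep, , drop = FALSE]
        tm
      })
      sol <- .mme_solve(d$y[keep], d$X[keep, , drop = FALSE], unname(terms_f),
                        resid = list(nt = 1), theta = theta,
                        need_cinv = FALSE)
      ebv_f <- stats::setNames(sol$s[sol$idx[[ia]]], d$meta$ids)
      ebv_store[val, r] <- ebv_f[val]
    }
    yv <- ybar[validate]
    if (stats::var(yv) == 0) next  # degenerate repeat, flagged by NA
    per_rep$r[r] <- stats::cor(ebv_store[, r], yv)
    per_rep$beta[r] <- dispersion_bias(ebv_store[, r], yv)
  }

  n_rep <- n_rep %||% stats::median(table(full$obs$clone[full$obs$clone %in% validate]))
  h2 <- heritability(vc_full, n_rep = n_rep)
  ok <- !is.na(per_rep$r)
  res <- list(trait = trait, kinship_kind = full$kinship_kind,
              per_repeat = per_rep,
              mean_r = mean(per_rep$r[ok]), sd_r = stats::sd(per_rep$r[ok]),
              dispersion = mean(per_rep$beta[ok]),
              h2_plot = h2$h2_plot, h2_design = h2$h2_design, n_rep = n_rep,
              accuracy = prediction_accuracy(mean(per_rep$r[ok]), h2$h2_design),
              plan = plan, ebv = ebv_store, ybar = ybar[validate],
              vc = vc_full, full_fit = full, k = k, repeats = repeats,
              seed = seed)
  class(res) <- "diallel_cv"
  res
}

#' @export
print.diallel_cv <- function(x, ...) {
  cat("Cross-validation (", x$repeats, " repeats of ", x$k, "-fold), trait: ",
      x$trait, ", matrix: ", x$kinship_kind, "\n", sep = "")
  cat(sprintf("  r(EBV, corrected means) = %.3f +/- %.3f\n", x$mean_r, x$sd_r))
  cat(sprintf("  design h2 = %.3f (n_rep = %d); prediction accuracy = %.3f\n",
              x$h2_design, as.integer(x$n_rep), x$accuracy))
  cat(sprintf("  dispersion slope = %.3f\n", x$dispersion))
  invisible(x)
}
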