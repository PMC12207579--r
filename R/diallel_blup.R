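## Design construction shared by the univariate fit, the bivariate fit and
## cross-validation.
.build_design <- function(pheno, trait, kinship, pedigree = NULL,
                          fixed = NULL, line = TRUE, line_by_year = FALSE,
                          family = TRUE) {
  stopifnot(all(c("clone", "trait", "value") %in% names(pheno)))
  obs <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations for trait '", trait, "'", call. = FALSE)
  obs$clone <- as.character(obs$clone)
  ids <- rownames(kinship)
  if (is.null(ids)) stop("kinship matrix needs clone dimnames", call. = FALSE)
  unknown <- setdiff(unique(obs$clone), ids)
  if (length(unknown) > 0)
    stop("clones with phenotypes but absent from the relationship matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)

  if ("year" %in% names(obs) && "block" %in% names(obs)) {
    obs$block_year <- factor(paste(obs$year, obs$block, sep = ":"))
  } else if ("block" %in% names(obs)) {
    obs$block_year <- factor(obs$block)
  }
  if (!is.null(pedigree) && "cytoplasm" %in% names(pedigree)) {
    cyt <- stats::setNames(as.character(pedigree$cytoplasm),
                           as.character(pedigree$clone))
    obs$cytoplasm <- cyt[obs$clone]
    lev <- unique(obs$cytoplasm[!is.na(obs$cytoplasm)])
    ## reference level: the W (gamma) cytoplasm when present
    wref <- grep("^W", lev, value = TRUE)
    if (length(wref) > 0) lev <- c(wref[1], setdiff(lev, wref[1]))
    obs$cytoplasm <- factor(obs$cytoplasm, levels = lev)
  }
  if (is.null(fixed)) {
    rhs <- character(0)
    if ("block_year" %in% names(obs) && length(unique(obs$block_year)) > 1)
      rhs <- c(rhs, "block_year")
    if ("cytoplasm" %in% names(obs) && !anyNA(obs$cytoplasm) &&
        length(unique(obs$cytoplasm)) > 1)
      rhs <- c(rhs, "cytoplasm")
    fixed <- stats::reformulate(if (length(rhs)) rhs else "1")
  }
  X <- stats::model.matrix(fixed, obs)

  y <- obs$value
  n <- length(y)
  ## additive term over every clone of the relationship matrix
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = match(obs$clone, ids),
                             x = 1, dims = c(n, length(ids)))
  K <- unclass(kinship)
  attributes(K)[setdiff(names(attributes(K)), c("dim", "dimnames"))] <- NULL
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-6 * mean(diag(K))
    message("relationship matrix near-singular; ridged by ", signif(ridge, 3))
    K <- K + diag(ridge, nrow(K))
    ch <- chol(K)
  }
  Kinv <- chol2inv(ch)
  ldetK <- 2 * sum(log(diag(ch)))
  terms <- list(additive = .reml_term("additive", Za, q = length(ids),
                                      K = K, Kinv = Kinv, ldetK = ldetK))
  meta <- list(ids = ids, fixed = fixed)

  if (line) {
    lf <- if (line_by_year && "year" %in% names(obs))
      factor(paste(obs$clone, obs$year, sep = ":")) else factor(obs$clone)
    Zl <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(lf), x = 1,
                               dims = c(n, nlevels(lf)))
    terms$line <- .reml_term("line", Zl, q = nlevels(lf))
    meta$line_levels <- levels(lf)
  }
  if (family) {
    if (is.null(pedigree))
      stop("a pedigree is required for the family (SCA) effect", call. = FALSE)
    fk <- family_key(pedigree)
    fam <- fk[obs$clone]
    obs$family_key <- unname(fam)
    flev <- sort(unique(fam[!is.na(fam)]))
    if (length(flev) > 0) {
      has <- !is.na(fam)
      Zf <- Matrix::sparseMatrix(i = which(has), j = match(fam[has], flev),
                                 x = 1, dims = c(n, length(flev)))
      terms$family <- .reml_term("family", Zf, q = length(flev))
      meta$family_levels <- flev
    }
  }
  list(y = y, X = X, terms = terms, obs = obs, meta = meta)
}

#' Fit the diallel mixed model by AI-REML and predict breeding values
#'
#' Fits the univariate linear mixed model
#' \deqn{y = Xb + Z_a a + Z_l l + Z_f f + e}
#' with additive genetic effects \eqn{a \sim N(0, M\sigma^2_a)} over a
#' relationship matrix M (pedigree A, genomic G, or single-step H), iid line
#' effects \eqn{l} capturing non-transmissible clone-specific deviations, iid
#' family effects \eqn{f} keyed by the unordered sire-dam pair (specific
#' combining ability) and iid residuals. Variance components are estimated by
#' average-information REML with EM-REML fallback steps; breeding values and
#' their prediction error variances come from Henderson's mixed-model
#' equations at the estimates.
#'
#' @param pheno Long-format phenotype table (`clone`, `trait`, `value`, and
#'   optionally `year`, `block`, `replicate`).
#' @param kinship Relationship matrix with clone-id dimnames covering every
#'   phenotyped clone (see [amat_tetra()], [gmat_vanraden()],
#'   [hmat_single_step()]).
#' @param trait Trait name to fit (defaults to the only trait present).
#' @param pedigree Pedigree table; required for the family effect and for the
#'   cytoplasm fixed effect.
#' @param fixed Fixed-effect formula over columns of `pheno` (plus derived
#'   `block_year` and `cytoplasm`). Default: block-by-year and cytoplasm
#'   where available.
#' @param line Include the line effect (TRUE for replicated traits).
#' @param line_by_year Nest the line effect within year (used for multi-year
#'   traits such as dry matter content).
#' @param family Include the family (SCA) effect.
#' @param vc Optional fixed variance components (named as in the fitted
#'   object); when supplied REML is skipped and only the BLUP solve is done,
#'   e.g. for cross-validation with full-data components as priors.
#' @param start,maxit,tol,verbose REML controls: starting values, maximum
#'   iterations (default 100), relative -2logL convergence tolerance
#'   (default 1e-8).
#' @return An object of class `"diallel_blup"` with components `vc` (variance
#'   components with standard errors), `beta` (fixed effects), `ebv`/`pev`
#'   (breeding values and prediction error variances for every clone of the
#'   relationship matrix), `family_effects`, `line_effects`, `m2ll`,
#'   convergence metadata, and the design bookkeeping used by downstream
#'   tools.
#' @seealso [heritability()], [sca_gca_ratio()], [cytoplasm_contrasts()],
#'   [cross_validate()], [diallel_blup2()]
#' @export
diallel_blup <- function(pheno, kinship, trait = NULL, pedigree = NULL,
                         fixed = NULL, line = TRUE, line_by_year = FALSE,
                         family = TRUE, vc = NULL, start = NULL,
                         maxit = 100, tol = 1e-8, verbose = FALSE) {
  if (is.null(trait)) {
    tt <- unique(as.character(pheno$trait))
    if (length(tt) != 1)
      stop("several traits present; choose one via `trait`", call. = FALSE)
    trait <- tt
  }
  d <- .build_design(pheno, trait, kinship, pedigree, fixed, line,
                     line_by_year, family)
  labels <- vapply(d$terms, `[[`, "", "label")
  vc_names <- c(paste0("sigma2_", substr(labels, 1, 1)), "sigma2_e")
  vc_names[vc_names == "sigma2_a"] <- "sigma2_a"

  if (is.null(vc)) {
    fit <- .reml_ai_fit(d$y, d$X, unname(d$terms), resid = list(nt = 1),
                        start = start, maxit = maxit, tol = tol,
                        verbose = verbose)
    theta <- fit$theta
    se <- fit$se
  } else {
    theta <- unname(vc[vc_names])
    if (anyNA(theta))
      stop("`vc` must carry components named ", paste(vc_names, collapse = ", "),
           call. = FALSE)
    fit <- .mme_solve(d$y, d$X, unname(d$terms), resid = list(nt = 1),
                      theta = theta)
    fit$converged <- NA
    fit$m2ll <- fit$m2ll
    se <- rep(NA_real_, length(theta))
    fit$boundary <- rep(FALSE, length(theta))
    fit$AI <- NULL
    fit$iterations <- NULL
  }

  p <- fit$p
  beta <- stats::setNames(fit$s[seq_len(p)], colnames(fit$X))
  beta_vcov <- fit$Cinv[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(beta_vcov) <- list(names(beta), names(beta))

  ia <- which(labels == "additive")
  Ja <- fit$idx[[ia]]
  ebv <- stats::setNames(fit$s[Ja], d$meta$ids)
  pev <- stats::setNames(diag(fit$Cinv[Ja, Ja, drop = FALSE]), d$meta$ids)

  line_effects <- NULL
  if ("line" %in% labels) {
    Jl <- fit$idx[[which(labels == "line")]]
    line_effects <- stats::setNames(fit$s[Jl], d$meta$line_levels)
  }
  family_effects <- NULL
  if ("family" %in% labels) {
    Jf <- fit$idx[[which(labels == "family")]]
    family_effects <- stats::setNames(fit$s[Jf], d$meta$family_levels)
  }

  structure(list(
    trait = trait,
    kinship_kind = attr(kinship, "kind") %||% "unknown",
    vc = stats::setNames(theta, vc_names),
    vc_se = stats::setNames(se, vc_names),
    boundary = stats::setNames(fit$boundary, vc_names),
    AI = fit$AI,
    m2ll = fit$m2ll,
    converged = fit$converged,
    iterations = fit$iterations,
    beta = beta, beta_vcov = beta_vcov,
    ebv = ebv, pev = pev,
    line_effects = line_effects,
    family_effects = family_effects,
    fixed = d$meta$fixed,
    obs = d$obs,
    X = fit$X,
    n = length(d$y),
    call = match.call()),
    class = "diallel_blup")
}

#' @export
print.diallel_blup <- function(x, ...) {
  cat("Diallel mixed model (", x$kinship_kind, "-matrix BLUP), trait: ",
      x$trait, "\n", sep = "")
  cat("  observations:", x$n, "  clones:", length(x$ebv), "\n")
  cat("  -2 log L:", format(x$m2ll, digits = 8),
      if (isTRUE(x$converged)) " (converged)" else
        if (isFALSE(x$converged)) " (NOT converged)" else
          " (BLUP at fixed components)", "\n")
  cat("Variance components:\n")
  print(round(rbind(estimate = x$vc, se = x$vc_se), 4))
  invisible(x)
}

#' @export
summary.diallel_blup <- function(object, n_rep = NULL, ...) {
  h2 <- heritability(object$vc, n_rep = n_rep %||%
                       max(1, round(object$n / length(unique(object$obs$clone)))))
  out <- list(fit = object, h2 = h2,
              sca_gca = sca_gca_ratio(object$vc),
              top = utils::head(sort(object$ebv, decreasing = TRUE), 10))
  class(out) <- "summary.diallel_blup"
  out
}

#' @export
print.summary.diallel_blup <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nPlot h2: %.3f   design h2 (n_rep = %d): %.3f   SCA/GCA: %s\n",
              x$h2$h2_plot, x$h2$n_rep, x$h2$h2_design,
              if (is.na(x$sca_gca)) "undefined" else sprintf("%.2f", x$sca_gca)))
  cat("Top clones by EBV:\n")
  print(round(x$top, 3))
  invisible(x)
}

#' @export
coef.diallel_blup <- function(object, ...) object$beta

#' @export
logLik.diallel_blup <- function(object, ...) {
  structure(-object$m2ll / 2, df = length(object$vc) + length(object$beta),
            class = "logLik")
}

#' Breeding-value predictions with confidence intervals
#'
#' @param object A fitted [diallel_blup()] model.
#' @param clones Clone ids to report (default: all clones of the relationship
#'   matrix). Clones with no records and no relatives shrink to EBV 0 with
#'   PEV equal to the prior variance.
#' @param level Confidence level for the normal-theory interval
#'   `ebv +/- z * sqrt(pev)` (default 0.95).
#' @param ... Unused.
#' @return Data frame with `clone`, `ebv`, `pev`, `ci_low`, `ci_high`.
#' @export
predict.diallel_blup <- function(object, clones = NULL, level = 0.95, ...) {
  cl <- clones %||% names(object$ebv)
  bad <- setdiff(cl, names(object$ebv))
  if (length(bad) > 0)
    stop("unknown clones: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  hw <- z * sqrt(object$pev[cl])
  data.frame(clone = cl, ebv = unname(object$ebv[cl]),
             pev = unname(object$pev[cl]),
             ci_low = unname(object$ebv[cl] - hw),
             ci_high = unname(object$ebv[cl] + hw),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
fitted.diallel_blup <- function(object, ...) {
  object$obs$value - residuals.diallel_blup(object)
}

#' @export
residuals.diallel_blup <- function(object, ...) {
  yhat <- as.numeric(object$X %*% object$beta) +
    object$ebv[object$obs$clone]
  if (!is.null(object$line_effects)) {
    key <- if (any(grepl(":", names(object$line_effects), fixed = TRUE)))
      paste(object$obs$clone, object$obs$year, sep = ":") else object$obs$clone
    yhat <- yhat + object$line_effects[key]
  }
  if (!is.null(object$family_effects)) {
    fk <- object$obs$family_key
    if (is.null(fk)) {
      fe <- rep(0, nrow(object$obs))
    } else fe <- ifelse(is.na(fk), 0, object$family_effects[fk])
    yhat <- yhat + fe
  }
  unname(object$obs$value - yhat)
}

#' @export
plot.diallel_blup <- function(x, clones = NULL, level = 0.95, ...) {
  pr <- predict(x, clones = clones, level = level)
  pr <- pr[order(pr$ebv), ]
  idx <- seq_len(nrow(pr))
  graphics::plot(pr$ebv, idx, xlim = range(pr$ci_low, pr$ci_high), yaxt = "n",
                 xlab = paste("EBV,", x$trait), ylab = "", pch = 19, ...)
  graphics::segments(pr$ci_low, idx, pr$ci_high, idx)
  graphics::axis(2, at = idx, labels = pr$clone, las = 2, cex.axis = 0.6)
  invisible(pr)
}
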