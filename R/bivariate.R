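#' Bivariate diallel mixed model and trait correlations
#'
#' Fits the two-trait analogue of the diallel model by AI-REML: stacked
#' phenotypes with trait-specific fixed effects, additive effects distributed
#' \eqn{N(0, M \otimes C)} with an unstructured 2x2 additive covariance C,
#' analogous 2x2 line and family covariances, and a 2x2 residual covariance
#' applied to records of the two traits from the same plot context
#' (clone-year-replicate). When the traits share no plot context (e.g.
#' recorded in disjoint years) the residual covariance is not estimable: it
#' is fixed at 0 and flagged, and the phenotypic correlation is reported as
#' undefined.
#'
#' @inheritParams diallel_blup
#' @param traits Character vector of the two trait names.
#' @param line Include line effects: `TRUE` uses a shared 2x2 line covariance
#'   when both traits are replicated; a trait without replicates
#'   automatically drops its line effect.
#' @return Object of class `"diallel_blup2"` with 2x2 covariance matrices
#'   `C_a`, `C_l`, `C_f`, `C_e` (with standard errors from the inverse AI
#'   matrix), the stacked fit metadata and the estimability flag
#'   `resid_cov_estimable`.
#' @seealso [genetic_correlation()], [phenotypic_correlation()]
#' @export
diallel_blup2 <- function(pheno, kinship, traits, pedigree = NULL,
                          fixed = NULL, line = TRUE, line_by_year = FALSE,
                          family = TRUE, start = NULL, maxit = 100,
                          tol = 1e-8, verbose = FALSE) {
  stopifnot(length(traits) == 2)
  d1 <- .build_design(pheno, traits[1], kinship, pedigree, fixed,
                      line = FALSE, family = FALSE)
  d2 <- .build_design(pheno, traits[2], kinship, pedigree, fixed,
                      line = FALSE, family = FALSE)
  n1 <- length(d1$y); n2 <- length(d2$y); n <- n1 + n2
  y <- c(d1$y, d2$y)
  X <- rbind(cbind(d1$X, matrix(0, n1, ncol(d2$X))),
             cbind(matrix(0, n2, ncol(d1$X)), d2$X))
  ids <- d1$meta$ids
  q <- length(ids)

  ## additive term: columns (trait1 levels, trait2 levels)
  Za1 <- d1$terms$additive$Z
  Za2 <- d2$terms$additive$Z
  Za <- rbind(cbind(Za1, Za1 * 0), cbind(Za2 * 0, Za2))
  at <- d1$terms$additive
  terms <- list(.reml_term("additive", Za, q = q, nt = 2, K = at$K,
                           Kinv = at$Kinv, ldetK = at$ldetK))

  has_rep <- function(d) any(duplicated(d$obs$clone))
  rep1 <- has_rep(d1); rep2 <- has_rep(d2)
  if (line && rep1 && rep2) {
    lids <- sort(unique(c(d1$obs$clone, d2$obs$clone)))
    mkZ <- function(d) Matrix::sparseMatrix(
      i = seq_len(nrow(d$obs)), j = match(d$obs$clone, lids), x = 1,
      dims = c(nrow(d$obs), length(lids)))
    Zl1 <- mkZ(d1); Zl2 <- mkZ(d2)
    Zl <- rbind(cbind(Zl1, Zl1 * 0), cbind(Zl2 * 0, Zl2))
    terms <- c(terms, list(.reml_term("line", Zl, q = length(lids), nt = 2)))
  } else if (line && (rep1 || rep2)) {
    ## only one trait replicated: single-trait line variance
    dd <- if (rep1) d1 else d2
    lids <- sort(unique(dd$obs$clone))
    Zl0 <- Matrix::sparseMatrix(i = seq_len(nrow(dd$obs)),
                                j = match(dd$obs$clone, lids), x = 1,
                                dims = c(nrow(dd$obs), length(lids)))
    zero <- function(nn) Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(nn, length(lids)))
    Zl <- if (rep1) rbind(Zl0, zero(n2)) else rbind(zero(n1), Zl0)
    terms <- c(terms, list(.reml_term("line", Zl, q = length(lids), nt = 1)))
  }

  if (family && !is.null(pedigree)) {
    fk <- family_key(pedigree)
    fam1 <- fk[d1$obs$clone]; fam2 <- fk[d2$obs$clone]
    flev <- sort(unique(c(fam1[!is.na(fam1)], fam2[!is.na(fam2)])))
    if (length(flev) > 0) {
      mkF <- function(fam, nn) {
        has <- !is.na(fam)
        Matrix::sparseMatrix(i = which(has), j = match(fam[has], flev), x = 1,
                             dims = c(nn, length(flev)))
      }
      Zf1 <- mkF(fam1, n1); Zf2 <- mkF(fam2, n2)
      Zf <- rbind(cbind(Zf1, Zf1 * 0), cbind(Zf2 * 0, Zf2))
      terms <- c(terms, list(.reml_term("family", Zf, q = length(flev), nt = 2)))
    }
  }

  ## residual pairing on shared plot context
  key1 <- paste(d1$obs$clone, d1$obs$year %||% 1, d1$obs$replicate %||% 1)
  key2 <- paste(d2$obs$clone, d2$obs$year %||% 1, d2$obs$replicate %||% 1)
  m12 <- match(key1, key2)
  pair <- rep(NA_integer_, n)
  ok <- !is.na(m12) & !duplicated(m12)
  pair[which(ok)] <- n1 + m12[ok]
  pair[n1 + m12[ok]] <- which(ok)
  est_cov <- sum(ok) >= 3
  if (!est_cov)
    message("no shared plot context between the traits; ",
            "residual covariance fixed at 0")
  resid <- list(nt = 2, trait = rep(1:2, c(n1, n2)), pair = pair,
                est_cov = est_cov)

  labels <- vapply(terms, `[[`, "", "label")
  npar_terms <- sum(vapply(terms, function(tm) if (tm$nt == 1) 1L else 3L, 1L))
  fixed_mask <- rep(FALSE, npar_terms + 3L)
  if (!est_cov) fixed_mask[npar_terms + 2L] <- TRUE

  fit <- .reml_ai_fit(y, X, terms, resid = resid, start = start,
                      maxit = maxit, tol = tol, fixed_mask = fixed_mask,
                      verbose = verbose)

  sp <- .split_theta(fit$theta, terms, 2)
  sp_se <- .split_theta(fit$se, terms, 2)
  mat_or_na <- function(lbl) {
    i <- which(labels == lbl)
    if (length(i) == 0) return(NULL)
    if (terms[[i]]$nt == 2) list(est = .cov2x2(sp[[i]]), se = .cov2x2(sp_se[[i]]))
    else list(est = sp[[i]][1], se = sp_se[[i]][1], single = TRUE,
              which_trait = if (has_rep(d1)) 1L else 2L)
  }
  ia <- which(labels == "additive")
  Ja <- fit$idx[[ia]]
  ebv <- matrix(fit$s[Ja], ncol = 2, dimnames = list(ids, traits))

  structure(list(
    traits = traits,
    kinship_kind = attr(kinship, "kind") %||% "unknown",
    C_a = mat_or_na("additive"),
    C_l = mat_or_na("line"),
    C_f = mat_or_na("family"),
    C_e = list(est = .cov2x2(sp$resid), se = .cov2x2(sp_se$resid)),
    resid_cov_estimable = est_cov,
    n_pairs = sum(ok),
    theta = fit$theta, AI = fit$AI, theta_labels = labels,
    m2ll = fit$m2ll, converged = fit$converged,
    ebv = ebv, n = c(n1, n2),
    call = match.call()),
    class = "diallel_blup2")
}

#' @export
print.diallel_blup2 <- function(x, ...) {
  cat("Bivariate diallel mixed model (", x$kinship_kind, "-matrix), traits: ",
      paste(x$traits, collapse = " & "), "\n", sep = "")
  cat("  -2 log L:", format(x$m2ll, digits = 8),
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  show2 <- function(lbl, b) {
    if (is.null(b)) return()
    cat(lbl, ":\n")
    if (isTRUE(b$single)) cat("  (single-trait line variance)",
                              round(b$est, 4), "\n")
    else print(round(b$est, 4))
  }
  show2("Additive covariance", x$C_a)
  show2("Line covariance", x$C_l)
  show2("Family covariance", x$C_f)
  show2("Residual covariance", x$C_e)
  if (!x$resid_cov_estimable)
    cat("  residual covariance not estimable (no shared plot context)\n")
  rg <- genetic_correlation(x)
  cat(sprintf("Genetic correlation: %.3f [%.3f, %.3f]\n",
              rg$r, rg$ci_low, rg$ci_high))
  rp <- phenotypic_correlation(x)
  if (rp$defined) cat(sprintf("Phenotypic correlation: %.3f\n", rp$r))
  else cat("Phenotypic correlation: undefined\n")
  invisible(x)
}

## delta-method variance of r = c12/sqrt(c11 c22) from the AI inverse
.cor_ci <- function(cmat, Vtheta) {
  c11 <- cmat[1, 1]; c12 <- cmat[1, 2]; c22 <- cmat[2, 2]
  r <- c12 / sqrt(c11 * c22)
  grad <- c(-r / (2 * c11), 1 / sqrt(c11 * c22), -r / (2 * c22))
  v <- as.numeric(t(grad) %*% Vtheta %*% grad)
  se <- if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  list(r = r, se = se,
       ci_low = max(-1, r - 1.96 * se), ci_high = min(1, r + 1.96 * se))
}

#' Additive genetic correlation between two traits
#'
#' \eqn{r_g = C_{12} / \sqrt{C_{11} C_{22}}} from the 2x2 additive covariance
#' of a bivariate fit, with a delta-method 95% CI from the inverse AI matrix.
#'
#' @param fit2 A [diallel_blup2()] fit.
#' @return List with `r`, `se`, `ci_low`, `ci_high`, `kind`, `defined`.
#' @export
genetic_correlation <- function(fit2) {
  stopifnot(inherits(fit2, "diallel_blup2"))
  C <- fit2$C_a$est
  if (any(diag(C) <= 0))
    return(list(r = NA_real_, se = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, kind = "genetic", defined = FALSE))
  Vt <- tryCatch(solve(fit2$AI), error = function(e) NULL)
  ia <- which(fit2$theta_labels == "additive")
  pos <- .theta_positions(fit2)[["additive"]]
  Vsub <- if (is.null(Vt)) matrix(NA_real_, 3, 3) else Vt[pos, pos]
  out <- .cor_ci(C, Vsub)
  c(out, list(kind = "genetic", defined = TRUE))
}

## start positions of each structure's parameters in theta
.theta_positions <- function(fit2) {
  out <- list()
  k <- 0L
  for (i in seq_along(fit2$theta_labels)) {
    lbl <- fit2$theta_labels[i]
    np <- if (lbl == "line" && isTRUE(fit2$C_l$single)) 1L else 3L
    out[[lbl]] <- k + seq_len(np)
    k <- k + np
  }
  out$resid <- k + 1:3
  out
}

#' Phenotypic correlation between two traits
#'
#' Plug-in composition over the random-effect structures: the sum of the
#' additive, line, family and residual covariances over the geometric mean of
#' the two total phenotypic variances. The line covariance enters only when
#' both traits carry a line term; the correlation is undefined whenever the
#' residual covariance is not estimable (traits with no shared plot context).
#'
#' @param fit2 A [diallel_blup2()] fit.
#' @return List with `r`, `kind`, `defined`.
#' @export
phenotypic_correlation <- function(fit2) {
  stopifnot(inherits(fit2, "diallel_blup2"))
  if (!fit2$resid_cov_estimable)
    return(list(r = NA_real_, kind = "phenotypic", defined = FALSE))
  blocks <- list(fit2$C_a, fit2$C_f, fit2$C_e)
  if (!is.null(fit2$C_l) && !isTRUE(fit2$C_l$single))
    blocks <- c(blocks, list(fit2$C_l))
  cov12 <- sum(vapply(blocks, function(b) b$est[1, 2], numeric(1)))
  v1 <- sum(vapply(blocks, function(b) b$est[1, 1], numeric(1)))
  v2 <- sum(vapply(blocks, function(b) b$est[2, 2], numeric(1)))
  ## single-trait line variance still contributes to that trait's total
  if (!is.null(fit2$C_l) && isTRUE(fit2$C_l$single)) {
    if (fit2$C_l$which_trait == 1L) v1 <- v1 + fit2$C_l$est else v2 <- v2 + fit2$C_l$est
  }
  list(r = cov12 / sqrt(v1 * v2), kind = "phenotypic", defined = TRUE)
}
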