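#' Additive relationship matrix for autotetraploids
#'
#' Builds the tetrasomic numerator relationship matrix from a pedigree by the
#' recursive kinship rules for autotetraploids, parameterised by the rate of
#' double reduction. Writing \eqn{\phi_{ij}} for the coancestry (probability
#' that one allele drawn at random from i and one from j are identical by
#' descent) the recursions over a topologically ordered pedigree are
#' \deqn{\phi_{ij} = (\phi_{sj} + \phi_{dj})/2,}
#' \deqn{F_i = \gamma_s/6 + \gamma_d/6 + 2\phi_{sd}/3, \qquad
#'       \gamma_p = w + (1-w)F_p,}
#' where \eqn{F_i} is the probability that two distinct alleles of i are IBD,
#' \eqn{\gamma_p} the probability that the two alleles of a gamete from p are
#' IBD, and w the double-reduction rate. The additive relationship is
#' \eqn{A_{ij} = 4\phi_{ij}} with diagonal \eqn{A_{ii} = 1 + 3F_i}; unknown
#' parents are treated as unrelated non-inbred founders, so an outbred founder
#' has diagonal exactly 1.
#'
#' @param ped Pedigree data frame (columns `clone`, `sire`, `dam`).
#' @param double_reduction Double-reduction rate w in \[0, 1\] (default 0).
#' @return Dense symmetric matrix with clone ids as dimnames, in pedigree
#'   topological order; attributes `kind = "A"`, `ploidy = 4` and
#'   `double_reduction`.
#' @export
amat_tetra <- function(ped, double_reduction = 0) {
  w <- double_reduction
  if (!is.numeric(w) || length(w) != 1 || w < 0 || w > 1)
    stop("double_reduction must be a single value in [0, 1]", call. = FALSE)
  ped <- sort_pedigree(ped, check_cytoplasm = FALSE)
  n <- nrow(ped)
  ids <- ped$clone
  idx <- stats::setNames(seq_len(n), ids)
  si <- idx[ped$sire]
  di <- idx[ped$dam]

  phi <- matrix(0, n, n)          # coancestry
  Fi <- numeric(n)                # prob. two distinct alleles IBD
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      ps <- if (is.na(s)) 0 else phi[s, j]
      pd <- if (is.na(d)) 0 else phi[d, j]
      phi[i, j] <- (ps + pd) / 2
      phi[j, i] <- phi[i, j]
    }
    gam_s <- if (is.na(s)) w else w + (1 - w) * Fi[s]
    gam_d <- if (is.na(d)) w else w + (1 - w) * Fi[d]
    phi_sd <- if (is.na(s) || is.na(d)) 0 else phi[s, d]
    Fi[i] <- if (is.na(s) && is.na(d)) 0 else
      gam_s / 6 + gam_d / 6 + 2 * phi_sd / 3
    phi[i, i] <- 1 / 4 + 3 / 4 * Fi[i]
  }
  A <- 4 * phi
  dimnames(A) <- list(ids, ids)
  attr(A, "kind") <- "A"
  attr(A, "ploidy") <- 4
  attr(A, "double_reduction") <- w
  A
}

#' Pedigree or genomic inbreeding coefficient
#'
#' For a relationship matrix K of an autopolyploid population the population
#' inbreeding coefficient is `(mean(diag(K)) - 1) / (ploidy - 1)`.
#'
#' @param K Relationship matrix (A, A22, G, ...).
#' @param ploidy Ploidy level (default 4).
#' @return A list with the coefficient `F` and the `source` matrix kind.
#' @export
inbreeding_coef <- function(K, ploidy = 4) {
  f <- (mean(diag(K)) - 1) / (ploidy - 1)
  list(F = f, source = attr(K, "kind") %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tetraploid VanRaden genomic relationship matrix
#'
#' Computes the genomic relationship matrix from biallelic allele dosages on
#' the 0-4 scale (non-integer allele-frequency dosages allowed). Missing
#' entries are imputed to the observed marker mean; allele frequencies p are
#' taken from the non-missing entries; dosages are centred as Z = dosage - 4p
#' and \deqn{G = ZZ' / (4\sum_j p_j(1-p_j)),} the ploidy-4 scaling of the
#' VanRaden denominator.
#'
#' @param dosage Clones x markers numeric matrix with rownames, entries in
#'   \[0, 4\] or NA.
#' @param min_maf Markers with minor allele frequency at or below this are
#'   dropped (default 0.01).
#' @param allele_freq Optional vector of reference allele frequencies (one
#'   per marker, e.g. base-population/founder frequencies); the default uses
#'   the observed frequencies of the genotyped sample. With base-population
#'   frequencies E\[G\] equals the pedigree relationship matrix.
#' @return Symmetric matrix over the clones with attribute `kind = "G"`.
#' @export
gmat_vanraden <- function(dosage, min_maf = 0.01, allele_freq = NULL) {
  M <- as.matrix(dosage)
  if (is.null(rownames(M))) stop("dosage matrix needs clone rownames", call. = FALSE)
  if (nrow(M) < 2) stop("need at least 2 clones", call. = FALSE)
  rng <- range(M, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 4)
    stop("dosages must lie in [0, 4]", call. = FALSE)
  p <- if (is.null(allele_freq)) colMeans(M, na.rm = TRUE) / 4 else allele_freq
  if (length(p) != ncol(M))
    stop("allele_freq must have one entry per marker", call. = FALSE)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > min_maf
  if (!any(keep))
    stop("degenerate input: no polymorphic markers after MAF filtering",
         call. = FALSE)
  M <- M[, keep, drop = FALSE]
  p <- p[keep]
  ## mean imputation of missing dosages
  if (anyNA(M)) {
    mu <- 4 * p
    na_idx <- which(is.na(M), arr.ind = TRUE)
    M[na_idx] <- mu[na_idx[, 2]]
  }
  Z <- sweep(M, 2, 4 * p)
  denom <- 4 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  attr(G, "kind") <- "G"
  attr(G, "ploidy") <- 4
  G
}

#' Rescale G to the pedigree scale of the genotyped clones
#'
#' Multiplies every entry of G by `mean(diag(A22)) / mean(diag(G))` so the
#' mean diagonal of the adjusted genomic matrix equals that of the pedigree
#' relationship matrix of the genotyped clones. The operation is idempotent.
#'
#' @param G Genomic relationship matrix of the genotyped clones.
#' @param A22 Pedigree relationship matrix restricted to the same clones, in
#'   the same order.
#' @return The rescaled matrix with attribute `kind = "G_adj"`.
#' @export
adjust_g_scale <- function(G, A22) {
  if (is.null(rownames(G)) || is.null(rownames(A22)) ||
      !identical(rownames(G), rownames(A22)))
    stop("G and A22 must be indexed by the same clones in the same order",
         call. = FALSE)
  Gadj <- G * (mean(diag(A22)) / mean(diag(G)))
  attr(Gadj, "kind") <- "G_adj"
  attr(Gadj, "ploidy") <- attr(G, "ploidy") %||% 4
  Gadj
}

#' Single-step H matrix (pedigree-genomic blend)
#'
#' Combines a pedigree relationship matrix A over all clones with a (scale
#' adjusted) genomic matrix of the genotyped subset. At the default
#' tau = omega = 1 the direct block identity is used:
#' \deqn{H = A + \begin{pmatrix}
#'   A_{12}A_{22}^{-1}\Delta A_{22}^{-1}A_{21} & A_{12}A_{22}^{-1}\Delta\\
#'   \Delta A_{22}^{-1}A_{21} & \Delta \end{pmatrix},
#'   \quad \Delta = G_{adj} - A_{22},}
#' so H equals A except in blocks involving genotyped clones. For general
#' tau/omega the blended inverse
#' \eqn{H^{-1} = A^{-1} + \mathrm{blockdiag}(0,\; \tau G_{adj}^{-1} -
#' \omega A_{22}^{-1})} is formed and inverted back.
#'
#' @param A Pedigree relationship matrix over all clones.
#' @param G_adj Scale-adjusted genomic matrix over the genotyped clones.
#' @param genotyped Character vector of genotyped clone ids (defaults to the
#'   rownames of `G_adj`).
#' @param tau,omega Blending weights (default 1, the standard single-step
#'   scaling).
#' @param jitter Ridge added to near-singular A22/G before inversion, with a
#'   warning (default 1e-8).
#' @return H matrix over all clones of A (genotyped clones last), attribute
#'   `kind = "H"`.
#' @export
hmat_single_step <- function(A, G_adj, genotyped = rownames(G_adj),
                             tau = 1, omega = 1, jitter = 1e-8) {
  ids <- rownames(A)
  if (!all(genotyped %in% ids))
    stop("genotyped ids must be a subset of A's clones", call. = FALSE)
  G_adj <- G_adj[genotyped, genotyped, drop = FALSE]
  ng <- setdiff(ids, genotyped)
  ord <- c(ng, genotyped)
  A <- A[ord, ord, drop = FALSE]
  i1 <- seq_along(ng)
  i2 <- length(ng) + seq_along(genotyped)
  A22 <- A[i2, i2, drop = FALSE]
  A22i <- .safe_solve(A22, jitter, "A22")

  if (tau == 1 && omega == 1) {
    D <- G_adj - A22
    H <- A
    if (length(i1) > 0) {
      A12 <- A[i1, i2, drop = FALSE]
      B <- A12 %*% A22i            # n1 x n2
      H[i1, i1] <- H[i1, i1] + B %*% D %*% t(B)
      H[i1, i2] <- H[i1, i2] + B %*% D
      H[i2, i1] <- t(H[i1, i2])
    }
    H[i2, i2] <- G_adj
  } else {
    Ai <- .safe_solve(A, jitter, "A")
    Gi <- .safe_solve(G_adj, jitter, "G_adj")
    Hi <- Ai
    Hi[i2, i2] <- Hi[i2, i2] + tau * Gi - omega * A22i
    H <- .safe_solve(Hi, jitter, "H inverse")
    dimnames(H) <- dimnames(A)
  }
  H <- (H + t(H)) / 2
  attr(H, "kind") <- "H"
  attr(H, "ploidy") <- attr(A, "ploidy") %||% 4
  attr(H, "tau") <- tau
  attr(H, "omega") <- omega
  H
}

.safe_solve <- function(M, jitter, label) {
  out <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(out)) {
    warning("singular ", label, "; regularized with jitter ", jitter)
    out <- tryCatch(solve(M + diag(jitter, nrow(M))), error = function(e) NULL)
    if (is.null(out))
      stop("numerical error: ", label, " not invertible even after jitter",
           call. = FALSE)
  }
  dimnames(out) <- dimnames(M)
  out
}

#' Clip a covariance matrix to positive semi-definite
#'
#' Eigenvalues below `-tol` trigger a warning and are clipped to zero; small
#' negative eigenvalues within tolerance are silently clipped.
#'
#' @param K Symmetric matrix.
#' @param tol Tolerance for negative eigenvalues (default 1e-8).
#' @return The PSD-projected matrix (attributes preserved).
#' @export
psd_clip <- function(K, tol = 1e-8) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) >= 0) return(K)
  if (min(e$values) < -tol * max(abs(e$values), 1))
    warning("matrix had eigenvalues below -tol; clipped to PSD")
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  dimnames(out) <- dimnames(K)
  for (a in c("kind", "ploidy", "double_reduction", "tau", "omega"))
    attr(out, a) <- attr(K, a)
  out
}
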