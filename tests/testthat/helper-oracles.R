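## Independent oracles used across the test files. These never call the code
## paths they check.

## Monte-Carlo gene-dropping estimate of the tetrasomic additive relationship
## matrix: unique labels on every founder allele are dropped through the
## pedigree (per-gamete, two distinct homologs unless double reduction) and
## A_ij is estimated as 4 x the allele-sharing probability.
gene_drop_A <- function(ped, w = 0, nrep = 1e5) {
  ped <- sort_pedigree(ped, check_cytoplasm = FALSE)
  n <- nrow(ped)
  ids <- ped$clone
  idx <- stats::setNames(seq_len(n), ids)
  lab <- vector("list", n)
  nf <- 0L
  gam <- function(P) {
    j1 <- sample.int(4, nrep, replace = TRUE)
    dr <- stats::runif(nrep) < w
    j2 <- ifelse(dr, j1, ((j1 - 1L + sample.int(3, nrep, TRUE)) %% 4L) + 1L)
    cbind(P[cbind(seq_len(nrep), j1)], P[cbind(seq_len(nrep), j2)])
  }
  for (i in seq_len(n)) {
    s <- idx[ped$sire[i]]; d <- idx[ped$dam[i]]
    if (is.na(s)) {
      gs <- matrix(c(nf + 1L, nf + 2L), nrep, 2, byrow = TRUE); nf <- nf + 2L
    } else gs <- gam(lab[[s]])
    if (is.na(d)) {
      gd <- matrix(c(nf + 1L, nf + 2L), nrep, 2, byrow = TRUE); nf <- nf + 2L
    } else gd <- gam(lab[[d]])
    lab[[i]] <- cbind(gs, gd)
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    m <- 0
    for (a in 1:4) for (b in 1:4)
      m <- m + mean(lab[[i]][, a] == lab[[j]][, b])
    A[i, j] <- A[j, i] <- m / 4
  }
  A
}

## -2 x restricted log likelihood by direct V inversion
m2ll_direct <- function(y, X, V) {
  n <- length(y)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  as.numeric((n - qr(X)$rank) * log(2 * pi) + determinant(V)$modulus +
               determinant(XVX)$modulus + t(y) %*% P %*% y)
}

## GLS fixed effects and BLUP breeding values by brute-force V inversion
gls_blup <- function(y, X, Z, K, s2a, V) {
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- s2a * K %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(beta = drop(b), ebv = drop(a))
}

## small reference pedigree: 3 founders, two full-sib matings, one selfing
toy_pedigree <- function() {
  data.frame(clone = c("P", "Q", "R", "S1", "S2", "X", "Y"),
             sire = c(NA, NA, NA, "P", "P", "S1", "X"),
             dam = c(NA, NA, NA, "Q", "Q", "S2", "X"),
             stringsAsFactors = FALSE)
}

## quick simulated dataset for fitting tests
quick_sim <- function(seed = 1, n_parents = 6, off = 8, ...) {
  cfg <- sim_config(n_parents = n_parents, offspring_per_family = off,
                    drop_fraction = 0.25, n_markers = 150,
                    genotyped_fraction = 0.3, ...)
  sim_diallel(cfg, seed = seed)
}
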