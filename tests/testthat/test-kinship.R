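test_that("founder-only pedigrees give the identity matrix", {
  ped <- data.frame(clone = letters[1:4], sire = NA, dam = NA)
  A <- amat_tetra(ped)
  expect_equal(unclass(A), diag(4), ignore_attr = TRUE)
  expect_equal(inbreeding_coef(A)$F, 0)
})

test_that("pedigree sorting flags cycles, orphans and cytoplasm violations", {
  expect_error(sort_pedigree(data.frame(clone = c("a", "b"), sire = c("b", "a"),
                                        dam = NA)), "cycle")
  expect_error(sort_pedigree(data.frame(clone = "a", sire = "zz", dam = NA)),
               "absent")
  bad <- data.frame(clone = c("m", "k"), sire = c(NA, NA), dam = c(NA, "m"),
                    cytoplasm = c("T", "D"))
  expect_error(sort_pedigree(bad), "maternally")
  ## offspring listed before parents gets reordered
  ped <- data.frame(clone = c("kid", "p", "q"), sire = c("p", NA, NA),
                    dam = c("q", NA, NA))
  sp <- sort_pedigree(ped)
  expect_equal(sp$clone, c("p", "q", "kid"))
  expect_equal(sp$generation, c(0L, 0L, 1L))
})

test_that("tetrasomic A matches first-principles values and gene dropping", {
  ped <- toy_pedigree()
  A <- amat_tetra(ped, double_reduction = 0)
  ## parent-offspring and full-sib relationships for outbred parents
  expect_equal(A["S1", "P"], 0.5)
  expect_equal(A["S1", "S2"], 0.5)
  expect_equal(A["P", "P"], 1)
  expect_equal(A["P", "Q"], 0)
  ## full-sib mating: offspring X is inbred, diagonal 1 + 3F
  expect_gt(A["X", "X"], 1)
  set.seed(7)
  Ag <- gene_drop_A(ped, w = 0, nrep = 2e4)
  expect_lt(max(abs(A - Ag)), 0.03)
  set.seed(8)
  Ag1 <- gene_drop_A(ped, w = 0.1, nrep = 2e4)
  expect_lt(max(abs(amat_tetra(ped, 0.1) - Ag1)), 0.03)
})

test_that("double reduction never decreases the diagonal of selfed progeny", {
  ped <- data.frame(clone = c("p", "s1", "s2"), sire = c(NA, "p", "s1"),
                    dam = c(NA, "p", "s1"))
  dg <- sapply(seq(0, 1, by = 0.1), function(w)
    diag(amat_tetra(ped, w))[c("s1", "s2")])
  expect_true(all(diff(dg["s1", ]) >= 0))
  expect_true(all(diff(dg["s2", ]) >= 0))
  expect_error(amat_tetra(ped, -0.1), "double_reduction")
  expect_error(amat_tetra(ped, 1.2), "double_reduction")
})

test_that("pedigree inbreeding follows (mean diagonal - 1)/(ploidy - 1)", {
  ped <- toy_pedigree()
  A <- amat_tetra(ped)
  expect_equal(inbreeding_coef(A)$F, (mean(diag(A)) - 1) / 3)
  ## forced arithmetic: mean diagonal 1.0006 -> F = 0.0002
  M <- diag(c(1.0012, 1.0000, 1.0006)); dimnames(M) <- list(1:3, 1:3)
  expect_equal(inbreeding_coef(M)$F, 0.0002, tolerance = 1e-12)
})

test_that("tetraploid VanRaden G matches the closed form", {
  D <- rbind(c(0, 4), c(2, 2), c(4, 1))
  rownames(D) <- c("a", "b", "c")
  G <- gmat_vanraden(D, min_maf = 0)
  p <- colMeans(D) / 4
  Z <- sweep(D, 2, 4 * p)
  expect_equal(unclass(G), Z %*% t(Z) / (4 * sum(p * (1 - p))),
               ignore_attr = TRUE)
  ## identical rows give identical entries
  D2 <- rbind(x = c(1, 3, 0), y = c(1, 3, 0), z = c(3, 1, 4))
  G2 <- gmat_vanraden(D2, min_maf = 0)
  expect_equal(G2["x", "x"], G2["x", "y"])
  expect_equal(G2["x", "x"], G2["y", "y"])
  ## genomic inbreeding is definitionally tied to the mean diagonal
  expect_equal(inbreeding_coef(G2)$F, (mean(diag(G2)) - 1) / 3)
  expect_error(gmat_vanraden(rbind(a = c(0, 0), b = c(0, 0))), "degenerate")
})

test_that("missing dosages are mean-imputed before centring", {
  set.seed(2)
  D <- matrix(rbinom(60, 4, 0.4), 6, 10,
              dimnames = list(paste0("c", 1:6), NULL))
  Dm <- D; Dm[sample(60, 12)] <- NA
  G <- gmat_vanraden(Dm, min_maf = 0)
  expect_true(isSymmetric(unclass(G)))
  ## imputing to the marker mean leaves the marker contribution centred
  Dexp <- Dm
  for (j in 1:10) Dexp[is.na(Dexp[, j]), j] <- mean(Dm[, j], na.rm = TRUE)
  p <- colMeans(Dm, na.rm = TRUE) / 4
  Z <- sweep(Dexp, 2, 4 * p)
  expect_equal(unclass(G), Z %*% t(Z) / (4 * sum(p * (1 - p))),
               ignore_attr = TRUE)
})

test_that("G-to-A22 scale adjustment is exact and idempotent", {
  set.seed(3)
  B <- matrix(rnorm(25), 5, 5); G <- crossprod(B) / 5 + diag(0.1, 5)
  dimnames(G) <- list(paste0("g", 1:5), paste0("g", 1:5))
  A22 <- diag(1.045, 5); dimnames(A22) <- dimnames(G)
  Gadj <- adjust_g_scale(G, A22)
  expect_equal(mean(diag(Gadj)), mean(diag(A22)), tolerance = 1e-12)
  expect_equal(unclass(Gadj), unclass(G) * mean(diag(A22)) / mean(diag(G)),
               ignore_attr = TRUE)
  expect_equal(unclass(adjust_g_scale(Gadj, A22)), unclass(Gadj),
               ignore_attr = TRUE)
  expect_error(adjust_g_scale(G, diag(4)), "same clones")
})

test_that("single-step H reduces to A when G carries no new information", {
  ped <- toy_pedigree()
  A <- amat_tetra(ped)
  gids <- c("S1", "S2", "X")
  A22 <- A[gids, gids]
  H <- hmat_single_step(A, A22, gids)
  expect_lt(max(abs(H[rownames(A), colnames(A)] - A)), 1e-10)
  ## all clones genotyped: H equals G_adj
  Gall <- A * 1.02
  attr(Gall, "kind") <- "G_adj"
  Hall <- hmat_single_step(A, Gall, rownames(A))
  expect_lt(max(abs(Hall[rownames(A), rownames(A)] - Gall)), 1e-10)
})

test_that("H matches the brute-force block identity and preserves A blocks", {
  ped <- data.frame(clone = c("p", "q", "k1", "k2", "u"),
                    sire = c(NA, NA, "p", "p", NA),
                    dam = c(NA, NA, "q", "q", NA))
  A <- amat_tetra(ped)
  gids <- c("k1", "k2")
  A22 <- A[gids, gids]
  set.seed(4)
  Gadj <- A22 + crossprod(matrix(rnorm(4), 2)) * 0.05
  dimnames(Gadj) <- dimnames(A22)
  H <- hmat_single_step(A, Gadj, gids)
  ## brute force block evaluation
  ng <- setdiff(rownames(A), gids)
  A12 <- A[ng, gids]; A22i <- solve(A22); D <- Gadj - A22
  Hexp <- A[c(ng, gids), c(ng, gids)]
  Hexp[ng, ng] <- Hexp[ng, ng] + A12 %*% A22i %*% D %*% A22i %*% t(A12)
  Hexp[ng, gids] <- Hexp[ng, gids] + A12 %*% A22i %*% D
  Hexp[gids, ng] <- t(Hexp[ng, gids])
  Hexp[gids, gids] <- Gadj
  expect_lt(max(abs(H[rownames(Hexp), colnames(Hexp)] - Hexp)), 1e-10)
  expect_true(isSymmetric(unclass(H)))
  ## clone u has no genotyped relatives: its A entries are untouched
  expect_equal(H["u", "u"], A["u", "u"])
  expect_equal(H["u", "p"], A["u", "p"])
  ## general tau/omega route agrees with the direct route at tau = omega = 1
  H2 <- hmat_single_step(A, Gadj, gids, tau = 1 + 1e-12, omega = 1)
  expect_lt(max(abs(H2[rownames(H), colnames(H)] - H)), 1e-6)
})

test_that("PSD clipping floors negative eigenvalues", {
  M <- diag(c(1, 1, -0.5))
  dimnames(M) <- list(1:3, 1:3)
  expect_warning(Mc <- psd_clip(M), "clipped")
  expect_gte(min(eigen(Mc, symmetric = TRUE)$values), 0)
  I3 <- diag(3); dimnames(I3) <- list(1:3, 1:3)
  expect_identical(psd_clip(I3), I3)
})
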