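test_that("founder simulation: labels, frequencies and effect scaling", {
  cfg <- sim_config(n_parents = 2, n_markers = 1)
  set.seed(1)
  fo <- simulate_founders(cfg)
  expect_equal(dim(fo$genomes), c(2, 4, 1))   # 2 founders x 4 homologs
  ## per-marker founder dosage variance approximates 4p(1-p)
  cfg2 <- sim_config(n_parents = 2, n_markers = 60)
  set.seed(2)
  fo2 <- simulate_founders(cfg2, n_founders = 3000)
  dos <- apply(fo2$genomes, c(1, 3), sum)
  ratio <- apply(dos, 2, var) / (4 * fo2$freq * (1 - fo2$freq))
  expect_lt(abs(mean(ratio) - 1), 0.05)
  ## breeding-value variance matches the configured additive variance
  cfg3 <- sim_config(n_parents = 2, n_markers = 400)
  set.seed(3)
  fo3 <- simulate_founders(cfg3, n_founders = 5000)
  dos3 <- apply(fo3$genomes, c(1, 3), sum)
  a <- drop(scale(dos3, scale = FALSE) %*% fo3$effects)
  s2a <- cfg3$traits[[1]]$vc[["sigma2_a"]]
  expect_lt(abs(var(a) / s2a - 1), 0.05)
})

test_that("gamete formation respects the double-reduction rate", {
  g <- matrix(0:1, 4, 1000)   # any genome; homolog attr carries the labels
  set.seed(4)
  h0 <- attr(make_gamete(g, w = 0), "homolog")
  expect_true(all(h0[1, ] != h0[2, ]))
  h1 <- attr(make_gamete(g, w = 1), "homolog")
  expect_true(all(h1[1, ] == h1[2, ]))
  g2 <- matrix(0, 4, 10000)
  hw <- attr(make_gamete(g2, w = 0.1), "homolog")
  frac <- mean(hw[1, ] == hw[2, ])
  expect_lt(abs(frac - 0.1), 0.012)
})

test_that("cross plan obeys sterility, counting and maternal cytoplasm", {
  parents <- data.frame(clone = paste0("P", 1:6),
                        cytoplasm = c("W/g", "T/b", "T/b", "D", "D", "T/b"),
                        male_sterile = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  cfg <- sim_config(n_parents = 6, drop_fraction = 0)
  set.seed(5)
  plan <- sim_cross_plan(parents, cfg)
  expect_true(all(plan$sire == "P6"))     # the only fertile sire
  ## permitted unordered pairs: C(6,2) minus pairs of two steriles
  expect_equal(nrow(plan), choose(6, 2) - choose(5, 2))
  ## impossible configuration
  parents$male_sterile <- TRUE
  expect_error(sim_cross_plan(parents, cfg), "no fertile cross")
  ## full simulation: offspring cytoplasm always equals the dam's
  sim <- quick_sim(seed = 6)
  ped <- sim$pedigree
  kids <- !is.na(ped$dam)
  dam_cyt <- ped$cytoplasm[match(ped$dam[kids], ped$clone)]
  expect_equal(ped$cytoplasm[kids], dam_cyt)
  ## W-type parents never appear as sire
  wpar <- ped$clone[grepl("^W", ped$cytoplasm) & is.na(ped$sire)]
  expect_false(any(ped$sire %in% wpar))
})

test_that("degenerate configuration returns the pure mean", {
  cfg <- sim_config(n_parents = 4, offspring_per_family = 3,
                    drop_fraction = 0, n_markers = 10, block_sd = 0,
                    traits = list(list(name = "t", mu = 7,
                                       vc = c(sigma2_a = 0, sigma2_l = 0,
                                              sigma2_f = 0, sigma2_e = 0),
                                       cyto = NULL)))
  sim <- sim_diallel(cfg, seed = 7)
  expect_true(all(abs(sim$pheno$value - 7) < 1e-10))
})

test_that("within-family breeding-value variance is half the additive variance", {
  ## single family with many offspring; Mendelian sampling under tetrasomy
  cfg <- sim_config(n_parents = 2, offspring_per_family = 1500,
                    drop_fraction = 0, n_markers = 400, block_sd = 0,
                    genotyped_fraction = 0,
                    traits = list(list(name = "t", mu = 0,
                                       vc = c(sigma2_a = 2, sigma2_l = 0,
                                              sigma2_f = 0, sigma2_e = 0),
                                       cyto = NULL)))
  sim <- sim_diallel(cfg, seed = 8)
  kids <- sim$pedigree$clone[!is.na(sim$pedigree$sire)]
  wf <- var(sim$truth$bv[kids, 1])
  expect_lt(abs(wf / (2 / 2) - 1), 0.15)
})

test_that("family effects propagate exactly and match their variance", {
  cfg <- sim_config(n_parents = 10, offspring_per_family = 6,
                    drop_fraction = 0.2, n_markers = 20, block_sd = 0,
                    n_rep = 1, parent_reps = 0,
                    traits = list(list(name = "t", mu = 0,
                                       vc = c(sigma2_a = 0, sigma2_l = 0,
                                              sigma2_f = 1.5, sigma2_e = 0),
                                       cyto = NULL)))
  sim <- sim_diallel(cfg, seed = 9)
  ## with only the family variance active, records equal the family effect
  fk <- family_key(sim$pedigree)
  fam_of_rec <- fk[sim$pheno$clone]
  expect_equal(unname(sim$pheno$value),
               unname(sim$truth$family[fam_of_rec, 1]), tolerance = 1e-10)
  ## method-of-moments: the family-mean variance estimates sigma2_f
  fm <- tapply(sim$pheno$value, fam_of_rec, mean)
  nf <- length(fm)
  expect_lt(abs(var(fm) - 1.5), 2 * 1.5 * sqrt(2 / (nf - 1)))
})

test_that("export/import round-trips byte-identically with the right missingness", {
  cfg <- sim_config(n_parents = 8, offspring_per_family = 10,
                    drop_fraction = 0.3, n_markers = 300,
                    genotyped_fraction = 0.5, missing_rate = 0.17)
  sim <- sim_diallel(cfg, seed = 10)
  expect_lt(abs(mean(is.na(sim$dosage)) - 0.17), 0.01)
  d1 <- file.path(tempdir(), "simx1"); d2 <- file.path(tempdir(), "simx2")
  sim_export(sim, d1)
  back <- list(pedigree = read_pedigree(file.path(d1, "pedigree.csv")),
               pheno = read_phenotypes(file.path(d1, "phenotypes.csv")),
               dosage = read_dosage(file.path(d1, "dosages.tsv")),
               truth = sim$truth)
  ## values survive the round trip exactly
  expect_equal(back$pheno$value, sim$pheno$value, tolerance = 0)
  expect_equal(back$dosage, sim$dosage)
  ## re-export is byte-identical
  sim2 <- sim
  sim2$pedigree <- back$pedigree[, names(sim$pedigree)]
  sim2$pheno <- back$pheno
  sim2$dosage <- back$dosage
  sim_export(sim2, d2)
  for (f in c("pedigree.csv", "phenotypes.csv", "dosages.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  ## truth lists every clone exactly once
  tj <- jsonlite::read_json(file.path(d1, "truth.json"), simplifyVector = TRUE)
  expect_equal(sort(tj$clones), sort(sim$pedigree$clone))
  expect_equal(anyDuplicated(tj$clones), 0L)
})

test_that("realized allele sharing matches the pedigree A matrix", {
  ## keystone cross-module check: average realized relationship among many
  ## full sibs equals the A entry within Monte-Carlo error
  cfg <- sim_config(n_parents = 12, offspring_per_family = 40,
                    drop_fraction = 0.5, n_markers = 600, block_sd = 0,
                    genotyped_fraction = 1, missing_rate = 0,
                    traits = list(list(name = "t", mu = 0,
                                       vc = c(sigma2_a = 1, sigma2_l = 0,
                                              sigma2_f = 0, sigma2_e = 0),
                                       cyto = NULL)))
  sim <- sim_diallel(cfg, seed = 12)
  A <- amat_tetra(sim$pedigree)
  ## G must be centred on base-population frequencies to estimate pedigree
  ## relationships (sample frequencies re-centre on the panel; frequencies
  ## estimated from few founders add a ~1/(n founders) upward bias), so the
  ## generator's true frequencies are the right reference here
  G <- gmat_vanraden(sim$dosage, min_maf = 0, allele_freq = sim$truth$freq)
  ## averaged realized (genomic) vs expected (pedigree) relationship within
  ## each of the three largest full-sib families
  fk <- family_key(sim$pedigree)
  fams <- names(sort(table(fk), decreasing = TRUE))[1:3]
  for (fam in fams) {
    kids <- names(fk)[!is.na(fk) & fk == fam]
    gsub <- G[kids, kids]; asub <- A[kids, kids]
    off <- upper.tri(gsub)
    expect_lt(abs(mean(gsub[off]) - mean(asub[off])), 0.06)
    expect_lt(abs(mean(diag(gsub)) - mean(diag(asub))), 0.08)
  }
  ## across the whole panel the two matrices agree strongly
  expect_gt(cor(A[upper.tri(A)], G[upper.tri(G)]), 0.85)
})
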