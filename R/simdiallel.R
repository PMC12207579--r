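#' Configuration for the tetrasomic diallel simulator
#'
#' Assembles and validates the generator settings. The defaults describe a
#' desk-scale incomplete diallel of elite tetraploid potato material: 12
#' parents with cytoplasm types T/beta, D and W/gamma at frequencies
#' 0.56/0.25/0.19, cytoplasmic male sterility of all W/gamma parents plus
#' additional steriles up to roughly 5/18 of the parents, roughly 40 fertile
#' families of 25 offspring each (~1000 clones), 500 independently
#' segregating biallelic markers, 17% missing genotype calls, and one
#' dry-matter-like trait with variance components
#' (additive 2.42, line 4.61, family 0.38, residual 0.70), population mean
#' 20.26 and cytoplasm shifts (T/beta -2.24, D -1.45) relative to W/gamma.
#'
#' @param n_parents Number of diallel parents.
#' @param offspring_per_family Full-sib family size.
#' @param drop_fraction Fraction of permitted crosses randomly dropped
#'   (infertile specific combinations).
#' @param n_markers Number of biallelic markers (independent segregation).
#' @param missing_rate Genotype missingness applied to exported dosages.
#' @param genotyped_fraction Fraction of offspring genotyped (parents are
#'   always genotyped).
#' @param double_reduction Double-reduction rate w used in gamete formation.
#' @param cyto_freq Named cytoplasm-type frequencies (must sum to 1; names
#'   starting with "W" are treated as male-sterile types).
#' @param sterile_target Expected fraction of male-sterile parents; non-W
#'   parents are added as steriles until this is reached.
#' @param traits List of trait specifications, each a list with `name`, `mu`,
#'   `vc` (named `sigma2_a`, `sigma2_l`, `sigma2_f`, `sigma2_e`) and optional
#'   `cyto` (named shifts per cytoplasm type).
#' @param r_g,r_l,r_f,r_e Between-trait correlations of marker effects, line,
#'   family and residual effects when two traits are simulated.
#' @param years,n_rep,block_size,block_sd Field layout: years, replicates per
#'   year, plots per block, standard deviation of block-by-year effects.
#' @param parent_reps Replicates of the parents planted as checks (0 = parents
#'   unphenotyped).
#' @param line_by_year Draw line effects independently per year (nested line).
#' @param freq_beta Shape parameters of the Beta distribution of founder
#'   allele frequencies (truncated to \[0.02, 0.98\]).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_parents = 12, offspring_per_family = 25,
                       drop_fraction = 0.35, n_markers = 500,
                       missing_rate = 0.17, genotyped_fraction = 0.15,
                       double_reduction = 0,
                       cyto_freq = c("T/b" = 0.56, "D" = 0.25, "W/g" = 0.19),
                       sterile_target = 5 / 18,
                       traits = list(list(
                         name = "dry_matter", mu = 20.26,
                         vc = c(sigma2_a = 2.42, sigma2_l = 4.61,
                                sigma2_f = 0.38, sigma2_e = 0.70),
                         cyto = c("T/b" = -2.24, "D" = -1.45, "W/g" = 0))),
                       r_g = 0.6, r_l = 0.2, r_f = 0.2, r_e = 0.2,
                       years = 1, n_rep = 2, block_size = 28, block_sd = 1,
                       parent_reps = 2, line_by_year = FALSE,
                       freq_beta = c(2, 2)) {
  stopifnot(n_parents >= 2, offspring_per_family >= 1, n_markers >= 1,
            missing_rate >= 0, missing_rate < 1,
            double_reduction >= 0, double_reduction <= 1,
            drop_fraction >= 0, drop_fraction < 1)
  if (abs(sum(cyto_freq) - 1) > 1e-8)
    stop("cytoplasm frequencies must sum to 1", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate founder genomes and marker effects
#'
#' Each founder carries 4 labelled homologs per marker; founder allele
#' frequencies are drawn from a Beta distribution and homolog alleles are
#' Bernoulli draws. Additive marker effects are drawn iid normal (bivariate
#' normal with correlation `r_g` for two traits) and rescaled so the expected
#' founder breeding-value variance under Hardy-Weinberg,
#' \eqn{\sum_j \alpha_j^2\, 4 p_j (1-p_j)}, equals the configured additive
#' variance of each trait.
#'
#' @param cfg A [sim_config()].
#' @param n_founders Number of founders (default `cfg$n_parents`).
#' @return List with `genomes` (array founders x 4 homologs x markers of 0/1
#'   alleles), `freq` (drawn allele frequencies) and `effects` (markers x
#'   traits matrix).
#' @export
simulate_founders <- function(cfg, n_founders = cfg$n_parents) {
  m <- cfg$n_markers
  p <- stats::rbeta(m, cfg$freq_beta[1], cfg$freq_beta[2])
  p <- pmin(pmax(p, 0.02), 0.98)
  genomes <- array(stats::rbinom(n_founders * 4 * m, 1, rep(p, each = n_founders * 4)),
                   dim = c(n_founders, 4, m))
  ntr <- length(cfg$traits)
  a_raw <- matrix(stats::rnorm(m * ntr), m, ntr)
  if (ntr == 2) {
    ## correlate the two effect columns at r_g
    a_raw[, 2] <- cfg$r_g * a_raw[, 1] + sqrt(1 - cfg$r_g^2) * a_raw[, 2]
  }
  hwvar <- 4 * p * (1 - p)
  effects <- vapply(seq_len(ntr), function(t) {
    s2a <- cfg$traits[[t]]$vc[["sigma2_a"]]
    a_raw[, t] * sqrt(s2a / sum(a_raw[, t]^2 * hwvar))
  }, numeric(m))
  list(genomes = genomes, freq = p, effects = effects)
}

#' Draw a diploid gamete from a tetraploid genome
#'
#' Per marker (markers segregate independently): with probability `1 - w` two
#' distinct homologs are sampled without replacement; with probability `w`
#' (double reduction) a single homolog is sampled and duplicated.
#'
#' @param genome 4 x markers matrix (one row per homolog).
#' @param w Double-reduction rate in \[0, 1\].
#' @return 2 x markers matrix of gamete alleles, with attribute `homolog`
#'   (2 x markers matrix of contributing homolog indices).
#' @export
make_gamete <- function(genome, w = 0) {
  stopifnot(w >= 0, w <= 1, nrow(genome) == 4)
  m <- ncol(genome)
  j1 <- sample.int(4, m, replace = TRUE)
  dr <- stats::runif(m) < w
  j2 <- ifelse(dr, j1, ((j1 - 1L + sample.int(3, m, replace = TRUE)) %% 4L) + 1L)
  out <- rbind(genome[cbind(j1, seq_len(m))], genome[cbind(j2, seq_len(m))])
  attr(out, "homolog") <- rbind(j1, j2)
  out
}

#' Plan the crosses of an incomplete diallel
#'
#' Enumerates unordered parent pairs (no selfs, no reciprocals), requires a
#' fertile sire in each pair (male-sterile parents can only serve as dam),
#' randomly drops `drop_fraction` of the permitted crosses, and orients each
#' retained pair (the fertile parent as sire when only one is fertile, random
#' orientation otherwise). Offspring inherit the dam's cytoplasm.
#'
#' @param parents Data frame with `clone`, `cytoplasm`, `male_sterile`.
#' @param cfg A [sim_config()].
#' @return Data frame of families: `sire`, `dam`, `n_offspring`.
#' @export
sim_cross_plan <- function(parents, cfg) {
  n <- nrow(parents)
  pairs <- utils::combn(n, 2)
  fert <- !parents$male_sterile
  ok <- fert[pairs[1, ]] | fert[pairs[2, ]]
  pairs <- pairs[, ok, drop = FALSE]
  if (ncol(pairs) == 0)
    stop("configuration error: no fertile cross is possible", call. = FALSE)
  keep <- stats::runif(ncol(pairs)) >= cfg$drop_fraction
  if (!any(keep)) keep[sample.int(length(keep), 1)] <- TRUE
  pairs <- pairs[, keep, drop = FALSE]
  sire <- dam <- integer(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (fert[i] && fert[j]) {
      if (stats::runif(1) < 0.5) { sire[k] <- i; dam[k] <- j } else { sire[k] <- j; dam[k] <- i }
    } else if (fert[i]) { sire[k] <- i; dam[k] <- j } else { sire[k] <- j; dam[k] <- i }
  }
  data.frame(sire = parents$clone[sire], dam = parents$clone[dam],
             n_offspring = cfg$offspring_per_family,
             stringsAsFactors = FALSE)
}

#' Simulate a tetrasomic incomplete diallel population
#'
#' Runs the full generator: founder genomes and marker effects, the
#' incomplete-diallel cross plan under cytoplasmic male sterility, gene
#' dropping with double reduction, maternal cytoplasm transmission, genomic
#' breeding values (sum of marker effects over allele content, centred on the
#' founder mean), iid line/family/residual effects at the configured
#' variances, the field layout (block-by-year effects, replicates, optional
#' parent check plots) and cytoplasm fixed shifts.
#'
#' Breeding values are genotypic (gene dropping through actual marker
#' alleles), which makes pedigree, genomic and single-step relationship
#' matrices mutually consistent by construction.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return List with `pedigree` (clone, sire, dam, cytoplasm, male_sterile),
#'   `pheno` (long-format plot records), `dosage` (genotyped clones x markers
#'   with NAs for missing calls), and `truth` (true breeding values, line,
#'   family, block effects and the generator parameters).
#' @export
sim_diallel <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  ## parents: cytoplasm, sterility
  n_par <- cfg$n_parents
  par_ids <- sprintf("P%02d", seq_len(n_par))
  cyto <- sample(names(cfg$cyto_freq), n_par, replace = TRUE,
                 prob = cfg$cyto_freq)
  sterile <- grepl("^W", cyto)
  target <- round(cfg$sterile_target * n_par)
  extra <- target - sum(sterile)
  if (extra > 0) {
    cand <- which(!sterile)
    sterile[sample(cand, min(extra, length(cand)))] <- TRUE
  }
  if (all(sterile)) sterile[sample.int(n_par, 1)] <- FALSE
  parents <- data.frame(clone = par_ids, cytoplasm = cyto,
                        male_sterile = sterile, stringsAsFactors = FALSE)

  fo <- simulate_founders(cfg)
  plan <- sim_cross_plan(parents, cfg)

  ## gene dropping
  m <- cfg$n_markers
  w <- cfg$double_reduction
  genomes <- vector("list", n_par)
  names(genomes) <- par_ids
  for (i in seq_len(n_par)) genomes[[i]] <- fo$genomes[i, , ]
  ped <- data.frame(clone = par_ids, sire = NA_character_, dam = NA_character_,
                    cytoplasm = cyto, male_sterile = sterile,
                    stringsAsFactors = FALSE)
  kid_rows <- vector("list", nrow(plan))
  cyto_by_id <- stats::setNames(cyto, par_ids)
  for (k in seq_len(nrow(plan))) {
    s <- plan$sire[k]; d <- plan$dam[k]
    ids <- sprintf("F%03d_%02d", k, seq_len(plan$n_offspring[k]))
    for (o in seq_along(ids)) {
      g <- rbind(make_gamete(genomes[[s]], w), make_gamete(genomes[[d]], w))
      attr(g, "homolog") <- NULL
      genomes[[ids[o]]] <- g
    }
    kid_rows[[k]] <- data.frame(clone = ids, sire = s, dam = d,
                                cytoplasm = cyto_by_id[[d]],
                                male_sterile = FALSE, stringsAsFactors = FALSE)
  }
  ped <- rbind(ped, do.call(rbind, kid_rows))
  all_ids <- ped$clone
  n_all <- length(all_ids)

  ## dosages and breeding values
  dosage_all <- t(vapply(genomes, colSums, numeric(m)))
  ntr <- length(cfg$traits)
  centre <- colMeans(dosage_all[seq_len(n_par), , drop = FALSE])
  bv <- (dosage_all - matrix(centre, n_all, m, byrow = TRUE)) %*% fo$effects
  colnames(bv) <- vapply(cfg$traits, `[[`, "", "name")
  rownames(bv) <- all_ids

  ## family, line effects (correlated across two traits where configured)
  corr_draw <- function(nlev, s2_name, r) {
    z <- matrix(stats::rnorm(nlev * ntr), nlev, ntr)
    if (ntr == 2) z[, 2] <- r * z[, 1] + sqrt(1 - r^2) * z[, 2]
    sweep(z, 2, vapply(cfg$traits, function(tr) sqrt(tr$vc[[s2_name]]),
                       numeric(1)), `*`)
  }
  fam_key <- ifelse(is.na(ped$sire), NA,
                    paste(pmin(ped$sire, ped$dam), pmax(ped$sire, ped$dam),
                          sep = "/"))
  fam_lev <- sort(unique(fam_key[!is.na(fam_key)]))
  fam_eff <- corr_draw(length(fam_lev), "sigma2_f", cfg$r_f)
  rownames(fam_eff) <- fam_lev

  phen_ids <- if (cfg$parent_reps > 0) all_ids else setdiff(all_ids, par_ids)
  nline <- length(phen_ids) * (if (cfg$line_by_year) cfg$years else 1L)
  line_eff <- corr_draw(nline, "sigma2_l", cfg$r_l)
  line_keys <- if (cfg$line_by_year)
    as.vector(outer(phen_ids, seq_len(cfg$years), paste, sep = ":")) else phen_ids
  rownames(line_eff) <- line_keys

  ## layout and phenotypes
  recs <- list()
  blocks <- list()
  for (yr in seq_len(cfg$years)) {
    for (rp in seq_len(cfg$n_rep)) {
      use <- setdiff(phen_ids, if (rp > cfg$parent_reps) par_ids else character(0))
      ord <- sample(use)
      bidx <- ceiling(seq_along(ord) / cfg$block_size)
      bid <- sprintf("y%d_r%d_b%02d", yr, rp, bidx)
      for (b in unique(bid)) if (is.null(blocks[[b]]))
        blocks[[b]] <- stats::rnorm(1, 0, cfg$block_sd)
      recs[[length(recs) + 1L]] <- data.frame(
        clone = ord, year = 2013L + yr, block = bid, replicate = rp,
        stringsAsFactors = FALSE)
    }
  }
  layout <- do.call(rbind, recs)
  block_eff <- unlist(blocks)

  e_mat <- matrix(stats::rnorm(nrow(layout) * ntr), nrow(layout), ntr)
  if (ntr == 2)
    e_mat[, 2] <- cfg$r_e * e_mat[, 1] + sqrt(1 - cfg$r_e^2) * e_mat[, 2]
  e_mat <- sweep(e_mat, 2, vapply(cfg$traits, function(tr)
    sqrt(tr$vc[["sigma2_e"]]), numeric(1)), `*`)

  pheno <- list()
  for (t in seq_len(ntr)) {
    tr <- cfg$traits[[t]]
    cyto_shift <- if (!is.null(tr$cyto))
      tr$cyto[ped$cytoplasm[match(layout$clone, ped$clone)]] else 0
    line_key <- if (cfg$line_by_year)
      paste(layout$clone, layout$year - 2013L, sep = ":") else layout$clone
    fkey <- fam_key[match(layout$clone, ped$clone)]
    f_val <- numeric(nrow(layout))
    hasf <- !is.na(fkey)
    f_val[hasf] <- fam_eff[fkey[hasf], t]
    pheno[[t]] <- data.frame(
      clone = layout$clone, trait = tr$name,
      value = tr$mu + block_eff[layout$block] + unname(cyto_shift) +
        bv[layout$clone, t] + line_eff[line_key, t] + f_val + e_mat[, t],
      year = layout$year, block = layout$block, replicate = layout$replicate,
      stringsAsFactors = FALSE)
  }
  pheno <- do.call(rbind, pheno)
  rownames(pheno) <- NULL

  ## genotyped panel: parents plus a fraction of offspring
  offspring <- setdiff(all_ids, par_ids)
  n_gen <- round(cfg$genotyped_fraction * length(offspring))
  gen_ids <- c(par_ids, sort(sample(offspring, n_gen)))
  dosage <- dosage_all[gen_ids, , drop = FALSE]
  colnames(dosage) <- sprintf("M%04d", seq_len(m))
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(length(dosage)) < cfg$missing_rate,
                   nrow(dosage), ncol(dosage))
    dosage[miss] <- NA
  }

  list(pedigree = ped,
       pheno = pheno,
       dosage = dosage,
       truth = list(bv = bv, line = line_eff, family = fam_eff,
                    blocks = block_eff, freq = fo$freq, effects = fo$effects,
                    config = cfg, seed = seed))
}
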