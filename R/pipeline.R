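#' Run the full diallel analysis from a single configuration
#'
#' Orchestrates simulation (or file input), relationship-matrix construction,
#' univariate REML fits per trait and matrix kind, cross-validation, pairwise
#' trait correlations and parent-EBV summaries, writing tab-separated summary
#' tables and a line-oriented log into an output directory. All randomness
#' flows from the single `seed` entry, so two runs with the same
#' configuration are identical.
#'
#' Configuration (a YAML file path or an equivalent nested list):
#' \preformatted{
#' seed: 7
#' simulate: {n_parents: 8, offspring_per_family: 10, ...}  # sim_config args
#' # or: inputs: {pedigree: ped.csv, phenotypes: ph.csv, dosages: dos.tsv}
#' matrices: [A, G, H]          # G/H require dosages
#' double_reduction: 0
#' traits:                      # optional per-trait model options
#'   dry_matter: {line: yes, line_by_year: no}
#' cv: {k: 8, repeats: 30}      # omit to skip cross-validation
#' correlations: yes            # pairwise bivariate models (>= 2 traits)
#' }
#'
#' @param config Path to a YAML file or a named list.
#' @param out_dir Output directory for the report bundle.
#' @return Invisibly, a list with the fitted objects and summary tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    message(msg)
  }
  fail <- function(stage, e) {
    logline("FAILED at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed at stage ", stage, ": ", conditionMessage(e),
         call. = FALSE)
  }
  seed <- config$seed %||% 1

  matrices <- toupper(config$matrices %||% "A")
  ## validate before any fitting
  if (any(matrices %in% c("G", "H")) &&
      is.null(config$simulate) && is.null(config$inputs$dosages))
    stop("configuration error: matrices G/H require dosage input",
         call. = FALSE)

  stage <- "input"
  dat <- tryCatch({
    if (!is.null(config$simulate)) {
      cfg <- do.call(sim_config, config$simulate)
      sim <- sim_diallel(cfg, seed = seed)
      logline("simulated diallel: ", nrow(sim$pedigree), " clones, ",
              length(unique(sim$pheno$trait)), " trait(s)")
      sim
    } else {
      inp <- config$inputs
      if (is.null(inp)) stop("config needs either `simulate` or `inputs`")
      for (f in unlist(inp)) if (!file.exists(f)) stop("missing input: ", f)
      list(pedigree = read_pedigree(inp$pedigree),
           pheno = read_phenotypes(inp$phenotypes),
           dosage = if (!is.null(inp$dosages)) read_dosage(inp$dosages))
    }
  }, error = function(e) fail(stage, e))

  stage <- "kinship"
  mats <- tryCatch({
    out <- list()
    w <- config$double_reduction %||% 0
    A <- amat_tetra(dat$pedigree, double_reduction = w)
    if ("A" %in% matrices) out$A <- A
    if (any(c("G", "H") %in% matrices)) {
      G <- gmat_vanraden(dat$dosage)
      if ("G" %in% matrices) out$G <- G
      if ("H" %in% matrices) {
        gids <- rownames(G)
        A22 <- A[gids, gids]
        out$H <- hmat_single_step(A, adjust_g_scale(G, A22), gids)
      }
    }
    logline("built matrices: ", paste(names(out), collapse = ", "),
            " (double reduction ", w, ")")
    out
  }, error = function(e) fail(stage, e))

  traits <- unique(as.character(dat$pheno$trait))
  topt <- config$traits %||% list()

  stage <- "reml"
  fits <- tryCatch({
    fits <- list()
    vc_rows <- list()
    for (tr in traits) {
      op <- topt[[tr]] %||% list()
      for (mk in names(mats)) {
        fit <- diallel_blup(dat$pheno, mats[[mk]], trait = tr,
                            pedigree = dat$pedigree,
                            line = op$line %||% TRUE,
                            line_by_year = op$line_by_year %||% FALSE,
                            family = op$family %||% TRUE)
        fits[[paste(tr, mk, sep = ".")]] <- fit
        h2 <- heritability(fit, n_rep = max(1, round(stats::median(
          table(fit$obs$clone)))))
        vc_rows[[length(vc_rows) + 1L]] <- data.frame(
          trait = tr, matrix = mk, t(fit$vc), t(stats::setNames(
            fit$vc_se, paste0("se_", names(fit$vc_se)))),
          h2_plot = h2$h2_plot, h2_design = h2$h2_design,
          sca_gca = sca_gca_ratio(fit), m2ll = fit$m2ll,
          converged = fit$converged)
        logline("REML fit: ", tr, " / ", mk, " -2logL=",
                format(fit$m2ll, digits = 8))
        ebv_tab <- predict(fit)
        utils::write.table(ebv_tab,
                           file.path(out_dir, paste0("ebv_", tr, "_", mk, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    vc_tab <- do.call(rbind, vc_rows)
    utils::write.table(vc_tab, file.path(out_dir, "variance_components.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(fits = fits, vc_tab = vc_tab)
  }, error = function(e) fail(stage, e))

  cv_tab <- NULL
  if (!is.null(config$cv)) {
    stage <- "crossval"
    cv_tab <- tryCatch({
      rows <- list()
      for (tr in traits) {
        op <- topt[[tr]] %||% list()
        for (mk in names(mats)) {
          key <- paste(tr, mk, sep = ".")
          cv <- cross_validate(dat$pheno, mats[[mk]], trait = tr,
                               pedigree = dat$pedigree,
                               k = config$cv$k %||% 8,
                               repeats = config$cv$repeats %||% 30,
                               seed = seed,
                               vc = fits$fits[[key]]$vc,
                               line = op$line %||% TRUE,
                               line_by_year = op$line_by_year %||% FALSE,
                               family = op$family %||% TRUE)
          rows[[key]] <- data.frame(
            trait = tr, matrix = mk, mean_r = cv$mean_r, sd_r = cv$sd_r,
            h2_plot = cv$h2_plot, h2_design = cv$h2_design,
            accuracy = cv$accuracy, dispersion = cv$dispersion)
          logline("cross-validation: ", tr, " / ", mk, " r=",
                  round(cv$mean_r, 3))
        }
      }
      tab <- do.call(rbind, rows)
      utils::write.table(tab, file.path(out_dir, "cv_summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      tab
    }, error = function(e) fail(stage, e))
  }

  cor_tab <- NULL
  if (isTRUE(config$correlations) && length(traits) >= 2) {
    stage <- "correlations"
    cor_tab <- tryCatch({
      rows <- list()
      mk <- names(mats)[1]
      cmb <- utils::combn(traits, 2)
      for (i in seq_len(ncol(cmb))) {
        f2 <- diallel_blup2(dat$pheno, mats[[mk]], traits = cmb[, i],
                            pedigree = dat$pedigree)
        rg <- genetic_correlation(f2)
        rp <- phenotypic_correlation(f2)
        rows[[i]] <- data.frame(
          trait1 = cmb[1, i], trait2 = cmb[2, i],
          kind = c("genetic", "phenotypic"),
          r = c(rg$r, rp$r),
          ci_low = c(rg$ci_low, NA), ci_high = c(rg$ci_high, NA),
          defined = c(rg$defined, rp$defined))
        logline("bivariate fit: ", paste(cmb[, i], collapse = " x "),
                " r_g=", round(rg$r, 3))
      }
      tab <- do.call(rbind, rows)
      utils::write.table(tab, file.path(out_dir, "correlations.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      tab
    }, error = function(e) fail(stage, e))
  }

  stage <- "parent_summary"
  parent_tab <- tryCatch({
    parents <- dat$pedigree$clone[is.na(dat$pedigree$sire) &
                                    is.na(dat$pedigree$dam)]
    tab <- summarize_parent_ebvs(fits$fits, parents)
    utils::write.table(tab, file.path(out_dir, "parent_ebvs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    tab
  }, error = function(e) fail(stage, e))

  logline("pipeline completed")
  invisible(list(fits = fits$fits, variance_components = fits$vc_tab,
                 cv = cv_tab, correlations = cor_tab, parents = parent_tab,
                 matrices = mats, data = dat))
}

#' Parent breeding values with confidence intervals across fits
#'
#' One row per parent, trait and matrix kind, with the EBV, its prediction
#' error variance and the 95% interval `ebv +/- 1.96 sqrt(pev)`.
#'
#' @param fits Named list of [diallel_blup()] fits (names `trait.matrix`).
#' @param parents Parent clone ids.
#' @return Data frame.
#' @export
summarize_parent_ebvs <- function(fits, parents) {
  rows <- lapply(names(fits), function(key) {
    fit <- fits[[key]]
    pr <- predict(fit, clones = intersect(parents, names(fit$ebv)))
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    data.frame(trait = parts[1], matrix = parts[2], pr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
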