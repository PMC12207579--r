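#' Tuber dry matter content from under-water weighing
#'
#' Converts a pair of basket weighings (in air and suspended in water) into a
#' dry matter percentage via the empirical specific-gravity calibration used
#' for starch potatoes:
#' \deqn{DM\% = 214 \times \left(\frac{w_{air}}{w_{air}-w_{water}} - 0.988\right).}
#'
#' @param weight_air Weight of the tuber basket in air (kg), strictly positive.
#' @param weight_water Weight of the same basket suspended in water (kg),
#'   non-negative and strictly less than `weight_air`.
#' @return Numeric vector of dry matter contents in percent.
#' @examples
#' dry_matter_content(1.088, 0.088)  # exactly 21.4
#' @export
dry_matter_content <- function(weight_air, weight_water) {
  if (any(!is.finite(weight_air)) || any(!is.finite(weight_water)))
    stop("weights must be finite numbers", call. = FALSE)
  if (any(weight_air <= 0) || any(weight_water < 0))
    stop("invalid measurement: weight_air must be > 0 and weight_water >= 0",
         call. = FALSE)
  if (any(weight_air <= weight_water))
    stop("invalid measurement: weight_air must exceed weight_water",
         call. = FALSE)
  214 * (weight_air / (weight_air - weight_water) - 0.988)
}

#' Recode a 1-9 grading scale to 1-6 by pooling the low end
#'
#' Manual 1-9 gradings whose low categories are rarely used are collapsed to a
#' 1-6 scale: every grade at or below `pool_threshold` becomes 1 and the
#' remaining grades shift down so the maximum grade 9 maps to 6.
#'
#' @param values Integer-valued grades on the original 1-9 scale.
#' @param pool_threshold Grades `<= pool_threshold` are pooled into the new
#'   grade 1 (default 4).
#' @return Recoded grades on the 1-6 scale.
#' @export
recode_grade_scale <- function(values, pool_threshold = 4) {
  v <- values[!is.na(values)]
  if (any(v < 1 | v > 9))
    stop("grade outside the declared 1-9 scale", call. = FALSE)
  pmax(values - (pool_threshold - 1), 1)
}

## Two-tailed critical values for Dixon's r10 ("Q") statistic at the
## 90/95/99% confidence levels, n = 3..30 (Rorabacher's corrected tables).
.dixon_qtab <- list(
  "0.9" = c(0.941, 0.765, 0.642, 0.560, 0.507, 0.468, 0.437, 0.412,
            0.392, 0.376, 0.361, 0.349, 0.338, 0.329, 0.320, 0.313,
            0.306, 0.300, 0.295, 0.290, 0.285, 0.281, 0.277, 0.273,
            0.269, 0.266, 0.263, 0.260),
  "0.95" = c(0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466,
             0.444, 0.426, 0.410, 0.396, 0.384, 0.374, 0.365, 0.356,
             0.349, 0.342, 0.337, 0.331, 0.326, 0.321, 0.317, 0.312,
             0.308, 0.305, 0.301, 0.298),
  "0.99" = c(0.994, 0.926, 0.821, 0.740, 0.680, 0.634, 0.598, 0.568,
             0.542, 0.522, 0.503, 0.488, 0.475, 0.463, 0.452, 0.442,
             0.433, 0.425, 0.418, 0.411, 0.404, 0.399, 0.393, 0.388,
             0.384, 0.380, 0.376, 0.372))

#' Critical value for Dixon's Q-test
#'
#' Tabulated two-tailed critical values of the r10 gap/range statistic for
#' batch sizes 3-30; for batches of 31-200 the tabulated values are
#' extrapolated by the regression \eqn{Q_{crit}(n) \approx a + b/\sqrt{n}}
#' fitted to the n = 10..30 tail of the table.
#'
#' @param n Batch size(s), between 3 and 200.
#' @param confidence Two-tailed confidence level: 0.90, 0.95 (default) or 0.99.
#' @return Critical value(s) of Q.
#' @export
dixon_qcrit <- function(n, confidence = 0.95) {
  key <- as.character(confidence)
  if (!key %in% names(.dixon_qtab))
    stop("confidence must be one of 0.90, 0.95, 0.99", call. = FALSE)
  if (any(n < 3 | n > 200))
    stop("Dixon's Q-test is defined here for batches of 3 to 200", call. = FALSE)
  tab <- .dixon_qtab[[key]]
  out <- numeric(length(n))
  small <- n <= 30
  out[small] <- tab[n[small] - 2]
  if (any(!small)) {
    nn <- 10:30
    fit <- stats::lm(tab[nn - 2] ~ I(1 / sqrt(nn)))
    out[!small] <- stats::coef(fit)[1] + stats::coef(fit)[2] / sqrt(n[!small])
  }
  out
}

#' Iterative outlier removal with Dixon's Q-test
#'
#' Screens a batch of tuber measurements (e.g. lengths or diameters) for
#' outliers relative to the nearest neighbour: Q = |suspect - nearest
#' neighbour| / range, compared two-tailed against `dixon_qcrit(n, confidence)`.
#' Removal starts from the most extreme value and iterates on the reduced
#' batch until no value exceeds the critical value.
#'
#' @param batch Numeric vector, 3 to 200 values. Batches shorter than 3 are
#'   returned unchanged with a warning recorded in the report.
#' @param confidence Two-tailed confidence level (default 0.95).
#' @param batch_id Optional label stored in the report.
#' @return A list with `values` (the retained measurements) and `report`, a
#'   data frame of removed values with their Q statistic and the critical
#'   value used.
#' @export
dixon_q_filter <- function(batch, confidence = 0.95, batch_id = NA_character_) {
  if (length(batch) > 200)
    stop("Dixon's Q-test batches are limited to 200 values", call. = FALSE)
  report <- data.frame(batch_id = character(), value = numeric(),
                       q = numeric(), qcrit = numeric(), n = integer(),
                       note = character(), stringsAsFactors = FALSE)
  x <- batch[!is.na(batch)]
  if (length(x) < 3) {
    warning("batch of fewer than 3 values returned unchanged")
    report <- data.frame(batch_id = batch_id, value = NA_real_, q = NA_real_,
                         qcrit = NA_real_, n = length(x),
                         note = "batch too small, returned unchanged",
                         stringsAsFactors = FALSE)
    return(list(values = batch, report = report))
  }
  repeat {
    n <- length(x)
    if (n < 3) break
    s <- sort(x)
    rng <- s[n] - s[1]
    if (rng == 0) break
    q_low <- (s[2] - s[1]) / rng
    q_high <- (s[n] - s[n - 1]) / rng
    if (q_high >= q_low) { q <- q_high; suspect <- s[n] } else { q <- q_low; suspect <- s[1] }
    qc <- dixon_qcrit(n, confidence)
    if (q <= qc) break
    report <- rbind(report, data.frame(
      batch_id = batch_id, value = suspect, q = q, qcrit = qc, n = n,
      note = "removed", stringsAsFactors = FALSE))
    x <- x[-match(suspect, x)]
  }
  list(values = x, report = report)
}

#' Tuber length/width ratio
#'
#' @param length Tuber length (mm), the longest measure.
#' @param diameter Tuber diameter (mm), perpendicular to the length.
#' @return `length / diameter`.
#' @export
length_width_ratio <- function(length, diameter) {
  if (any(length <= 0, na.rm = TRUE) || any(diameter <= 0, na.rm = TRUE))
    stop("invalid measurement: length and diameter must be positive",
         call. = FALSE)
  length / diameter
}

#' Descriptive statistics of a long-format trait table
#'
#' Per-trait range, mean with its standard error, phenotypic variance,
#' coefficient of variation (CV = sd/mean), number of observations and number
#' of replicates, in the layout of a field-trial summary table.
#'
#' @param pheno Long-format data frame with columns `clone`, `trait`, `value`
#'   and optionally `replicate`.
#' @return Data frame with one row per trait.
#' @export
trait_stats <- function(pheno) {
  stopifnot(all(c("clone", "trait", "value") %in% names(pheno)))
  traits <- unique(as.character(pheno$trait))
  out <- lapply(traits, function(tr) {
    d <- pheno[pheno$trait == tr & !is.na(pheno$value), , drop = FALSE]
    if (nrow(d) < 2)
      stop("need at least 2 observations per trait: ", tr, call. = FALSE)
    v <- d$value
    n <- length(v)
    varv <- stats::var(v)
    m <- mean(v)
    nrep <- if ("replicate" %in% names(d)) {
      max(table(paste(d$clone)))
    } else NA_integer_
    data.frame(trait = tr, min = min(v), max = max(v), mean = m,
               se = sqrt(varv / n), variance = varv,
               cv = if (m == 0) NA_real_ else sqrt(varv) / m,
               n_obs = n, n_rep = nrep, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Flag (but keep) extreme trait values
#'
#' Lists observations above a user threshold without removing them, mirroring
#' the practice of retaining extreme dry matter records for dataset
#' completeness while keeping them auditable.
#'
#' @param pheno Long-format phenotype table.
#' @param trait Trait to screen.
#' @param threshold Values strictly above this are flagged.
#' @return The flagged subset of rows.
#' @export
flag_extreme_values <- function(pheno, trait, threshold) {
  pheno[pheno$trait == trait & !is.na(pheno$value) & pheno$value > threshold, ,
        drop = FALSE]
}
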