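#' Validate and topologically sort a pedigree
#'
#' Orders clone records so that parents always precede their offspring and
#' checks structural invariants: no clone may be its own ancestor, parent ids
#' must either be "0"/NA (unknown) or refer to a clone in the table, and a
#' clone's cytoplasm type must equal its dam's whenever the dam is known
#' (cytoplasm is maternally transmitted).
#'
#' @param ped Data frame with columns `clone`, `sire`, `dam` and optionally
#'   `cytoplasm`. `"0"`, `""` and `NA` denote an unknown parent.
#' @param check_cytoplasm Verify maternal transmission of cytoplasm types
#'   (default TRUE when the column is present).
#' @return The pedigree sorted in topological order, with parent codes
#'   normalised to `NA` for unknown, and an integer `generation` column
#'   (founders = 0).
#' @export
sort_pedigree <- function(ped, check_cytoplasm = TRUE) {
  stopifnot(all(c("clone", "sire", "dam") %in% names(ped)))
  ped <- as.data.frame(ped)
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "") | is.na(x)] <- NA_character_
    x
  }
  ped$clone <- as.character(ped$clone)
  ped$sire <- norm(ped$sire)
  ped$dam <- norm(ped$dam)
  if (anyDuplicated(ped$clone))
    stop("duplicated clone ids in pedigree", call. = FALSE)
  known <- c(ped$sire, ped$dam)
  known <- known[!is.na(known)]
  missing_parents <- setdiff(known, ped$clone)
  if (length(missing_parents) > 0)
    stop("parents absent from pedigree: ",
         paste(utils::head(missing_parents, 5), collapse = ", "),
         call. = FALSE)

  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$clone
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  gen <- rep(NA_integer_, n)
  remaining <- rep(TRUE, n)
  level <- 0L
  while (any(remaining)) {
    ready <- remaining &
      (is.na(si) | !remaining[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | !remaining[ifelse(is.na(di), 1L, di)])
    if (!any(ready))
      stop("pedigree contains a cycle (a clone is its own ancestor)",
           call. = FALSE)
    gen[ready] <- level
    remaining[ready] <- FALSE
    level <- level + 1L
  }
  ped$generation <- gen
  ped <- ped[order(ped$generation, idx), , drop = FALSE]
  rownames(ped) <- NULL

  if (check_cytoplasm && "cytoplasm" %in% names(ped)) {
    cyt <- stats::setNames(as.character(ped$cytoplasm), ped$clone)
    has_dam <- !is.na(ped$dam)
    bad <- has_dam & !is.na(cyt[ped$clone]) & !is.na(cyt[ped$dam]) &
      cyt[ped$clone] != cyt[ped$dam]
    if (any(bad))
      stop("cytoplasm type must be maternally inherited; offending clones: ",
           paste(utils::head(ped$clone[bad], 5), collapse = ", "),
           call. = FALSE)
  }
  ped
}

#' Family (sire-dam pair) key for each clone
#'
#' The family of a clone is the unordered pair of its parents; clones with any
#' unknown parent have no family (NA). Used to build the specific combining
#' ability (family) design.
#'
#' @param ped Pedigree data frame (see [sort_pedigree()]).
#' @return Named character vector of family keys indexed by clone id.
#' @export
family_key <- function(ped) {
  ped <- sort_pedigree(ped, check_cytoplasm = FALSE)
  key <- ifelse(is.na(ped$sire) | is.na(ped$dam), NA_character_,
                paste(pmin(ped$sire, ped$dam), pmax(ped$sire, ped$dam),
                      sep = "/"))
  stats::setNames(key, ped$clone)
}
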