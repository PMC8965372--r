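# Studbook pedigree: kinship and inbreeding by the recursive tabular method,
# and the comparison of expected (pedigree) versus realized (gene-drop) IBD.
#
# Founders — individuals with both parents unknown — are assumed unrelated
# and noninbred, the standard studbook convention; an unknown parent
# contributes zero kinship (Malecot convention).

#' Construct and validate a pedigree
#'
#' @param id character identifiers (unique).
#' @param sire,dam parent identifiers; unknown encoded as `"0"`, `0`, `NA`
#'   or `""`.
#' @param sex optional sex per individual (`"M"`/`"F"`/`NA`); when given,
#'   parent roles are checked for consistency (no individual appears as both
#'   sire and dam).
#' @param cohort optional cohort/group label.
#' @return A `pedigree` data frame in topological order (parents before
#'   offspring) with columns `id`, `sire`, `dam`, `sex`, `cohort`,
#'   `is_founder`.
#' @export
pedigree <- function(id, sire, dam, sex = NA, cohort = NA) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate individual identifiers")
  norm <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p %in% c("0", "")] <- NA_character_
    p
  }
  sire <- norm(sire); dam <- norm(dam)
  if (any(!is.na(sire) & sire == id) || any(!is.na(dam) & dam == id))
    stop("selfing/own-parent entries are not allowed")
  missing_parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(missing_parents) > 0)
    stop("parent(s) not in pedigree: ", paste(missing_parents, collapse = ", "))
  both_roles <- intersect(stats::na.omit(sire), stats::na.omit(dam))
  if (length(both_roles) > 0)
    stop("individual(s) appear as both sire and dam: ",
         paste(both_roles, collapse = ", "))
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    sex = rep_len(as.character(sex), length(id)),
                    cohort = rep_len(as.character(cohort), length(id)),
                    stringsAsFactors = FALSE)
  ped$is_founder <- is.na(ped$sire) & is.na(ped$dam)
  .toposort(ped)
}

# Kahn's algorithm; errors naming a cycle if one exists
.toposort <- function(ped) {
  n <- nrow(ped)
  placed <- character(0)
  remaining <- ped
  out <- ped[0, ]
  while (nrow(remaining) > 0) {
    ready <- (is.na(remaining$sire) | remaining$sire %in% placed) &
             (is.na(remaining$dam) | remaining$dam %in% placed)
    if (!any(ready))
      stop("pedigree cycle involving: ",
           paste(remaining$id, collapse = ", "))
    out <- rbind(out, remaining[ready, ])
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Read a studbook-style pedigree TSV
#'
#' Expected columns: `id`, `sire`, `dam`, optionally `sex` and `cohort`;
#' unknown parents encoded as 0.
#'
#' @param path TSV path.
#' @return A `pedigree`.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#")
  pedigree(tab$id, tab$sire, tab$dam,
           sex = if ("sex" %in% names(tab)) tab$sex else NA,
           cohort = if ("cohort" %in% names(tab)) tab$cohort else NA)
}

#' Kinship matrix by the tabular method
#'
#' Recursive kinship coefficients Theta for all pairs: for `x` later than
#' `y` in topological order, `Theta(x, y) = (Theta(sire_x, y) +
#' Theta(dam_x, y)) / 2`, an unknown parent contributing 0, and
#' `Theta(x, x) = (1 + Theta(sire_x, dam_x)) / 2`. Founders are unrelated
#' and noninbred unless `founder_kinship` supplies prior coefficients.
#'
#' @param ped a `pedigree`.
#' @param founder_kinship optional symmetric matrix of kinship among
#'   founders (rows/cols named by founder id), overriding the default
#'   unrelated/noninbred assumption.
#' @return Symmetric numeric matrix Theta with `Theta(x, x) = 0.5 (1 + F_x)`.
#' @export
kinship_matrix <- function(ped, founder_kinship = NULL) {
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    if (ped$is_founder[i]) {
      K[i, i] <- 0.5
      if (!is.null(founder_kinship) && ped$id[i] %in% rownames(founder_kinship))
        K[i, i] <- founder_kinship[ped$id[i], ped$id[i]]
    } else {
      ks <- if (is.na(si[i]) || is.na(di[i])) 0 else K[si[i], di[i]]
      K[i, i] <- 0.5 * (1 + ks)
    }
    j <- seq_len(i - 1)
    if (length(j) > 0 && !ped$is_founder[i]) {
      ksj <- if (is.na(si[i])) rep(0, length(j)) else K[si[i], j]
      kdj <- if (is.na(di[i])) rep(0, length(j)) else K[di[i], j]
      K[i, j] <- K[j, i] <- 0.5 * (ksj + kdj)
    } else if (length(j) > 0 && !is.null(founder_kinship) &&
               ped$id[i] %in% rownames(founder_kinship)) {
      common <- intersect(ped$id[j], rownames(founder_kinship))
      K[i, match(common, ped$id)] <- K[match(common, ped$id), i] <-
        founder_kinship[ped$id[i], common]
    }
  }
  K
}

#' Pedigree inbreeding coefficient
#'
#' `F_PED` of an individual is the kinship of its parents; founders and
#' individuals with an unknown parent get 0.
#'
#' @param ped a `pedigree`.
#' @param individual identifier(s); default all.
#' @param kinship optional precomputed [kinship_matrix()].
#' @return Named numeric vector of coefficients.
#' @export
f_ped <- function(ped, individual = ped$id, kinship = NULL) {
  unknown <- setdiff(individual, ped$id)
  if (length(unknown) > 0)
    stop("unknown individual(s): ", paste(unknown, collapse = ", "))
  if (is.null(kinship)) kinship <- kinship_matrix(ped)
  i <- match(individual, ped$id)
  out <- ifelse(is.na(ped$sire[i]) | is.na(ped$dam[i]), 0,
                kinship[cbind(match(ped$sire[i], ped$id),
                              match(ped$dam[i], ped$id))])
  stats::setNames(as.numeric(out), individual)
}

#' Expected versus realized inbreeding
#'
#' Summarizes gene-drop replicates against the pedigree expectation: per
#' individual, the mean and variance of realized IBD across replicates next
#' to `F_PED`. The variance reflects Mendelian sampling and linkage, which
#' the pedigree expectation cannot capture.
#'
#' @param ped a `pedigree`.
#' @param realized numeric matrix, replicates x individuals (columns named
#'   by id), of realized IBD fractions from [gene_drop()].
#' @return `data.frame` per individual: `f_ped`, `mean_realized`,
#'   `var_realized` (NA with fewer than 2 replicates), `n_replicates`, and
#'   the Pearson correlation between `F_PED` and mean realized IBD as
#'   attribute `correlation`.
#' @export
expected_vs_realized <- function(ped, realized) {
  fp <- f_ped(ped)
  ids <- colnames(realized)
  out <- data.frame(
    id = ids, f_ped = as.numeric(fp[ids]),
    mean_realized = colMeans(realized),
    var_realized = if (nrow(realized) >= 2) apply(realized, 2, stats::var)
                   else NA_real_,
    n_replicates = nrow(realized), stringsAsFactors = FALSE, row.names = NULL)
  v <- stats::var(out$f_ped)
  attr(out, "correlation") <- if (!is.na(v) && v > 0 &&
                                  stats::var(out$mean_realized) > 0)
    stats::cor(out$f_ped, out$mean_realized) else NA_real_
  out
}
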