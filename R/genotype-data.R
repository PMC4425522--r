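#' Construct a multilocus codominant genotype dataset
#'
#' The central container of the package: a set of individuals scored at a
#' shared, ordered list of codominant loci (microsatellites), each genotype an
#' unordered pair of positive integer allele codes, with per-individual group
#' labels (e.g. `"D06"`, `"M06"`, `"JUV06"`), optional coordinates, and a life
#' stage.
#'
#' Genotypes are stored as two parallel integer matrices (individuals x loci)
#' holding the two allele codes; a missing genotype has `NA` in both matrices at
#' that locus. Allele pairs are unordered: the constructor stores
#' `pmin`/`pmax` so that `(a, b)` and `(b, a)` are the same genotype. A
#' half-called pair (one allele coded, the other missing) is rejected:
#' codominant data cannot be half-called.
#'
#' @param a1,a2 Integer matrices (individuals x loci) of allele codes; `NA` for
#'   missing. Codes must be positive integers.
#' @param locus_names Character vector of unique locus names, one per column.
#' @param id Character vector of individual identifiers.
#' @param group Character vector of group labels, one per individual.
#' @param lat,lon Optional numeric vectors of decimal-degree coordinates
#'   (WGS84 assumed; the package only ever compares means, no projection math).
#' @param stage Character vector (or scalar) of life stages, `"larva"` or
#'   `"juvenile"`.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `a1`, `a2` (allele-code matrices, column-wise min/max), `loci` (locus
#'   names), and `ind` (data frame of `id`, `group`, `lat`, `lon`, `stage`).
#' @seealso [read_genepop()], [summarize_genotypes()], [allele_freqs()]
#' @export
genotype_dataset <- function(a1, a2, locus_names, id, group,
                             lat = NULL, lon = NULL, stage = "larva") {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- nrow(a1); L <- ncol(a1)
  if (!all(dim(a2) == c(n, L)))
    stop("allele matrices 'a1' and 'a2' must have identical dimensions")
  if (length(locus_names) != L)
    stop("'locus_names' length must equal the number of genotype columns")
  if (anyDuplicated(locus_names))
    stop("duplicate locus name: ", locus_names[duplicated(locus_names)][1])
  if (length(id) != n || length(group) != n)
    stop("'id' and 'group' must have one entry per individual")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf("half-called genotype for individual '%s' at locus '%s': %s",
                 id[w[1]], locus_names[w[2]],
                 "a codominant genotype must have both alleles or neither"))
  }
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele codes must be positive integers (0 encodes missing on file only)")
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  dimnames(lo) <- dimnames(hi) <- list(as.character(id), locus_names)
  ind <- data.frame(
    id = as.character(id),
    group = as.character(group),
    lat = if (is.null(lat)) NA_real_ else as.numeric(lat),
    lon = if (is.null(lon)) NA_real_ else as.numeric(lon),
    stage = rep_len(as.character(stage), n),
    stringsAsFactors = FALSE
  )
  structure(list(a1 = lo, a2 = hi, loci = as.character(locus_names), ind = ind),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  tab <- table(x$ind$group)
  cat(sprintf("genotype_dataset: %d individuals, %d loci, %d groups\n",
              nrow(x$a1), length(x$loci), length(tab)))
  cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci in a genotype dataset
#' @param x A `genotype_dataset`.
#' @return Integer count.
#' @export
n_individuals <- function(x) nrow(x$a1)

#' @rdname n_individuals
#' @export
n_loci <- function(x) length(x$loci)

#' Group labels present in a dataset
#' @param x A `genotype_dataset`.
#' @return Character vector of unique group labels, in order of appearance.
#' @export
dataset_groups <- function(x) unique(x$ind$group)

#' Dataset-wide allele codes per locus
#'
#' The ordered set of distinct allele codes observed anywhere in the dataset,
#' per locus. This defines the allele space used for the `1/k` prior of the
#' Bayesian assignment likelihood.
#'
#' @param x A `genotype_dataset`.
#' @return Named list (one element per locus) of sorted integer allele codes.
#' @export
locus_alleles <- function(x) {
  out <- lapply(seq_along(x$loci), function(l)
    sort(unique(c(x$a1[, l], x$a2[, l])), na.last = NA))
  names(out) <- x$loci
  out
}

#' Subset a genotype dataset by individuals
#'
#' @param x A `genotype_dataset`.
#' @param which Logical, integer, or character (ids) index of individuals.
#' @return A `genotype_dataset` restricted to the selected individuals.
#' @export
subset_individuals <- function(x, which) {
  if (is.character(which)) which <- match(which, x$ind$id)
  genotype_dataset(x$a1[which, , drop = FALSE], x$a2[which, , drop = FALSE],
                   x$loci, x$ind$id[which], x$ind$group[which],
                   x$ind$lat[which], x$ind$lon[which], x$ind$stage[which])
}

#' Combine two genotype datasets sharing a locus list
#'
#' @param x,y `genotype_dataset` objects scored at the identical ordered locus
#'   list.
#' @return A combined `genotype_dataset`.
#' @export
bind_datasets <- function(x, y) {
  if (!identical(x$loci, y$loci))
    stop("datasets must share an identical ordered locus list")
  genotype_dataset(rbind(x$a1, y$a1), rbind(x$a2, y$a2), x$loci,
                   c(x$ind$id, y$ind$id), c(x$ind$group, y$ind$group),
                   c(x$ind$lat, y$ind$lat), c(x$ind$lon, y$ind$lon),
                   c(x$ind$stage, y$ind$stage))
}

#' Per-locus summary statistics for one group
#'
#' Computes, for every locus within one group: the number of successfully
#' genotyped individuals `n`, the number of distinct alleles `n_alleles`,
#' observed heterozygosity `h_obs` (fraction of non-missing individuals that
#' are heterozygous), and unbiased expected heterozygosity
#' `h_exp = (2n/(2n-1)) * (1 - sum(p^2))` where `p` are the group allele
#' frequencies.
#'
#' @param x A `genotype_dataset`.
#' @param group A group label present in `x`.
#' @return Data frame with columns `locus`, `n`, `n_alleles`, `h_obs`, `h_exp`.
#' @export
summarize_genotypes <- function(x, group) {
  sel <- x$ind$group == group
  if (!any(sel)) stop("group not found or empty: ", group)
  a1 <- x$a1[sel, , drop = FALSE]; a2 <- x$a2[sel, , drop = FALSE]
  out <- lapply(seq_along(x$loci), function(l) {
    ok <- !is.na(a1[, l])
    n <- sum(ok)
    if (n == 0)
      return(data.frame(locus = x$loci[l], n = 0L, n_alleles = 0L,
                        h_obs = NA_real_, h_exp = NA_real_))
    g1 <- a1[ok, l]; g2 <- a2[ok, l]
    cnt <- table(c(g1, g2))
    p <- cnt / (2 * n)
    h_obs <- mean(g1 != g2)
    h_exp <- if (n > 1) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA_real_
    data.frame(locus = x$loci[l], n = n, n_alleles = length(cnt),
               h_obs = h_obs, h_exp = h_exp)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
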