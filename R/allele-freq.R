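#' Per-group, per-locus allele counts and frequencies
#'
#' Tabulates allele counts per group over a shared dataset-wide allele space
#' (all codes seen anywhere in `x`, optionally extended with `extra_alleles`
#' from another dataset so unknown-origin individuals carrying novel alleles
#' are representable). This table underlies every likelihood and F-statistic
#' in the package.
#'
#' @param x A [genotype_dataset()].
#' @param groups Group labels to tabulate (default: all groups in `x`).
#' @param extra_alleles Optional list (named by locus) of additional allele
#'   codes to include in the allele space with zero counts.
#' @return An object of class `allele_freq_table`: list with `loci`, `alleles`
#'   (list of sorted codes per locus), `counts` (per group, a list of numeric
#'   count vectors aligned with `alleles`), and `n_copies` (groups x loci
#'   matrix of total gene copies).
#' @export
allele_freqs <- function(x, groups = NULL, extra_alleles = NULL) {
  if (is.null(groups)) groups <- dataset_groups(x)
  alleles <- locus_alleles(x)
  if (!is.null(extra_alleles)) {
    for (nm in names(extra_alleles)) {
      if (nm %in% names(alleles))
        alleles[[nm]] <- sort(unique(c(alleles[[nm]], extra_alleles[[nm]])))
    }
  }
  L <- length(x$loci)
  counts <- lapply(groups, function(g) {
    sel <- x$ind$group == g
    lapply(seq_len(L), function(l) {
      codes <- c(x$a1[sel, l], x$a2[sel, l])
      codes <- codes[!is.na(codes)]
      cnt <- tabulate(match(codes, alleles[[l]]), nbins = length(alleles[[l]]))
      names(cnt) <- alleles[[l]]
      as.numeric(cnt)
    })
  })
  names(counts) <- groups
  n_copies <- matrix(unlist(lapply(counts, function(cl)
    vapply(cl, sum, 0))), nrow = length(groups), ncol = L, byrow = TRUE,
    dimnames = list(groups, x$loci))
  structure(list(loci = x$loci, alleles = alleles, counts = counts,
                 n_copies = n_copies),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d loci, groups: %s\n", length(x$loci),
              paste(names(x$counts), collapse = ", ")))
  cat("  alleles per locus:",
      paste(vapply(x$alleles, length, 0L), collapse = " "), "\n")
  invisible(x)
}

#' Allele frequencies for one group
#'
#' @param ft An [allele_freqs()] table.
#' @param group Group label.
#' @return List (per locus) of frequency vectors; a locus with zero gene
#'   copies yields all-zero frequencies.
#' @export
group_frequencies <- function(ft, group) {
  cnt <- ft$counts[[group]]
  if (is.null(cnt)) stop("group not in frequency table: ", group)
  lapply(cnt, function(v) if (sum(v) > 0) v / sum(v) else v)
}

#' Number of distinct alleles per locus in the pooled allele space
#'
#' This is the `k` of the Bayesian genotype likelihood's `1/k` prior: the
#' number of alleles observed dataset-wide at each locus.
#'
#' @param ft An [allele_freqs()] table.
#' @return Integer vector, one per locus.
#' @export
pooled_allele_counts <- function(ft) {
  vapply(ft$alleles, length, 0L)
}

#' Bonferroni-adjusted significance level
#'
#' For a table of `k` simultaneous tests at family-wise level `alpha`, a test
#' is significant when its p-value falls below `alpha / k`.
#'
#' @param p Numeric vector of p-values belonging to one table of simultaneous
#'   tests.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Logical vector: `TRUE` where `p < alpha / length(p)`.
#' @export
bonferroni_significant <- function(p, alpha = 0.05) {
  p < alpha / length(p)
}
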