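# Small builders shared across test files.

# A dataset from explicit genotype strings: each element "a/b" or NA,
# one row per individual, columns = loci.
make_ds <- function(geno, groups, loci = NULL, ...) {
  geno <- as.matrix(geno)
  if (is.null(loci)) loci <- sprintf("loc%d", seq_len(ncol(geno)))
  split2 <- function(s, part) {
    ifelse(is.na(s), NA_integer_,
           as.integer(vapply(strsplit(s, "/"), `[`, "", part)))
  }
  a1 <- apply(geno, 2, split2, part = 1L)
  a2 <- apply(geno, 2, split2, part = 2L)
  if (is.null(dim(a1))) { a1 <- matrix(a1, nrow = nrow(geno)); a2 <- matrix(a2, nrow = nrow(geno)) }
  genotype_dataset(a1, a2, loci, sprintf("i%02d", seq_len(nrow(geno))),
                   groups, ...)
}

# Two Balding-Nichols groups drawn through the package generator, returned
# as a larvae-only dataset with groups "A" and "B".
make_bn_pair <- function(fst, n_per_group, n_loci = 12, alleles = c(5, 25),
                         seed = NULL) {
  cfg <- sim_config(n_loci = n_loci, allele_range = alleles, fst = fst,
                    n_larvae = c(Detroit = n_per_group, Maumee = n_per_group),
                    n_juveniles = 2, migrant_fraction = 0, missing_rate = 0,
                    seed = seed)
  pops <- simulate_populations(cfg)
  ind <- simulate_individuals(pops, cfg)
  ds <- ind$larvae
  ds$ind$group <- ifelse(ds$ind$group == "D06", "A", "B")
  ds
}

# Write text lines to a temp file and return the path.
tmp_lines <- function(lines, ext = ".gen") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
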