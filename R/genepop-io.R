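#' Read a GenePop file
#'
#' Parses the GenePop dialect used throughout microsatellite population
#' genetics: a title line; locus names either one per line or comma-separated
#' on a single line; `Pop` separator lines; then one line per individual of the
#' form `id , 001002 003003 ...` with 2- or 3-digit allele codes concatenated
#' per locus. `00`/`000` encodes a missing allele; a genotype must be either
#' fully missing (`0000`/`000000`) or fully called -- a half-called pair is a
#' parse error.
#'
#' Group names default to the id of the *last* individual in each `Pop` block
#' (the conventional GenePop reading) and can be overridden explicitly, which
#' is the recommended way to attach meaningful labels such as `"D06"`.
#'
#' @param path Path to a GenePop (`.gen`) file.
#' @param group_names Optional character vector, one label per `Pop` block,
#'   overriding the default naming.
#' @param stage Life stage recorded for all individuals (default `"larva"`).
#' @return A [genotype_dataset()].
#' @export
read_genepop <- function(path, group_names = NULL, stage = "larva") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\ufeff", "", lines, fixed = TRUE)
  if (length(lines) < 3) stop("GenePop parse error: file too short")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("GenePop parse error: no 'Pop' separator found")
  header <- lines[2:(first_pop - 1)]
  # locus names: either one per line, or comma-separated on one (or more) lines
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stop("GenePop parse error: no locus names before first 'Pop'")
  if (anyDuplicated(loci))
    stop("GenePop parse error: duplicate locus name '",
         loci[duplicated(loci)][1], "'")
  L <- length(loci)

  pop_of <- cumsum(is_pop)
  body <- which(!is_pop & seq_along(lines) > first_pop & nzchar(trimws(lines)))
  if (length(body) == 0) stop("GenePop parse error: no individuals")
  n <- length(body)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  id <- character(n)
  blk <- integer(n)

  for (i in seq_len(n)) {
    ln <- body[i]
    txt <- lines[ln]
    parts <- strsplit(txt, ",")[[1]]
    if (length(parts) < 2)
      stop(sprintf("GenePop parse error at line %d: missing ',' after individual id", ln))
    id[i] <- trimws(parts[1])
    genos <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(genos) != L)
      stop(sprintf(
        "GenePop parse error at line %d: %d genotype fields for %d loci", ln,
        length(genos), L))
    w <- nchar(genos)
    if (!all(w %in% c(4L, 6L)) || !all(grepl("^[0-9]+$", genos)))
      stop(sprintf("GenePop parse error at line %d: genotype fields must be 4 or 6 digits", ln))
    half <- w %/% 2L
    x1 <- as.integer(substr(genos, 1L, half))
    x2 <- as.integer(substr(genos, half + 1L, w))
    bad <- xor(x1 == 0L, x2 == 0L)
    if (any(bad))
      stop(sprintf("GenePop parse error at line %d: half-called genotype '%s' at locus '%s'",
                   ln, genos[bad][1], loci[which(bad)[1]]))
    miss <- x1 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
    blk[i] <- pop_of[ln]
  }

  n_pops <- max(blk)
  if (is.null(group_names)) {
    group_names <- vapply(seq_len(n_pops),
                          function(b) id[which(blk == b)[sum(blk == b)]],
                          character(1))
  } else if (length(group_names) != n_pops) {
    stop(sprintf("'group_names' has %d labels but the file has %d Pop blocks",
                 length(group_names), n_pops))
  }
  genotype_dataset(a1, a2, loci, id, group_names[blk], stage = stage)
}

#' Write a GenePop file
#'
#' Writes one `Pop` block per group (in order of first appearance), with
#' 3-digit allele codes (`000000` for missing); microsatellite allele sizes
#' exceed 99, so the 3-digit dialect is canonical on write even though 2-digit
#' files are accepted on read.
#'
#' @param x A [genotype_dataset()].
#' @param path Output file path.
#' @param title Title line written at the top of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "plumeRecruit export") {
  if (any(x$a1 > 999, na.rm = TRUE))
    stop("allele codes above 999 cannot be written in the 3-digit dialect")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(x$loci, con)
  for (g in dataset_groups(x)) {
    writeLines("Pop", con)
    sel <- which(x$ind$group == g)
    for (i in sel) {
      f1 <- x$a1[i, ]; f2 <- x$a2[i, ]
      f1[is.na(f1)] <- 0L; f2[is.na(f2)] <- 0L
      writeLines(sprintf("%s ,  %s", x$ind$id[i],
                         paste0(sprintf("%03d", f1), sprintf("%03d", f2),
                                collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a site metadata table
#'
#' Reads a delimited table of sampling-site records with header columns
#' `site_id, year, transmissometry, lat, lon` and an optional `plume` column
#' holding the geographic pre-assignment (`"Detroit"` or `"Maumee"`).
#'
#' @param path Path to a CSV/TSV file (delimiter auto-detected from the
#'   header line).
#' @return Data frame of site records.
#' @seealso [classify_habitat()]
#' @export
read_site_table <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("site_id", "year", "transmissometry", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("site table missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a weekly larval abundance survey table
#'
#' Reads a delimited table with header `year, week, plume, site_id, density`
#' where `density` is larvae per cubic metre at one site in one survey week.
#'
#' @param path Path to a CSV/TSV file.
#' @return Data frame of class `abundance_survey`.
#' @seealso [peak_abundance_ratio()], [weekly_anova()]
#' @export
read_abundance_survey <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("year", "week", "plume", "site_id", "density")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("abundance survey missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$density < 0)) stop("larval densities must be nonnegative")
  if (anyDuplicated(df[c("year", "week", "site_id")]))
    stop("duplicate (year, week, site) record in abundance survey")
  class(df) <- c("abundance_survey", class(df))
  df
}
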