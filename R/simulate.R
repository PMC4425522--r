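#' Configuration for a synthetic plume-recruitment study
#'
#' Describes a complete simulated study: two weakly diverged larval source
#' populations (Balding-Nichols model), larval samples with a migrant
#' fraction, a juvenile mixture produced under differential survival, and a
#' weekly larval abundance survey with transmissometry and coordinates.
#'
#' Defaults emulate the statistical structure of a two-plume microsatellite
#' study of larval fish: 12 loci with 5-25 alleles each, multilocus
#' divergence near F_ST = 0.008, roughly 180 Detroit-plume and 90
#' Maumee-plume larvae and 130 juveniles genotyped per year, a ~15% migrant
#' fraction among sampled larvae, a few percent missing genotypes, and
#' overdispersed weekly tow densities whose peak weekly means sit near a
#' 73:27 Detroit:Maumee ratio.
#'
#' @param n_loci Number of loci (default 12).
#' @param allele_range Integer range of allele counts per locus (default
#'   `c(5, 25)`).
#' @param fst Balding-Nichols divergence parameter: the target F_ST between
#'   the two sources (default 0.008; must be in `[0, 1)`).
#' @param n_larvae Named integer vector `c(Detroit = ..., Maumee = ...)` of
#'   larvae sampled (genotyped) per plume per year; these are sampling
#'   choices, not production sizes.
#' @param n_juveniles Juveniles sampled per year.
#' @param survival Positive survival weights `c(Detroit = ..., Maumee = ...)`;
#'   a juvenile's true source is drawn with probability proportional to the
#'   larval production ratio (the normalized peaks of `weekly_means`) times
#'   the survival weight, so equal survival makes the juvenile source
#'   fractions match the abundance ratio -- the null of the recruitment test.
#' @param migrant_fraction Fraction of each plume's sampled larvae that are
#'   first-generation migrants: pure other-plume genotypes carrying the
#'   sampling plume's label (default 0.15).
#' @param missing_rate Per-locus probability a genotype is unscored
#'   (default 0.03).
#' @param years Integer vector of study years (default 2006).
#' @param weekly_means Named list of per-plume weekly mean larval densities
#'   (larvae per cubic metre); the peak weekly means set the larval abundance
#'   ratio.
#' @param sites_per_plume Survey sites per plume per week (default 10).
#' @param dispersion Overdispersion of tow counts: site densities are
#'   negative binomial with variance `mu + dispersion * mu^2` (size
#'   `1/dispersion`). Plankton tows are clumped, hence the default 0.2;
#'   `dispersion = 0` is the degenerate no-noise limit where every site
#'   density equals its configured weekly mean, so the peak ratio equals the
#'   configured mean ratio exactly.
#' @param contradictory_fraction Fraction of sites given a transmissometry
#'   value contradicting their plume (default 0), to exercise the
#'   flag-and-exclude rule.
#' @param seed Optional integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_loci = 12,
                       allele_range = c(5, 25),
                       fst = 0.008,
                       n_larvae = c(Detroit = 180, Maumee = 90),
                       n_juveniles = 130,
                       survival = c(Detroit = 1, Maumee = 1),
                       migrant_fraction = 0.15,
                       missing_rate = 0.03,
                       years = 2006,
                       weekly_means = list(Detroit = c(25, 146, 60),
                                           Maumee = c(12, 54, 22)),
                       sites_per_plume = 10,
                       dispersion = 0.2,
                       contradictory_fraction = 0,
                       seed = NULL) {
  if (fst < 0 || fst >= 1) stop("'fst' must lie in [0, 1)")
  if (migrant_fraction < 0 || migrant_fraction >= 1)
    stop("'migrant_fraction' must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)")
  if (any(allele_range < 2)) stop("need at least 2 alleles per locus")
  if (any(survival <= 0)) stop("survival weights must be positive")
  if (is.null(names(n_larvae))) names(n_larvae) <- c("Detroit", "Maumee")
  if (is.null(names(survival))) names(survival) <- names(n_larvae)
  structure(list(n_loci = n_loci, allele_range = allele_range, fst = fst,
                 n_larvae = n_larvae, n_juveniles = n_juveniles,
                 survival = survival, migrant_fraction = migrant_fraction,
                 missing_rate = missing_rate, years = years,
                 weekly_means = weekly_means,
                 sites_per_plume = sites_per_plume, dispersion = dispersion,
                 contradictory_fraction = contradictory_fraction,
                 seed = seed),
            class = "sim_config")
}

#' Simulate diverged source-population allele frequencies
#'
#' Balding-Nichols model: per locus, ancestral frequencies are drawn from a
#' symmetric Dirichlet(1) over the locus's allele space; each plume's
#' frequencies are then drawn from a Dirichlet with mean equal to the
#' ancestral frequencies and concentration `(1 - F)/F`, whose expected
#' between-population F_ST is `F`. At `F = 0` both plumes receive exactly the
#' ancestral frequencies. The model targets F_ST directly -- the one
#' divergence quantity the analysis estimates -- and is fast at desk scale.
#'
#' @param config A [sim_config()].
#' @return List with `alleles` (codes per locus), `freqs` (per plume, a list
#'   of per-locus frequency vectors), `ancestral`.
#' @export
simulate_populations <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  plumes <- names(config$n_larvae)
  rng <- seq(config$allele_range[1], config$allele_range[2])
  n_all <- rng[sample.int(length(rng), config$n_loci, replace = TRUE)]
  alleles <- lapply(n_all, function(m) 100L + seq_len(m))  # size-like codes
  names(alleles) <- sprintf("L%02d", seq_len(config$n_loci))
  ancestral <- lapply(n_all, function(m) rdirichlet1(rep(1, m)))
  freqs <- lapply(plumes, function(p) {
    lapply(seq_len(config$n_loci), function(l) {
      if (config$fst == 0) return(ancestral[[l]])
      conc <- (1 - config$fst) / config$fst
      rdirichlet1(ancestral[[l]] * conc)
    })
  })
  names(freqs) <- plumes
  list(alleles = alleles, freqs = freqs, ancestral = ancestral)
}

#' True larval production ratio of a simulation configuration
#'
#' The normalized peak weekly mean densities -- the quantity
#' [peak_abundance_ratio()] estimates from a simulated survey, and the ratio
#' the juvenile source draw uses.
#'
#' @param config A [sim_config()].
#' @return Named numeric vector over plumes, summing to 1.
#' @export
production_ratio <- function(config) {
  peaks <- vapply(config$weekly_means, max, 0)
  peaks / sum(peaks)
}

# One Dirichlet draw via normalized gammas; zero shape gives a structural zero.
rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  if (sum(g) == 0) g[which.max(shape)] <- 1
  g / sum(g)
}

#' Simulate larval and juvenile genotypes with known truth
#'
#' Larvae are drawn as Hardy-Weinberg genotypes from their plume's frequency
#' table; a `migrant_fraction` of each plume's larvae is instead drawn from
#' the *other* plume's table while keeping the sampling plume's label
#' (first-generation migrants). Juveniles are drawn from plume *d* with
#' probability proportional to larval output times the survival weight, then
#' genotyped from that plume's table. Missing genotypes are introduced
#' independently per locus at `missing_rate`. Group labels follow the
#' field convention `D06` / `M06` / `JUV06`.
#'
#' @param pops Output of [simulate_populations()].
#' @param config A [sim_config()].
#' @param year Study year for the group labels (default first of
#'   `config$years`).
#' @return List with `larvae` and `juveniles` ([genotype_dataset()]s sharing
#'   the locus list) and `truth` (data frame: `id`, `label_group`,
#'   `true_origin`, `stage`, `migrant`).
#' @export
simulate_individuals <- function(pops, config, year = config$years[1]) {
  if (!is.null(config$seed)) set.seed(config$seed)
  plumes <- names(config$n_larvae)
  yy <- substr(as.character(year), 3, 4)
  L <- length(pops$alleles)
  draw <- function(n, plume) {
    a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
    for (l in seq_len(L)) {
      p <- pops$freqs[[plume]][[l]]
      a1[, l] <- sample(pops$alleles[[l]], n, replace = TRUE, prob = p)
      a2[, l] <- sample(pops$alleles[[l]], n, replace = TRUE, prob = p)
    }
    list(a1 = a1, a2 = a2)
  }
  add_missing <- function(g) {
    if (config$missing_rate > 0) {
      drop <- matrix(stats::runif(length(g$a1)) < config$missing_rate,
                     nrow(g$a1))
      g$a1[drop] <- NA_integer_; g$a2[drop] <- NA_integer_
    }
    g
  }

  # larvae: per plume, a migrant fraction originates from the other plume
  lar <- list(); truth <- list()
  for (i in seq_along(plumes)) {
    p <- plumes[i]; other <- plumes[-i][1]
    n <- config$n_larvae[[p]]
    n_mig <- stats::rbinom(1, n, config$migrant_fraction)
    origin <- c(rep(other, n_mig), rep(p, n - n_mig))[sample(n)]
    g <- list(a1 = matrix(NA_integer_, n, L), a2 = matrix(NA_integer_, n, L))
    for (src in unique(origin)) {
      rows <- origin == src
      gs <- draw(sum(rows), src)
      g$a1[rows, ] <- gs$a1; g$a2[rows, ] <- gs$a2
    }
    g <- add_missing(g)
    label <- paste0(substr(p, 1, 1), yy)
    ids <- sprintf("%s_%03d", label, seq_len(n))
    lar[[p]] <- genotype_dataset(g$a1, g$a2, names(pops$alleles), ids,
                                 rep(label, n), stage = "larva")
    truth[[p]] <- data.frame(id = ids, label_group = label,
                             true_origin = origin, stage = "larva",
                             migrant = origin != p, stringsAsFactors = FALSE)
  }
  larvae <- bind_datasets(lar[[1]], lar[[2]])

  # juveniles: true source ~ larval production x survival weight
  lr <- production_ratio(config)[plumes]
  w <- lr * config$survival[plumes]
  src <- sample(plumes, config$n_juveniles, replace = TRUE, prob = w / sum(w))
  g <- list(a1 = matrix(NA_integer_, config$n_juveniles, L),
            a2 = matrix(NA_integer_, config$n_juveniles, L))
  for (p in unique(src)) {
    rows <- src == p
    gs <- draw(sum(rows), p)
    g$a1[rows, ] <- gs$a1; g$a2[rows, ] <- gs$a2
  }
  g <- add_missing(g)
  jlabel <- paste0("JUV", yy)
  jids <- sprintf("%s_%03d", jlabel, seq_len(config$n_juveniles))
  juveniles <- genotype_dataset(g$a1, g$a2, names(pops$alleles), jids,
                                rep(jlabel, config$n_juveniles),
                                stage = "juvenile")
  truth$juv <- data.frame(id = jids, label_group = jlabel, true_origin = src,
                          stage = "juvenile", migrant = FALSE,
                          stringsAsFactors = FALSE)
  list(larvae = larvae, juveniles = juveniles,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Simulate a weekly larval abundance survey with site metadata
#'
#' Weekly site densities are drawn from a negative binomial around the
#' per-plume weekly mean (size = `dispersion`; plankton tows are clumped).
#' Maumee sites receive transmissometry above 6 m^-1 and Detroit sites below,
#' except for a configurable fraction of contradictory sites that exercise
#' the flag-and-exclude rule of [classify_habitat()]. Coordinates are drawn
#' from two plume-centred clusters in the western-basin coordinate range.
#'
#' @param config A [sim_config()].
#' @param year Study year (default first of `config$years`).
#' @return List with `survey` (abundance records) and `sites` (site table
#'   with `plume`, `transmissometry`, `lat`, `lon`).
#' @export
simulate_survey <- function(config, year = config$years[1]) {
  if (!is.null(config$seed)) set.seed(config$seed)
  plumes <- names(config$weekly_means)
  centres <- list(Detroit = c(lat = 41.95, lon = -83.10),
                  Maumee = c(lat = 41.72, lon = -83.25))
  survey <- list(); sites <- list()
  for (p in plumes) {
    mu <- config$weekly_means[[p]]
    ns <- config$sites_per_plume
    site_ids <- sprintf("%s_S%02d", substr(p, 1, 1), seq_len(ns))
    ctr <- if (p %in% names(centres)) centres[[p]] else c(lat = 41.8, lon = -83.2)
    contradicts <- stats::runif(ns) < config$contradictory_fraction
    trans <- ifelse(xor(p == "Maumee", contradicts),
                    stats::runif(ns, 6.5, 12), stats::runif(ns, 1.5, 5.5))
    sites[[p]] <- data.frame(site_id = site_ids, year = year, plume = p,
                             transmissometry = trans,
                             lat = ctr["lat"] + stats::rnorm(ns, 0, 0.05),
                             lon = ctr["lon"] + stats::rnorm(ns, 0, 0.07),
                             stringsAsFactors = FALSE)
    for (w in seq_along(mu)) {
      dens <- if (config$dispersion > 0)
        stats::rnbinom(ns, size = 1 / config$dispersion, mu = mu[w])
      else rep(mu[w], ns)
      survey[[paste(p, w)]] <- data.frame(year = year, week = w, plume = p,
                                          site_id = site_ids,
                                          density = as.numeric(dens),
                                          stringsAsFactors = FALSE)
    }
  }
  survey <- do.call(rbind, c(survey, list(make.row.names = FALSE)))
  class(survey) <- c("abundance_survey", class(survey))
  list(survey = survey, sites = do.call(rbind, c(sites, list(make.row.names = FALSE))))
}

#' Simulate a complete multi-year synthetic study
#'
#' Draws source populations once, then for each year larval and juvenile
#' samples and an abundance survey; juveniles also receive capture
#' coordinates drawn from a basin-wide cloud (both sources well mixed, the
#' null of the spatial mixing test).
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_study`: list with `config`, `pops`,
#'   `larvae`, `juveniles` (multi-year [genotype_dataset()]s), `truth`,
#'   `survey`, `sites`.
#' @export
simulate_study <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- within_seed_null(config)   # sub-generators must share one stream
  pops <- simulate_populations(cfg)
  lar <- juv <- NULL; truth <- survey <- sites <- list()
  for (y in config$years) {
    ind <- simulate_individuals(pops, cfg, year = y)
    sv <- simulate_survey(cfg, year = y)
    nj <- n_individuals(ind$juveniles)
    ind$juveniles$ind$lat <- stats::runif(nj, 41.6, 42.0)
    ind$juveniles$ind$lon <- stats::runif(nj, -83.4, -82.9)
    lar <- if (is.null(lar)) ind$larvae else bind_datasets(lar, ind$larvae)
    juv <- if (is.null(juv)) ind$juveniles else bind_datasets(juv, ind$juveniles)
    truth[[as.character(y)]] <- cbind(year = y, ind$truth)
    survey[[as.character(y)]] <- sv$survey
    sites[[as.character(y)]] <- sv$sites
  }
  survey <- do.call(rbind, c(survey, list(make.row.names = FALSE)))
  class(survey) <- c("abundance_survey", class(survey))
  structure(list(config = config, pops = pops, larvae = lar, juveniles = juv,
                 truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 survey = survey,
                 sites = do.call(rbind, c(sites, list(make.row.names = FALSE)))),
            class = "synthetic_study")
}

# simulate_study seeds the RNG itself; prevent nested functions from
# re-seeding and collapsing the stream.
within_seed_null <- function(config) { config$seed <- NULL; config }

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: years %s, F target %.4g\n",
              paste(x$config$years, collapse = ", "), x$config$fst))
  cat(sprintf("  larvae: %d, juveniles: %d, survey records: %d\n",
              n_individuals(x$larvae), n_individuals(x$juveniles),
              nrow(x$survey)))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Writes `refs.gen`, `juveniles.gen`, `tows.csv`, `sites.csv`, `truth.csv`
#' into a directory, the on-disk form every reader of the package accepts.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genepop(study$larvae, file.path(dir, "refs.gen"),
                title = "synthetic larval reference groups")
  write_genepop(study$juveniles, file.path(dir, "juveniles.gen"),
                title = "synthetic unknown-origin juveniles")
  utils::write.csv(study$survey, file.path(dir, "tows.csv"),
                   row.names = FALSE)
  utils::write.csv(study$sites, file.path(dir, "sites.csv"),
                   row.names = FALSE)
  utils::write.csv(study$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
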