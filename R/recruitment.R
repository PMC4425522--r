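#' Classify sampling sites into plume habitats from transmissometry
#'
#' Applies the turbidity threshold rule: a transmissometry value strictly
#' greater than `threshold` (default 6.0 m^-1) indicates the highly turbid
#' Maumee River plume; a value at or below it indicates the clearer Detroit
#' River plume. When a geographic pre-assignment (`plume` column) is present,
#' sites whose measured class contradicts it are flagged for exclusion rather
#' than silently re-assigned.
#'
#' @param sites Data frame of site records with columns `site_id` and
#'   `transmissometry`, optionally `plume` (geographic pre-assignment,
#'   `"Detroit"` or `"Maumee"`).
#' @param threshold Transmissometry threshold in m^-1 (default 6.0).
#' @return `sites` with added columns `turbidity_class` (`"Detroit"` or
#'   `"Maumee"`) and `flagged` (`TRUE` where the measured class contradicts
#'   the geographic pre-assignment; `FALSE` when no pre-assignment exists).
#' @export
classify_habitat <- function(sites, threshold = 6.0) {
  if (is.null(sites$transmissometry) || any(is.na(sites$transmissometry)))
    stop("missing transmissometry; use the geographic pre-assignment only and flag the site")
  sites$turbidity_class <- ifelse(sites$transmissometry > threshold,
                                  "Maumee", "Detroit")
  sites$flagged <- if (!is.null(sites$plume))
    sites$turbidity_class != sites$plume else FALSE
  sites
}

#' Peak weekly larval abundance ratio between plumes
#'
#' For one year, averages larval density over the sites sampled in each week
#' within each plume, takes each plume's peak (maximum) weekly mean -- the
#' standard proxy for larval production -- and returns the two peaks
#' normalized to sum to 1. Ties between weeks resolve to the earlier week,
#' which never changes the ratio value.
#'
#' @param survey Abundance survey data frame (see [read_abundance_survey()])
#'   with columns `year`, `week`, `plume`, `site_id`, `density`.
#' @param year Year to evaluate.
#' @param plumes Character vector of the two plume labels, in the order the
#'   ratio is reported (default `c("Detroit", "Maumee")`).
#' @return List with `ratio` (named numeric of length 2 summing to 1),
#'   `peaks` (peak weekly mean densities), `peak_weeks`.
#' @export
peak_abundance_ratio <- function(survey, year,
                                 plumes = c("Detroit", "Maumee")) {
  sv <- survey[survey$year == year & survey$plume %in% plumes, ]
  if (nrow(sv) == 0) stop("no survey records for year ", year)
  peaks <- peak_weeks <- stats::setNames(numeric(2), plumes)
  for (p in plumes) {
    sp <- sv[sv$plume == p, ]
    if (nrow(sp) == 0) stop("no survey weeks for plume ", p, " in ", year)
    wk <- sort(unique(sp$week))
    means <- vapply(wk, function(w) mean(sp$density[sp$week == w]), 0)
    best <- which.max(means)       # which.max takes the earliest tie
    peaks[p] <- means[best]
    peak_weeks[p] <- wk[best]
  }
  if (sum(peaks) == 0) stop("zero peak abundance in both plumes")
  list(ratio = peaks / sum(peaks), peaks = peaks, peak_weeks = peak_weeks)
}

#' One-way ANOVA of weekly larval abundance within a plume
#'
#' Tests temporal stability of larval abundance: site densities within one
#' plume and year grouped by survey week.
#'
#' @param survey Abundance survey data frame.
#' @param year Year to evaluate.
#' @param plume Plume label.
#' @return List with `f_stat`, `df`, `p_value`, and the underlying `aov` fit.
#' @export
weekly_anova <- function(survey, year, plume) {
  sv <- survey[survey$year == year & survey$plume == plume, ]
  wk_sizes <- table(sv$week)
  if (length(wk_sizes) < 2 || any(wk_sizes < 2))
    stop("weekly ANOVA needs >= 2 weeks with >= 2 sites each")
  if (stats::var(sv$density) == 0)   # no variance anywhere: F = 0 by convention
    return(list(f_stat = 0, df = c(length(wk_sizes) - 1,
                                   nrow(sv) - length(wk_sizes)),
                p_value = 1, fit = NULL))
  fit <- stats::aov(density ~ factor(week), data = sv)
  s <- summary(fit)[[1]]
  list(f_stat = s[["F value"]][1], df = s[["Df"]],
       p_value = s[["Pr(>F)"]][1], fit = fit)
}

#' Observed-versus-expected recruitment chi-square test
#'
#' Compares the observed counts of juveniles assigned to each plume with the
#' counts expected if survival were equal in both habitats, i.e. expected
#' counts proportional to the larval abundance ratio:
#' `E = ratio * (O_1 + O_2)`. The statistic is the uncorrected
#' `chi^2 = sum((O - E)^2 / E)` on 1 degree of freedom (two categories, no
#' continuity correction). A positive residual `O - E` for a plume means
#' recruitment from that plume exceeded its larval production share.
#'
#' @param observed Named or ordered integer vector of length 2: juveniles
#'   assigned to each plume.
#' @param ratio Numeric vector of length 2 summing to 1: the larval abundance
#'   ratio in the same plume order.
#' @return Object of class `recruitment_test`: list with `observed`,
#'   `expected`, `residuals` (O - E, summing to 0), `chi_sq`, `df`, `p_value`,
#'   `n`.
#' @export
recruitment_chi_square <- function(observed, ratio) {
  if (length(observed) != 2 || length(ratio) != 2)
    stop("the test is defined for two plume categories")
  if (abs(sum(ratio) - 1) > 1e-8) stop("'ratio' must sum to 1")
  n <- sum(observed)
  if (n < 1) stop("need at least one assigned juvenile")
  expected <- ratio * n
  if (any(expected == 0 & observed > 0))
    stop("expected count of zero with observed juveniles present")
  chi_sq <- sum((observed - expected)^2 / expected)
  structure(list(observed = observed, expected = expected,
                 residuals = observed - expected, chi_sq = chi_sq, df = 1L,
                 p_value = stats::pchisq(chi_sq, 1, lower.tail = FALSE),
                 n = n),
            class = "recruitment_test")
}

#' @export
print.recruitment_test <- function(x, ...) {
  cat(sprintf("recruitment chi-square: X2 = %.3f, df = %d, p = %.4g\n",
              x$chi_sq, x$df, x$p_value))
  tab <- rbind(observed = x$observed, expected = round(x$expected, 2),
               residual = round(x$residuals, 2))
  print(tab)
  invisible(x)
}

#' Spatial mixing t-tests on assigned juveniles
#'
#' Tests whether juveniles assigned to the two sources were caught in
#' spatially distinct parts of the basin: two-sample t-tests on capture
#' latitude and longitude between the two assigned groups. The classical
#' equal-variance Student's t-test is the default; Welch's correction is
#' available by flag.
#'
#' @param assignments The `results` data frame of an [assign_juveniles()]
#'   output (or any data frame with `category`, `lat`, `lon`).
#' @param groups The two source group labels.
#' @param var_equal Use the pooled-variance Student's t-test (default `TRUE`).
#' @return Data frame with one row per axis (`lat`, `lon`): group means,
#'   `t_stat`, `df`, `p_value`.
#' @export
spatial_mixing_test <- function(assignments, groups, var_equal = TRUE) {
  g1 <- assignments$category == paste0("assigned-", groups[1])
  g2 <- assignments$category == paste0("assigned-", groups[2])
  out <- lapply(c("lat", "lon"), function(ax) {
    v1 <- assignments[[ax]][g1]; v2 <- assignments[[ax]][g2]
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    if (length(v1) < 2 || length(v2) < 2)
      stop("need >= 2 assigned juveniles with coordinates per group for axis ", ax)
    if (stats::sd(c(v1, v2)) == 0) {
      # identical coordinate multisets: no difference by construction
      return(data.frame(axis = ax, mean_1 = mean(v1), mean_2 = mean(v2),
                        t_stat = 0, df = length(v1) + length(v2) - 2,
                        p_value = 1))
    }
    tt <- stats::t.test(v1, v2, var.equal = var_equal)
    data.frame(axis = ax, mean_1 = mean(v1), mean_2 = mean(v2),
               t_stat = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  out <- do.call(rbind, out)
  names(out)[2:3] <- paste0("mean_", groups)
  out
}
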