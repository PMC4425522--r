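#' Run the full plume-recruitment study pipeline
#'
#' Orchestrates the complete analysis on a synthetic or loaded study, per
#' year: per-locus summary tables for each larval group; larval F_ST between
#' plumes with permutation significance and exact differentiation tests;
#' migrant screening of the larval references; two-step juvenile assignment
#' with a category count table; F_ST between the assigned juvenile sets; a
#' threshold sensitivity sweep; the peak larval abundance ratio and the
#' observed-versus-expected recruitment chi-square; and spatial mixing
#' t-tests when coordinates are available. Across years (when more than one),
#' a hierarchical AMOVA partitions larval variance among years, among plumes
#' within years, and within plumes.
#'
#' Group labels are expected to follow the `D06` / `M06` / `JUV06` convention
#' produced by [simulate_study()] (plume initial + two-digit year for larvae;
#' `JUV` + year for juveniles).
#'
#' @param study A `synthetic_study` from [simulate_study()], or a list with
#'   elements `larvae`, `juveniles` ([genotype_dataset()]s), `survey`, and
#'   optionally `sites`.
#' @param config An [assignment_config()].
#' @param n_perm Permutations for F_ST, exact tests and AMOVA (0 skips the
#'   significance machinery, useful in simulation loops).
#' @param thresholds Thresholds for the sensitivity sweep (default
#'   `seq(0.60, 0.90, by = 0.05)`; `NULL` skips the sweep).
#' @param plumes The two plume labels in report order.
#' @param out_dir Optional directory; when given, every table is also written
#'   as CSV.
#' @param seed Optional integer seed governing all stochastic stages.
#' @return List of class `study_report` with one element per stage per year.
#' @export
run_study <- function(study, config = assignment_config(), n_perm = 0,
                      thresholds = seq(0.60, 0.90, by = 0.05),
                      plumes = c("Detroit", "Maumee"), out_dir = NULL,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  larvae <- study$larvae; juveniles <- study$juveniles; survey <- study$survey
  if (n_individuals(juveniles) == 0)
    stop("assignment stage: no juveniles in the study")
  years <- sort(unique(sub("^JUV", "", juveniles$ind$group)))
  report <- list(years = years)

  per_year <- list()
  for (yy in years) {
    gD <- paste0(substr(plumes[1], 1, 1), yy)
    gM <- paste0(substr(plumes[2], 1, 1), yy)
    jg <- paste0("JUV", yy)
    lar_y <- subset_individuals(larvae, larvae$ind$group %in% c(gD, gM))
    juv_y <- subset_individuals(juveniles, juveniles$ind$group == jg)
    res <- list()
    res$summary <- do.call(rbind, lapply(c(gD, gM), function(g)
      cbind(group = g, summarize_genotypes(lar_y, g))))
    res$fst_larvae <- weir_cockerham_fst(lar_y, c(gD, gM), n_perm = n_perm)
    if (n_perm > 0)
      res$exact_larvae <- exact_differentiation(lar_y, gD, gM, n_perm = n_perm)
    screen <- self_assign(lar_y, c(gD, gM), config)
    res$migrant_screen <- screen
    refs <- drop_migrants(lar_y, screen)
    res$assignment <- assign_juveniles(juv_y, refs, config)
    asg <- res$assignment$results
    cat_counts <- c(sum(asg$category == paste0("assigned-", gD)),
                    sum(asg$category == paste0("assigned-", gM)))
    keep <- asg$category %in% paste0("assigned-", c(gD, gM))
    if (sum(keep) >= 4 && all(cat_counts >= 2)) {
      assigned <- subset_individuals(juv_y, which(keep))
      assigned$ind$group <- sub("^assigned-", "", asg$category[keep])
      res$fst_juveniles <- weir_cockerham_fst(assigned, c(gD, gM),
                                              n_perm = n_perm)
    }
    if (!is.null(thresholds))
      res$sensitivity <- sensitivity_sweep(juv_y, refs, thresholds, config)
    year_num <- unique(survey$year)[endsWith(as.character(unique(survey$year)), yy)]
    if (length(year_num) == 1) {
      ab <- peak_abundance_ratio(survey, year_num, plumes)
      res$abundance <- ab
      res$recruitment <- recruitment_chi_square(cat_counts, ab$ratio)
    }
    if (all(cat_counts >= 2) && any(!is.na(asg$lat)))
      res$spatial <- tryCatch(
        spatial_mixing_test(asg, c(gD, gM)), error = function(e) NULL)
    per_year[[yy]] <- res
  }
  report$per_year <- per_year

  if (length(years) >= 2) {
    lab <- larvae$ind$group
    report$amova <- amova(larvae,
                          years = substr(lab, 2, 3),
                          plumes = substr(lab, 1, 1),
                          n_perm = n_perm)
  }
  if (!is.null(out_dir)) write_report(report, out_dir)
  class(report) <- "study_report"
  report
}

# Flat CSV export of the per-year report tables.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (yy in names(report$per_year)) {
    res <- report$per_year[[yy]]
    w <- function(df, nm)
      utils::write.csv(df, file.path(out_dir, sprintf("%s_%s.csv", nm, yy)),
                       row.names = FALSE)
    w(res$summary, "summary")
    w(res$fst_larvae$per_locus, "fst_larvae")
    w(res$migrant_screen, "migrant_screen")
    w(res$assignment$results, "assignments")
    w(res$assignment$summary, "assignment_counts")
    if (!is.null(res$sensitivity)) w(res$sensitivity, "sensitivity")
    if (!is.null(res$recruitment)) {
      rt <- res$recruitment
      w(data.frame(plume = names(res$abundance$ratio),
                   ratio = unname(res$abundance$ratio),
                   observed = unname(rt$observed),
                   expected = unname(rt$expected),
                   residual = unname(rt$residuals),
                   chi_sq = rt$chi_sq, p_value = rt$p_value), "recruitment")
    }
  }
  if (!is.null(report$amova))
    utils::write.csv(as.data.frame(report$amova),
                     file.path(out_dir, "amova.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  for (yy in names(x$per_year)) {
    res <- x$per_year[[yy]]
    cat(sprintf("== year %s ==\n", yy))
    cat(sprintf("  larval theta = %.4f", res$fst_larvae$theta))
    if (!is.na(res$fst_larvae$p_value))
      cat(sprintf(" (p = %.4g)", res$fst_larvae$p_value))
    cat("\n  assignment counts: ")
    print(res$assignment$summary, row.names = FALSE)
    if (!is.null(res$recruitment))
      cat(sprintf("  recruitment X2 = %.3f, p = %.4g\n",
                  res$recruitment$chi_sq, res$recruitment$p_value))
  }
  if (!is.null(x$amova)) {
    cat("== larval AMOVA ==\n")
    print(as.data.frame(x$amova), row.names = FALSE)
  }
  invisible(x)
}
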