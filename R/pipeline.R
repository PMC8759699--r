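default_config <- function() {
  list(enrollment_threshold = 20,
       homa_bc_variant = "mmol",
       auc_window = c(0, 180),
       control = minmod_control())
}

# The 13 between-group endpoints; AUCs use the pooled t-test, all others
# Mann-Whitney U.
endpoint_plan <- function() {
  data.frame(
    endpoint = c("SI", "Sg", "AIRg", "DI", "homa_ir", "homa_bc_pct",
                 "quicki", "risqi", "mirg", "auc_glucose", "auc_insulin",
                 "baseline_glucose", "baseline_insulin"),
    table = c("fits", "fits", "fits", "fits", "proxies", "proxies",
              "proxies", "proxies", "proxies", "summaries", "summaries",
              "summaries", "summaries"),
    test = c(rep("mann_whitney", 9), "t", "t", "mann_whitney",
             "mann_whitney"),
    stringsAsFactors = FALSE)
}

#' Run the end-to-end I-FSIGTT analysis
#'
#' Applies the enrollment filter, fits the minimal model and computes the
#' proxy panel and response summary for every retained subject, then
#' performs the between-group comparisons (Mann-Whitney U for the model
#' parameters, proxies and baselines; pooled-variance t for the AUCs —
#' no multiple-testing correction across endpoints, since each endpoint
#' describes a different aspect of glucose/insulin homeostasis), the
#' within-group Friedman/Dunn time-course tests for glucose and insulin,
#' and the Spearman correlation between foal age and SI. Subjects whose
#' fit fails are quarantined (listed with the error, excluded from the
#' group statistics) rather than aborting the run.
#'
#' @param cohort An [ifsigtt_cohort()], or a path to a cohort CSV.
#' @param config Optional list overriding entries of the default
#'   configuration (`enrollment_threshold`, `homa_bc_variant`,
#'   `auc_window`, `control`).
#' @return An object of class `ifsigtt_report`: `fits`, `proxies`,
#'   `summaries` (per-subject data frames), `comparisons` (list of
#'   `cohort_comparison`), `comparison_table` (flat data frame),
#'   `within_group_time_tests`, `age_si_correlation`, `excluded`,
#'   `fit_failures`, `counts`, `provenance`.
#' @export
run_analysis <- function(cohort, config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  stopifnot(inherits(cohort, "ifsigtt_cohort"))
  n_input <- length(cohort)

  filt <- apply_enrollment_filter(cohort, cfg$enrollment_threshold)
  cohort <- filt$cohort
  groups <- cohort_groups(cohort)
  if (!all(c("foal", "horse") %in% groups)) {
    stop("pipeline error: need >= 1 subject per group after the ",
         "enrollment filter", call. = FALSE)
  }

  fits <- list()
  failures <- data.frame(subject_id = character(), error = character(),
                         stringsAsFactors = FALSE)
  prox <- list()
  summ <- list()
  for (s in cohort$subjects) {
    res <- tryCatch(list(
      fit = ifsigtt_fit(s, cohort$protocol, cfg$control),
      prox = proxy_panel(s, cfg$homa_bc_variant),
      summ = summarize_subject(s, cfg$auc_window[1], cfg$auc_window[2],
                               cohort$protocol$insulin_time)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures, data.frame(
        subject_id = s$subject_id, error = conditionMessage(res),
        stringsAsFactors = FALSE))
      message("subject quarantined: ", s$subject_id, ": ",
              conditionMessage(res))
      next
    }
    fits[[s$subject_id]] <- res$fit
    prox[[s$subject_id]] <- res$prox
    summ[[s$subject_id]] <- res$summ
  }
  if (length(fits) == 0) stop("pipeline error: every fit failed",
                              call. = FALSE)

  fit_df <- do.call(rbind, lapply(fits, function(f) data.frame(
    subject_id = f$subject_id, group = f$group, SI = f$SI,
    Sg = f$params$Sg, p2 = f$params$p2, p3 = f$params$p3,
    G0 = f$params$G0, Gb = f$params$Gb, Ib = f$params$Ib,
    AIRg = f$AIRg, DI = f$DI, residual_sse = f$residual_sse,
    n_points_fit = f$n_points_fit, at_bound = f$at_bound,
    stringsAsFactors = FALSE)))
  prox_df <- do.call(rbind, prox)
  summ_df <- do.call(rbind, summ)
  rownames(fit_df) <- rownames(prox_df) <- rownames(summ_df) <- NULL
  tables <- list(fits = fit_df, proxies = as.data.frame(prox_df),
                 summaries = as.data.frame(summ_df))

  plan <- endpoint_plan()
  comparisons <- vector("list", nrow(plan))
  names(comparisons) <- plan$endpoint
  for (i in seq_len(nrow(plan))) {
    tab <- tables[[plan$table[i]]]
    v <- tab[[plan$endpoint[i]]]
    g <- tab$group
    comparisons[[i]] <- tryCatch({
      if (plan$test[i] == "t") {
        students_t(v[g == "foal"], v[g == "horse"], plan$endpoint[i],
                   labels = c("foal", "horse"))
      } else {
        mann_whitney_u(v[g == "foal"], v[g == "horse"], plan$endpoint[i],
                       labels = c("foal", "horse"))
      }
    }, error = function(e) {
      new_comparison(plan$endpoint[i], list(), NA_real_, "failed",
                     NA_real_, NA_real_, note = conditionMessage(e))
    })
  }

  # within-group repeated-measures tests on the raw concentrations
  block <- function(analyte, grp) {
    subs <- cohort$subjects[cohort_groups(cohort) == grp]
    subs <- subs[vapply(subs, function(s) s$subject_id %in% fit_df$subject_id,
                        logical(1))]
    times <- cohort$protocol$sample_times
    times <- times[times >= 0]
    m <- t(vapply(subs, function(s) {
      s[[analyte]][match(times, s$times)]
    }, numeric(length(times))))
    colnames(m) <- times
    friedman_with_dunns(m, baseline_col = which(times == 0))
  }
  within_tests <- list(
    glucose = list(foal = block("glucose", "foal"),
                   horse = block("glucose", "horse")),
    insulin = list(foal = block("insulin", "foal"),
                   horse = block("insulin", "horse")))

  foal_rows <- fit_df$group == "foal"
  ages <- vapply(cohort$subjects, function(s) s$age, numeric(1))
  names(ages) <- cohort_ids(cohort)
  foal_age <- ages[fit_df$subject_id[foal_rows]]
  age_si <- if (sum(!is.na(foal_age)) >= 3) {
    tryCatch(spearman_cor(foal_age, fit_df$SI[foal_rows],
                          endpoint = "foal age (h) vs SI"),
             error = function(e) NULL)
  } else NULL

  report <- list(
    fits = fit_df, proxies = tables$proxies, summaries = tables$summaries,
    fit_objects = fits, comparisons = comparisons,
    comparison_table = comparison_table(comparisons),
    within_group_time_tests = within_tests,
    age_si_correlation = age_si,
    excluded = filt$excluded, fit_failures = failures,
    counts = c(n_input = n_input, n_retained = nrow(fit_df),
               n_filter_excluded = length(filt$excluded),
               n_fit_failed = nrow(failures)),
    provenance = list(
      config = cfg[c("enrollment_threshold", "homa_bc_variant",
                     "auc_window")],
      fit_control = unclass(cfg$control),
      package_version = as.character(utils::packageVersion("ifsigtt"))))
  class(report) <- "ifsigtt_report"
  report
}

comparison_table <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(cmp) {
    gs <- cmp$group_summaries
    pick <- function(grp, field) {
      if (is.null(gs[[grp]])) NA_real_ else unname(gs[[grp]][field])
    }
    data.frame(
      endpoint = cmp$endpoint, statistic_name = cmp$statistic_name,
      statistic = cmp$statistic, df = cmp$df, p_value = cmp$p_value,
      foal_median = pick("foal", "median"), foal_q25 = pick("foal", "q25"),
      foal_q75 = pick("foal", "q75"), foal_mean = pick("foal", "mean"),
      foal_ci_lo = pick("foal", "ci_lo"), foal_ci_hi = pick("foal", "ci_hi"),
      horse_median = pick("horse", "median"),
      horse_q25 = pick("horse", "q25"), horse_q75 = pick("horse", "q75"),
      horse_mean = pick("horse", "mean"),
      horse_ci_lo = pick("horse", "ci_lo"),
      horse_ci_hi = pick("horse", "ci_hi"),
      stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' @export
print.ifsigtt_report <- function(x, ...) {
  cat("I-FSIGTT analysis report\n")
  cat(sprintf("  subjects: %d in, %d retained, %d filter-excluded, %d fit-failed\n",
              x$counts["n_input"], x$counts["n_retained"],
              x$counts["n_filter_excluded"], x$counts["n_fit_failed"]))
  cat("Between-group comparisons:\n")
  tab <- x$comparison_table
  show <- data.frame(endpoint = tab$endpoint,
                     foal = ifelse(is.na(tab$foal_median),
                                   signif(tab$foal_mean, 4),
                                   signif(tab$foal_median, 4)),
                     horse = ifelse(is.na(tab$horse_median),
                                    signif(tab$horse_mean, 4),
                                    signif(tab$horse_median, 4)),
                     stat = paste0(tab$statistic_name, " = ",
                                   signif(tab$statistic, 4)),
                     p = signif(tab$p_value, 3))
  print(show, row.names = FALSE)
  if (!is.null(x$age_si_correlation)) {
    cat(sprintf("Foal age vs SI: rho = %.3f, p = %.3f\n",
                x$age_si_correlation$statistic,
                x$age_si_correlation$p_value))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits five files with stable names: `fits.csv`, `proxies.csv`,
#' `summaries.csv` (per-subject tables), `comparisons.csv` and
#' `comparisons.json` (between-group results plus counts and
#' provenance). Reruns on identical input produce byte-identical
#' payloads.
#'
#' @param report An `ifsigtt_report`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the five file paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "ifsigtt_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create ", out_dir, call. = FALSE)
  }
  paths <- file.path(out_dir, c("fits.csv", "proxies.csv",
                                "summaries.csv", "comparisons.csv",
                                "comparisons.json"))
  utils::write.csv(report$fits, paths[1], row.names = FALSE)
  utils::write.csv(report$proxies, paths[2], row.names = FALSE)
  utils::write.csv(report$summaries, paths[3], row.names = FALSE)
  utils::write.csv(report$comparison_table, paths[4], row.names = FALSE)
  jsonlite::write_json(
    list(comparisons = report$comparison_table,
         counts = as.list(report$counts),
         excluded = report$excluded,
         fit_failures = report$fit_failures,
         provenance = report$provenance),
    paths[5], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
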