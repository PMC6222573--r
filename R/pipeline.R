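#' Pipeline configuration
#'
#' Collects the tunable choices of the full analysis: the behavioral /
#' non-behavioral trait partition for the trait-type comparison, the
#' dimensionless variance-floor scale for the regression weights, the
#' mean-scaling convention for the evolvability fit, the significance
#' test for the among-line variance, the number of permutations, and the
#' seed that makes permutation p-values reproducible.
#'
#' @param behavioral,non_behavioral Trait partition for
#'   [compare_trait_types()].
#' @param variance_floor_scale Passed to [estimate_delta_m()].
#' @param scaling Passed to [estimate_cv_m2()].
#' @param vg_test `"permutation"`, `"lrt"`, or `"none"`.
#' @param n_null Permutations for the among-line variance test.
#' @param seed Integer seed for the permutation test.
#' @return A list of class `"ma_config"`.
#' @export
ma_config <- function(behavioral = behavioral_traits(),
                      non_behavioral = non_behavioral_traits(),
                      variance_floor_scale = 1e-8,
                      scaling = "grand_mean",
                      vg_test = "permutation",
                      n_null = 1000,
                      seed = 1L) {
  structure(list(behavioral = behavioral, non_behavioral = non_behavioral,
                 variance_floor_scale = variance_floor_scale,
                 scaling = scaling, vg_test = vg_test,
                 n_null = n_null, seed = seed),
            class = "ma_config")
}

#' Run the full MA analysis
#'
#' Phenotype table in, report out: per-line summaries feed the
#' mutational-bias regression ([estimate_delta_m()]) and the REML
#' evolvability fit ([estimate_cv_m2()]) for every genotype-trait, and
#' the resulting bias estimates are compared across traits, trait types,
#' genotypes and populations ([hierarchy_tests()]). Deterministic for a
#' fixed input and config.
#'
#' @param records Phenotype tibble (canonical columns), e.g. from
#'   [read_phenotypes()] or [simulate_experiment()].
#' @param config An [ma_config()].
#' @return A list of class `"ma_report"` with elements `estimates` (one
#'   row per genotype-trait: GOD, z0, delta_M with SE/t/p, CV_m^2 with
#'   variance components and p), `comparisons` (the four hierarchy
#'   tests), and `log` (notes on floors hit and boundary fits).
#' @export
run_ma_pipeline <- function(records, config = ma_config()) {
  stopifnot(inherits(config, "ma_config"))
  problems <- validate_phenotypes(records)
  if (nrow(problems) > 0)
    stop("input failed validation (", nrow(problems), " problem(s)); ",
         "first: row ", problems$row[1], " [", problems$field[1], "] ",
         problems$message[1])
  notes <- character()
  bias <- withCallingHandlers(
    estimate_delta_m(records, variance_floor_scale = config$variance_floor_scale),
    warning = function(w) {
      notes <<- c(notes, paste("delta_m:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  evol <- withCallingHandlers(
    estimate_cv_m2(records, scaling = config$scaling,
                   test = config$vg_test, n_null = config$n_null,
                   seed = config$seed),
    warning = function(w) {
      notes <<- c(notes, paste("cv_m2:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  estimates <- dplyr::left_join(
    bias,
    dplyr::rename(evol, p_cv_m2 = "p", god_cv = "god"),
    by = c("population", "genotype", "trait")
  ) |>
    dplyr::rename(p_delta_m = "p") |>
    dplyr::select(-"god_cv")
  n_boundary <- sum(estimates$boundary, na.rm = TRUE)
  if (n_boundary > 0)
    notes <- c(notes, paste0("cv_m2: ", n_boundary,
                             " genotype-trait fit(s) at the v_g = 0 boundary"))
  comparisons <- hierarchy_tests(estimates,
                                 behavioral = config$behavioral,
                                 non_behavioral = config$non_behavioral)
  structure(list(estimates = estimates, comparisons = comparisons, log = notes),
            class = "ma_report")
}

#' @export
print.ma_report <- function(x, ...) {
  cat("MA analysis report:", nrow(x$estimates), "genotype-trait estimates\n\n")
  print(x$estimates, n = Inf)
  cat("\nHierarchy comparisons:\n")
  print(x$comparisons)
  if (length(x$log) > 0) cat("\nNotes:\n", paste("-", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a report to CSV files
#'
#' Writes `estimates.csv`, `comparisons.csv` and `log.txt` under `dir`.
#'
#' @param report An `"ma_report"` from [run_ma_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$estimates, file.path(dir, "estimates.csv"),
                   progress = FALSE)
  readr::write_csv(report$comparisons, file.path(dir, "comparisons.csv"),
                   progress = FALSE)
  writeLines(report$log, file.path(dir, "log.txt"))
  invisible(dir)
}

group_mean_se <- function(value, group) {
  tibble::tibble(value = value, group = group) |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
}

#' Summary bar plots of the mutational-bias estimates
#'
#' Four panels in the spirit of a standard MA-experiment figure: mean
#' |delta_M| by trait and by trait type, and mean signed delta_M by
#' genotype and by population, each with +/- SE bars computed across the
#' per-genotype-trait estimates in the group.
#'
#' @param estimates Estimates tibble (from [run_ma_pipeline()]'s
#'   `$estimates`, [estimate_delta_m()], or [dmagna_ma_estimates()]).
#' @param behavioral,non_behavioral Trait partition for the type panel.
#' @return Named list of ggplot objects: `traits`, `trait_types`,
#'   `genotypes`, `populations`. Panels whose grouping has a single
#'   level are dropped with a warning.
#' @export
plot_delta_m <- function(estimates,
                         behavioral = behavioral_traits(),
                         non_behavioral = non_behavioral_traits()) {
  panels <- list(
    traits = list(v = abs(estimates$delta_m), g = estimates$trait,
                  ylab = "|delta_M|"),
    trait_types = list(
      v = abs(estimates$delta_m),
      g = ifelse(estimates$trait %in% behavioral, "behavioral", "non-behavioral"),
      ylab = "|delta_M|"),
    genotypes = list(v = estimates$delta_m,
                     g = paste0(estimates$population, estimates$genotype),
                     ylab = "delta_M"),
    populations = list(v = estimates$delta_m, g = estimates$population,
                       ylab = "delta_M")
  )
  out <- list()
  for (nm in names(panels)) {
    p <- panels[[nm]]
    if (length(unique(p$g)) < 2) {
      warning("panel '", nm, "' skipped: a single group")
      next
    }
    dat <- group_mean_se(p$v, p$g)
    out[[nm]] <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$mean)) +
      ggplot2::geom_col(fill = "grey70", color = "black", width = 0.7) +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
        width = 0.2) +
      ggplot2::labs(x = NULL, y = p$ylab, title = gsub("_", " ", nm)) +
      ggplot2::theme_classic()
  }
  out
}

#' Write the summary panels to files
#'
#' @inheritParams plot_delta_m
#' @param dir Output directory.
#' @param device File extension understood by [ggplot2::ggsave()]
#'   (default `"png"`).
#' @return Character vector of the files written, invisibly.
#' @export
plot_summaries <- function(estimates, dir,
                           behavioral = behavioral_traits(),
                           non_behavioral = non_behavioral_traits(),
                           device = "png") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plots <- plot_delta_m(estimates, behavioral, non_behavioral)
  files <- character()
  for (nm in names(plots)) {
    f <- file.path(dir, paste0("delta_m_", nm, ".", device))
    ggplot2::ggsave(f, plots[[nm]], width = 5, height = 4, dpi = 150)
    files <- c(files, f)
  }
  invisible(files)
}
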