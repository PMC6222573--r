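#' @importFrom rlang .data
#' @importFrom stats var
NULL

#' Canonical phenotype-table columns
#'
#' Long-format MA phenotype tables have one row per individual per trait,
#' tagged with population, genotype, line class (`"control"` or `"MA"`),
#' line id, individual id, trait, measured value, and generations of
#' divergence from the control population (0 for control individuals).
#'
#' @return Character vector of the canonical column names, in order.
#' @export
phenotype_columns <- function() {
  c("population", "genotype", "line_class", "line_id", "individual_id",
    "trait", "value", "generations")
}

#' Validate a phenotype table
#'
#' Checks the structural invariants of a long-format MA phenotype table:
#' finite values, non-negative generations, `generations == 0` exactly for
#' control rows and `> 0` for MA rows, a known line class, and a single
#' line class per (genotype, line_id).
#'
#' @param x A data frame with the columns of [phenotype_columns()].
#' @return A tibble validation report with columns `row`, `field`,
#'   `message`; zero rows when the table is valid.
#' @export
validate_phenotypes <- function(x) {
  problems <- list()
  note <- function(row, field, message) {
    problems[[length(problems) + 1L]] <<- tibble::tibble(
      row = as.integer(row), field = field, message = message
    )
  }
  bad_value <- which(!is.finite(x$value))
  for (i in bad_value) note(i, "value", "value is missing or not finite")
  bad_gen <- which(!is.finite(x$generations) | x$generations < 0)
  for (i in bad_gen) note(i, "generations", "generations is missing, non-finite or negative")
  bad_class <- which(!x$line_class %in% c("control", "MA"))
  for (i in bad_class) note(i, "line_class", "line_class must be 'control' or 'MA'")

  ok_gen <- is.finite(x$generations)
  ctrl_pos <- which(x$line_class == "control" & ok_gen & x$generations != 0)
  for (i in ctrl_pos) note(i, "generations", "control rows must have generations = 0")
  ma_zero <- which(x$line_class == "MA" & ok_gen & x$generations <= 0)
  for (i in ma_zero) note(i, "generations", "MA rows must have generations > 0")

  # one line class per (genotype, line_id)
  key <- paste(x$genotype, x$line_id, sep = "\r")
  n_class <- tapply(x$line_class, key, function(z) length(unique(z)))
  for (k in names(n_class)[n_class > 1]) {
    rows <- which(key == k)
    note(rows[1], "line_id",
         sprintf("line '%s' appears with more than one line_class", x$line_id[rows[1]]))
  }
  if (length(problems) == 0) {
    tibble::tibble(row = integer(), field = character(), message = character())
  } else {
    dplyr::bind_rows(problems)
  }
}

#' Read a long-format phenotype CSV
#'
#' Reads an MA phenotype table and coerces it to the canonical column set.
#' Rows that fail numeric coercion or violate a structural invariant are
#' collected into a validation report attached as the `"problems"`
#' attribute (readr-style), never silently dropped; pass `strict = TRUE`
#' to turn a non-empty report into an error.
#'
#' @param path Path to a CSV file with a header row.
#' @param col_map Optional named character vector mapping canonical names
#'   (see [phenotype_columns()]) to the file's actual header names, e.g.
#'   `c(value = "phenotype")`. Unmapped canonical names must appear
#'   verbatim in the file.
#' @param strict Error if any row fails validation (default `FALSE`).
#' @return A tibble of phenotype records with attribute `"problems"`
#'   (a validation report as from [validate_phenotypes()]).
#' @export
read_phenotypes <- function(path, col_map = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  wanted <- phenotype_columns()
  map <- stats::setNames(wanted, wanted)
  if (!is.null(col_map)) {
    unknown <- setdiff(names(col_map), wanted)
    if (length(unknown) > 0)
      stop("col_map names must be canonical columns; unknown: ",
           paste(unknown, collapse = ", "))
    map[names(col_map)] <- unname(col_map)
  }
  missing <- map[!map %in% names(raw)]
  if (length(missing) > 0)
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  out <- tibble::as_tibble(stats::setNames(raw[unname(map)], wanted))
  out$value <- suppressWarnings(as.numeric(out$value))
  out$generations <- suppressWarnings(as.numeric(out$generations))
  problems <- validate_phenotypes(out)
  if (strict && nrow(problems) > 0)
    stop("phenotype table failed validation (", nrow(problems), " problem(s)); ",
         "first: row ", problems$row[1], " [", problems$field[1], "] ",
         problems$message[1])
  attr(out, "problems") <- problems
  out
}

#' Write a phenotype table to CSV
#'
#' Inverse of [read_phenotypes()]: writes the canonical columns with full
#' precision so that a write/read round trip preserves all fields.
#'
#' @param records Phenotype tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path) {
  readr::write_csv(records[phenotype_columns()], path, progress = FALSE)
  invisible(path)
}

#' Write a validation report to CSV
#'
#' @param problems Report from [validate_phenotypes()] or the
#'   `"problems"` attribute of [read_phenotypes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(problems, path) {
  readr::write_csv(problems, path, progress = FALSE)
  invisible(path)
}

#' Summarize MA lines and the control population for one genotype-trait
#'
#' Computes, for a single genotype and trait, the per-line summaries that
#' feed the mutational-bias regression: each MA line's mean phenotype
#' `z_M`, its sample variance (n-1 denominator), the sampling variance of
#' the mean (`s^2 / n`), and its generations of divergence; and the pooled
#' control summary (`z_0`). All control individuals of the genotype are
#' pooled into a single control population, mirroring designs where
#' replicate control jars are mixed.
#'
#' @param records Phenotype tibble (canonical columns).
#' @param genotype Genotype identifier to subset on.
#' @param trait Trait identifier to subset on.
#' @return A list with elements `lines` (tibble: `line_id`, `n`, `mean`,
#'   `sample_variance`, `sampling_variance`, `generations`, `flagged`) and
#'   `control` (tibble: `mean`, `n`, `sampling_variance`). Lines with a
#'   single individual have `NA` sampling variance and `flagged = TRUE`.
#' @export
summarize_lines <- function(records, genotype, trait) {
  sub <- records[records$genotype == genotype & records$trait == trait, ]
  ctrl <- sub[sub$line_class == "control", ]
  ma <- sub[sub$line_class == "MA", ]
  if (nrow(ctrl) == 0)
    stop("no control records for genotype '", genotype, "', trait '", trait, "'")
  if (nrow(ma) == 0)
    stop("no MA records for genotype '", genotype, "', trait '", trait, "'")

  lines <- ma |>
    dplyr::group_by(line_id = .data$line_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sample_variance = ifelse(dplyr::n() >= 2, var(.data$value), NA_real_),
      generations = {
        g <- unique(.data$generations)
        if (length(g) > 1)
          stop("line '", .data$line_id[1], "' has inconsistent generations")
        g
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sampling_variance = .data$sample_variance / .data$n,
      flagged = .data$n < 2
    ) |>
    dplyr::select("line_id", "n", "mean", "sample_variance",
                  "sampling_variance", "generations", "flagged")

  control <- tibble::tibble(
    mean = mean(ctrl$value),
    n = nrow(ctrl),
    sampling_variance = if (nrow(ctrl) >= 2) var(ctrl$value) / nrow(ctrl) else NA_real_
  )
  list(lines = lines, control = control)
}

#' Mean generations of divergence across MA lines
#'
#' The unweighted arithmetic mean of the per-line generations of
#' divergence (the genotype-level "GOD" that scales the among-line
#' variance into a per-generation evolvability).
#'
#' @param lines Line-summary tibble from [summarize_lines()], or a numeric
#'   vector of per-line generations.
#' @return The mean generations of divergence.
#' @export
mean_generations <- function(lines) {
  g <- if (is.data.frame(lines)) lines$generations else lines
  if (length(g) == 0) stop("no lines: cannot average generations of divergence")
  mean(g)
}

#' Published MA estimates for six Daphnia magna genotypes
#'
#' Published per-genotype, per-trait estimates from a mutation-accumulation
#' experiment on six *Daphnia magna* genotypes (three per source population,
#' Germany and Israel; five MA lines per genotype): mean generations of
#' divergence (`god`), control mean phenotype (`z0`), mutational bias
#' (`delta_m`) and evolvability (`cv_m2`). Traits: `AM` age at maturity,
#' `Egg` egg number at maturity, `Size` body length at maturity, `MaxV`,
#' `MeanV`, `SDV` maximum / mean / standard deviation of swimming velocity.
#' Useful as a realistic input for the hierarchy comparisons and as the
#' template the synthetic generator emulates.
#'
#' @return Tibble with columns `population`, `genotype`, `trait`, `god`,
#'   `z0`, `delta_m`, `cv_m2` (36 rows), plus a `trait_type` column
#'   (`"behavioral"` for the velocity traits, `"non_behavioral"` otherwise).
#' @export
dmagna_ma_estimates <- function() {
  path <- system.file("extdata", "dmagna_ma_estimates.csv", package = "mutacc",
                      mustWork = TRUE)
  x <- readr::read_csv(path, col_types = "cccdddd", progress = FALSE)
  x$trait_type <- ifelse(x$trait %in% behavioral_traits(),
                         "behavioral", "non_behavioral")
  x
}

#' Default trait sets
#'
#' The six assayed traits, split into behavioral (velocity) and
#' non-behavioral (life-history and morphology) sets. These are the
#' default groupings for trait-type comparisons.
#'
#' @return Character vector of trait codes.
#' @export
behavioral_traits <- function() c("MaxV", "MeanV", "SDV")

#' @rdname behavioral_traits
#' @export
non_behavioral_traits <- function() c("AM", "Egg", "Size")
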