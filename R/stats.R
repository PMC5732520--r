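#' Ordinary least-squares regression with slope test
#'
#' Thin wrapper over [stats::lm()] returning the quantities the validation
#' report uses: slope, intercept, R^2 and the two-sided p-value of the
#' slope t-test.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return A one-row tibble of class `regression_result`: `slope`,
#'   `intercept`, `r2`, `p_value`, `n`.
#' @export
linreg <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need matching x/y of length >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("zero variance in x: regression undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      # noise-free synthetic cohorts legitimately produce perfect fits
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  out <- tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    n = length(x)
  )
  class(out) <- c("regression_result", class(out))
  out
}

#' Mann-Whitney U test
#'
#' Exact enumeration p-value when both groups have at most 8 observations
#' and no ties; normal approximation with tie correction otherwise
#' (no continuity correction). `U` counts pairs where an `a` value is below
#' a `b` value (+ half the ties).
#'
#' @param a,b Numeric group samples.
#' @param exact_max Per-group size limit for the exact p (default 8).
#' @return A one-row tibble: `U`, `p_value`, `n_a`, `n_b`, `exact`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 8L) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- any(duplicated(c(a, b)))
  exact <- length(a) <= exact_max && length(b) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  # wilcox.test's W is the Mann-Whitney U of the first group
  tibble::tibble(
    U = unname(wt$statistic), p_value = wt$p.value,
    n_a = length(a), n_b = length(b), exact = exact
  )
}

#' Cohort-level validation report
#'
#' Runs the five validation analyses on a cohort of specimens with paired
#' mechanical and FE metrics: (1) mechanical vs FE fracture-load
#' regression, (2) mechanical vs FE stiffness regression, (3) fracture
#' load vs stiffness within each source, (4) right-vs-left Mann-Whitney
#' tests on load and stiffness, (5) fracture load vs age regression per
#' source.
#'
#' @param records A data frame with one row per specimen and columns
#'   `specimen`, `age`, `sex`, `side` (`"right"`/`"left"`),
#'   `mech_fracture_load`, `mech_stiffness`, `fea_fracture_load`,
#'   `fea_stiffness`.
#' @return Object of class `cohort_report`: list of tibbles `regressions`
#'   (analysis, source, slope, intercept, r2, p), `laterality`
#'   (Mann-Whitney per metric/source), and the input `records`.
#' @export
cohort_report <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("specimen", "age", "side", "mech_fracture_load",
              "mech_stiffness", "fea_fracture_load", "fea_stiffness")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("cohort records missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- records$specimen[!stats::complete.cases(records[needed])]
  if (length(bad)) {
    stop("cohort records with missing fields for specimens: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) < 3L) stop("need at least 3 specimens", call. = FALSE)

  reg_row <- function(analysis, source, x, y) {
    r <- linreg(x, y)
    tibble::tibble(analysis = analysis, source = source,
                   slope = r$slope, intercept = r$intercept,
                   r2 = r$r2, p_value = r$p_value, n = r$n)
  }
  regressions <- dplyr::bind_rows(
    reg_row("fracture_load_mech_vs_fea", "both",
            records$fea_fracture_load, records$mech_fracture_load),
    reg_row("stiffness_mech_vs_fea", "both",
            records$fea_stiffness, records$mech_stiffness),
    reg_row("load_vs_stiffness", "mechanical",
            records$mech_stiffness, records$mech_fracture_load),
    reg_row("load_vs_stiffness", "fea",
            records$fea_stiffness, records$fea_fracture_load),
    reg_row("load_vs_age", "mechanical",
            records$age, records$mech_fracture_load),
    reg_row("load_vs_age", "fea",
            records$age, records$fea_fracture_load)
  )
  right <- records[records$side == "right", ]
  left <- records[records$side == "left", ]
  lat_row <- function(metric, col) {
    mw <- mann_whitney_u(right[[col]], left[[col]])
    tibble::tibble(metric = metric, U = mw$U, p_value = mw$p_value,
                   n_right = mw$n_a, n_left = mw$n_b)
  }
  laterality <- dplyr::bind_rows(
    lat_row("mech_fracture_load", "mech_fracture_load"),
    lat_row("mech_stiffness", "mech_stiffness"),
    lat_row("fea_fracture_load", "fea_fracture_load"),
    lat_row("fea_stiffness", "fea_stiffness")
  )
  structure(
    list(regressions = regressions, laterality = laterality,
         records = records),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d specimens\n", nrow(x$records)))
  print(x$regressions)
  print(x$laterality)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_report <- function(x, ...) x$regressions

#' @exportS3Method generics::glance
glance.cohort_report <- function(x, ...) {
  r2_load <- x$regressions$r2[
    x$regressions$analysis == "fracture_load_mech_vs_fea"]
  age_slope <- x$regressions$slope[
    x$regressions$analysis == "load_vs_age" &
      x$regressions$source == "mechanical"]
  tibble::tibble(
    n_specimens = nrow(x$records),
    load_mech_vs_fea_r2 = r2_load,
    mech_age_slope = age_slope,
    laterality_min_p = min(x$laterality$p_value)
  )
}

#' Write a cohort report to JSON (and its tables to CSV)
#' @param report A [cohort_report()].
#' @param path Output `.json` path; regression/laterality CSVs are written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(report, path) {
  jsonlite::write_json(
    list(regressions = report$regressions, laterality = report$laterality),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  base <- sub("\\.json$", "", path)
  utils::write.csv(report$regressions, paste0(base, "_regressions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$laterality, paste0(base, "_laterality.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Multiple regression of fracture load on age, sex and side
#'
#' Ordinary least squares with coefficient t-tests, the adjunct analysis
#' reported alongside the cohort tables.
#'
#' @param records As in [cohort_report()], with a `sex` column.
#' @param response Column to model (default `"mech_fracture_load"`).
#' @return Tidy coefficient tibble (term, estimate, std_error, t, p).
#' @export
load_predictors <- function(records, response = "mech_fracture_load") {
  records <- tibble::as_tibble(records)
  fit <- stats::lm(
    stats::reformulate(c("age", "sex", "side"), response = response),
    data = records
  )
  cf <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )$coefficients
  tibble::tibble(
    term = rownames(cf), estimate = unname(cf[, 1]),
    std_error = unname(cf[, 2]), t = unname(cf[, 3]),
    p_value = unname(cf[, 4])
  )
}

#' Plot cohort validation regressions
#' @param object A [cohort_report()].
#' @param ... Unused.
#' @return A ggplot object: mechanical vs FE fracture load with the fitted
#'   line.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_report <- function(object, ...) {
  reg <- object$regressions[
    object$regressions$analysis == "fracture_load_mech_vs_fea", ]
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$fea_fracture_load,
                               y = .data$mech_fracture_load)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = reg$slope, intercept = reg$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "FE-predicted fracture load (N)",
      y = "Mechanical fracture load (N)",
      title = sprintf("Fracture load: mech = %.3f x FE + %.1f (R2 = %.3f)",
                      reg$slope, reg$intercept, reg$r2)
    )
}
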