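# Cohort-level accounting: diagnostic yield, carrier enrichment and the
# recruitment/solve summary.

#' Diagnostic yield as a percentage
#'
#' @param n_solved,n_total Solved and total case counts,
#'   `0 <= n_solved <= n_total`, `n_total > 0`.
#' @return `100 * n_solved / n_total` rounded to one decimal place.
#' @examples
#' diagnostic_yield(10, 41) # 24.4
#' diagnostic_yield(18, 41) # 43.9
#' @export
diagnostic_yield <- function(n_solved, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0", call. = FALSE)
  if (any(n_solved < 0) || any(n_solved > n_total)) {
    stop("n_solved must be in [0, n_total]", call. = FALSE)
  }
  round(100 * n_solved / n_total, 1)
}

#' Carrier enrichment of a variant in a study subcohort
#'
#' Compares a variant's carrier percentage in the full cohort with its
#' percentage in a phenotype-defined subcohort. Percentages follow the
#' reporting convention of cohort-wide rates to 2 decimal places and
#' subcohort rates to 1.
#'
#' @param carriers_cohort,n_cohort Carriers and denominator in the full
#'   cohort.
#' @param carriers_sub,n_sub Carriers and denominator in the subcohort;
#'   `carriers_sub <= carriers_cohort`, `n_sub <= n_cohort`.
#' @return One-row tibble: `pct_cohort`, `pct_sub`, `ratio`
#'   (`pct_sub / pct_cohort`; `NA` when both rates are zero).
#' @examples
#' carrier_enrichment(15, 75000, 3, 11) # 0.02% vs 27.3%
#' @export
carrier_enrichment <- function(carriers_cohort, n_cohort, carriers_sub, n_sub) {
  if (n_cohort <= 0 || n_sub <= 0) stop("denominators must be > 0", call. = FALSE)
  if (carriers_sub > carriers_cohort) {
    stop("carriers_sub cannot exceed carriers_cohort", call. = FALSE)
  }
  if (n_sub > n_cohort) stop("n_sub cannot exceed n_cohort", call. = FALSE)
  pct_cohort <- round(100 * carriers_cohort / n_cohort, 2)
  pct_sub <- round(100 * carriers_sub / n_sub, 1)
  ratio <- if (pct_cohort == 0) NA_real_ else pct_sub / pct_cohort
  tibble::tibble(pct_cohort = pct_cohort, pct_sub = pct_sub, ratio = ratio)
}

#' Recruitment and solve accounting for a case manifest
#'
#' Counts cases by recruitment status and solve status and computes the
#' diagnostic yield over correctly recruited cases before and after the
#' second-hit screen (i.e. with and without the newly solved cases).
#'
#' @param cases Case manifest tibble ([read_case_manifest()]); must be
#'   non-empty.
#' @return An object of class `cohort_summary` (also a list):
#'   `n_recruited`, `n_excluded`, `n_no_first_hit_info`,
#'   `n_correctly_recruited`, `n_previously_solved`, `n_newly_solved`,
#'   `yield_before`, `yield_after`. Supports `tidy()`, `glance()` and
#'   `print()`.
#' @export
cohort_summary <- function(cases) {
  if (!is.data.frame(cases) || nrow(cases) == 0) {
    stop("cohort_summary() requires a non-empty case table", call. = FALSE)
  }
  status <- cases$recruitment_status
  correct <- status == "correctly_recruited"
  n_correct <- sum(correct)
  n_prev <- sum(correct & cases$solved == "previously_solved")
  n_new <- sum(correct & cases$solved == "newly_solved")
  out <- list(
    n_recruited = nrow(cases),
    n_excluded = sum(startsWith(status, "excluded")),
    n_no_first_hit_info = sum(status == "no_first_hit_info"),
    n_correctly_recruited = n_correct,
    n_previously_solved = n_prev,
    n_newly_solved = n_new,
    yield_before = diagnostic_yield(n_prev, n_correct),
    yield_after = diagnostic_yield(n_prev + n_new, n_correct))
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat("  recruited:            ", x$n_recruited, "\n")
  cat("  excluded:             ", x$n_excluded, "\n")
  cat("  no first-hit info:    ", x$n_no_first_hit_info, "\n")
  cat("  correctly recruited:  ", x$n_correctly_recruited, "\n")
  cat("  previously solved:    ", x$n_previously_solved, "\n")
  cat("  newly solved:         ", x$n_newly_solved, "\n")
  cat(sprintf("  diagnostic yield:      %.1f%% -> %.1f%%\n",
              x$yield_before, x$yield_after))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cohort_summary <- function(x, ...) {
  tibble::tibble(statistic = names(unclass(x)),
                 value = unlist(unclass(x), use.names = FALSE))
}

#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
tidy.secondhit_screen <- function(x, ...) {
  x$candidates
}

#' @export
glance.secondhit_screen <- function(x, ...) {
  top <- dplyr::filter(x$candidates, .data$rank == 1)
  tibble::tibble(
    n_cases_screened = nrow(x$cases),
    n_cases_with_candidates = dplyr::n_distinct(x$candidates$case_id),
    n_candidates = nrow(x$candidates),
    n_top_trans = sum(top$phase == "TRANS", na.rm = TRUE),
    n_top_hom_in_roh = sum(top$zygosity_path == "HOMOZYGOUS_IN_ROH"))
}

#' Write a screen's outputs to a report directory
#'
#' One per-case candidate TSV plus a JSON cohort summary.
#'
#' @param screen A `secondhit_screen`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(screen, dir) {
  stopifnot(inherits(screen, "secondhit_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(screen$candidates, file.path(dir, "candidates.tsv"))
  jsonlite::write_json(as.list(glance(screen)),
                       file.path(dir, "summary.json"), auto_unbox = TRUE)
  invisible(dir)
}
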