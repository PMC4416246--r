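#' Read a per-patient clinical table
#'
#' Expected CSV columns (exact names): `patient_id`, `prednisone_use`
#' (0/1), `prednisone_dose_mg_day`, `das28_baseline`, `das28_month6`
#' (may be empty); extra columns are carried through untouched.
#'
#' @param path CSV (or TSV) file.
#' @return A validated `data.frame` (class `cohort_table`).
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(patient_id = "character"))
  cohort_table(df)
}

#' Validate a clinical cohort table
#'
#' Checks the invariants a downstream analysis relies on: unique patient
#' ids, dose 0 for prednisone non-users, non-negative doses and DAS28
#' values within the instrument's 0-10 range.
#'
#' @param df data.frame with the columns described in
#'   [read_clinical_table()].
#' @return `df` with class `cohort_table` prepended.
#' @export
cohort_table <- function(df) {
  required <- c("patient_id", "prednisone_use", "prednisone_dose_mg_day",
                "das28_baseline", "das28_month6")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("clinical table missing required column(s): ",
         paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient id(s): ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "))
  df$prednisone_use <- as.logical(as.integer(df$prednisone_use))
  if (anyNA(df$prednisone_use)) stop("prednisone_use must be 0/1")
  if (any(df$prednisone_dose_mg_day < 0, na.rm = TRUE))
    stop("negative prednisone dose")
  bad <- !df$prednisone_use & df$prednisone_dose_mg_day != 0
  if (any(bad, na.rm = TRUE))
    stop("non-zero prednisone dose for non-user(s): ",
         paste(df$patient_id[which(bad)], collapse = ", "))
  das <- c(df$das28_baseline, df$das28_month6)
  if (any(das < 0 | das > 10, na.rm = TRUE))
    stop("DAS28 values must lie in [0, 10]")
  if (!inherits(df, "cohort_table")) class(df) <- c("cohort_table", class(df))
  df
}

#' Derive rituximab response labels from DAS28
#'
#' The response criterion is a strict decrease in disease activity:
#' dDAS28 = baseline - month 6, and a patient is a responder iff
#' dDAS28 > 1.2. Patients with a missing month-6 DAS28 cannot be
#' labeled; they are excluded and listed in the `"excluded"` attribute.
#'
#' @param cohort a `cohort_table`.
#' @return data.frame with `patient_id`, `delta_das28`, `responder`
#'   (logical); attribute `excluded` lists unlabeled patients.
#' @export
classify_response <- function(cohort) {
  cohort <- cohort_table(as.data.frame(cohort))
  labeled <- !is.na(cohort$das28_month6) & !is.na(cohort$das28_baseline)
  out <- data.frame(
    patient_id = cohort$patient_id[labeled],
    delta_das28 = cohort$das28_baseline[labeled] - cohort$das28_month6[labeled],
    stringsAsFactors = FALSE)
  # strict boundary, tolerant of floating-point representation error far
  # below the clinical resolution of DAS28 (two decimals)
  out$responder <- out$delta_das28 - 1.2 > 1e-9
  attr(out, "excluded") <- cohort$patient_id[!labeled]
  out
}

#' Compare IFN-scores between two groups
#'
#' Implements a normality-gated two-group comparison: under
#' `policy = "auto"` an unpaired two-sided Student's t-test is used when
#' both groups pass a Shapiro-Wilk normality check at `alpha_normality`
#' and each has at least 8 observations; otherwise a two-sided
#' Wilcoxon-Mann-Whitney rank-sum test is used (exact enumeration when
#' both groups have at most 10 untied observations, normal approximation
#' with tie correction otherwise).
#'
#' @param scores a `score_table` or named numeric vector.
#' @param groups binary grouping: logical/factor/character vector named
#'   by sample id (or aligned with `scores`).
#' @param policy `"auto"`, `"force_t"` or `"force_rank"`.
#' @param alpha_normality significance level of the normality gate.
#' @return list (class `group_test`) with `test_name` (`"t_unpaired"` or
#'   `"rank_sum"`), `statistic`, `p_value`, and `group_summaries`
#'   (per-group n, mean, median).
#' @export
compare_score_by_group <- function(scores, groups,
                                   policy = c("auto", "force_t", "force_rank"),
                                   alpha_normality = 0.05) {
  policy <- match.arg(policy)
  s <- score_vector(scores)
  if (!is.null(names(groups)) && !is.numeric(groups)) {
    common <- intersect(names(s), names(groups))
    s <- s[common]; groups <- groups[common]
  }
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  a <- s[g == levels(g)[1L]]
  b <- s[g == levels(g)[2L]]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (policy == "auto") {
    normal_ok <- function(v) {
      length(v) >= 8L && stats::sd(v) > 0 &&
        stats::shapiro.test(v)$p.value > alpha_normality
    }
    policy <- if (normal_ok(a) && normal_ok(b)) "force_t" else "force_rank"
  }
  if (policy == "force_t") {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("zero-variance group under t-test")
    ht <- stats::t.test(a, b, var.equal = FALSE)
    test_name <- "t_unpaired"
  } else {
    exact <- length(a) <= 10L && length(b) <= 10L &&
      !anyDuplicated(c(a, b))
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = !exact))
    test_name <- "rank_sum"
  }
  structure(list(
    test_name = test_name,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    group_summaries = data.frame(
      group = levels(g),
      n = c(length(a), length(b)),
      mean = c(mean(a), mean(b)),
      median = c(stats::median(a), stats::median(b)),
      stringsAsFactors = FALSE)),
    class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  print(x$group_summaries, row.names = FALSE)
  invisible(x)
}

#' Default prednisone dose bins (mg/day)
#'
#' Non-users form their own bin; users are split at 5 and 10 mg/day, the
#' last bin collecting doses of 10 mg/day or more, where score
#' suppression is most pronounced.
#'
#' @param dose numeric dose vector (mg/day).
#' @return ordered factor of bin labels.
#' @export
dose_bins <- function(dose) {
  lab <- ifelse(dose == 0, "0 (non-user)",
         ifelse(dose <= 5, "(0,5]",
         ifelse(dose < 10, "(5,10)", ">=10")))
  factor(lab, levels = c("0 (non-user)", "(0,5]", "(5,10)", ">=10"),
         ordered = TRUE)
}

#' Kruskal-Wallis comparison of scores across dose bins
#'
#' Tests whether IFN-score distributions differ across prednisone dose
#' groups using the Kruskal-Wallis rank test (with tie correction).
#'
#' @param scores `score_table` or named numeric vector.
#' @param cohort a `cohort_table` supplying `prednisone_dose_mg_day`.
#' @param bins function mapping doses to bin labels; default [dose_bins()].
#' @return A `group_test` list with `test_name = "kruskal_wallis"`.
#' @export
compare_dose_groups <- function(scores, cohort, bins = dose_bins) {
  s <- score_vector(scores)
  cohort <- cohort_table(as.data.frame(cohort))
  dose <- stats::setNames(cohort$prednisone_dose_mg_day, cohort$patient_id)
  common <- intersect(names(s), names(dose))
  if (!length(common)) stop("no overlap between scored and clinical patients")
  s <- s[common]
  grp <- droplevels(bins(dose[common]))
  if (nlevels(grp) < 2L) stop("need >= 2 non-empty dose bins")
  ht <- stats::kruskal.test(s, grp)
  agg <- do.call(rbind, lapply(levels(grp), function(l) data.frame(
    group = l, n = sum(grp == l), mean = mean(s[grp == l]),
    median = stats::median(s[grp == l]), stringsAsFactors = FALSE)))
  structure(list(test_name = "kruskal_wallis",
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 group_summaries = agg),
            class = "group_test")
}

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio of a 2x2 count table with the Woolf 95%
#' interval (log-OR +/- 1.96 SE). If any cell is zero, the
#' Haldane-Anscombe correction adds 0.5 to every cell first; the result
#' flags when the correction was applied.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param conf_level confidence level, default 0.95.
#' @return list with `or`, `ci_low`, `ci_high`, `corrected` (logical).
#' @export
odds_ratio <- function(tab, conf_level = 0.95) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("2x2 table required")
  if (any(tab < 0)) stop("negative cell count")
  if (any(tab != round(tab))) stop("counts must be integers")
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       corrected = corrected)
}

#' Serialize a group test result to JSON
#' @param x a `group_test`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_test <- function(x, path) {
  jsonlite::write_json(list(
    test_name = x$test_name, statistic = x$statistic, p_value = x$p_value,
    group_summaries = x$group_summaries), path, auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
  invisible(path)
}
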