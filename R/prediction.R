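# Align scores with response labels; positive class = non-responder.
# Returns list(score = named numeric, nonresp = named logical).
align_scores_labels <- function(scores, labels) {
  s <- score_vector(scores)
  if (is.data.frame(labels)) {
    if (!all(c("patient_id", "responder") %in% names(labels)))
      stop("labels need columns patient_id, responder")
    lab <- stats::setNames(!labels$responder, labels$patient_id)
  } else if (is.logical(labels) && !is.null(names(labels))) {
    lab <- !labels  # named logical `responder`
  } else stop("labels must be a classify_response() data.frame or named logical")
  unmatched <- setdiff(names(s), names(lab))
  if (length(unmatched))
    stop("scored samples without response label: ",
         paste(utils::head(unmatched, 10L), collapse = ", "))
  list(score = s, nonresp = lab[names(s)])
}

#' Empirical ROC curve for non-response prediction
#'
#' The state variable is rituximab non-response (dDAS28 <= 1.2) and the
#' decision rule is "predict non-responder when the IFN-score exceeds the
#' threshold". Candidate thresholds are the midpoints between consecutive
#' distinct observed scores, plus one threshold below the minimum (all
#' flagged) and one above the maximum (none flagged). The AUC is computed
#' by the trapezoidal rule over (1 - specificity, sensitivity) and equals
#' the concordance probability that a random non-responder scores higher
#' than a random responder (ties counting one half).
#'
#' @param scores `score_table` or named numeric vector.
#' @param labels output of [classify_response()] (or a named logical
#'   `responder` vector).
#' @return list (class `roc_curve`) with `points` (data.frame threshold,
#'   sensitivity, specificity, ordered by threshold), `auc`, `n_pos`
#'   (non-responders), `n_neg` (responders).
#' @export
roc_curve <- function(scores, labels) {
  al <- align_scores_labels(scores, labels)
  s <- al$score; pos <- al$nonresp
  if (anyNA(s) || anyNA(pos)) stop("missing score or label")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one responder and one non-responder")
  d <- sort(unique(s))
  thr <- c(d[1L] - 1, if (length(d) > 1L) (d[-length(d)] + d[-1L]) / 2,
           d[length(d)] + 1)
  sens <- vapply(thr, function(c) sum(s[pos] > c) / n_pos, numeric(1L))
  spec <- vapply(thr, function(c) sum(s[!pos] <= c) / n_neg, numeric(1L))
  # threshold descending => FPR ascending from 0 to 1
  ord <- order(thr, decreasing = TRUE)
  fpr <- 1 - spec[ord]; tpr <- sens[ord]
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.3f (%d non-responders vs %d responders)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Specificity-constrained cut-off selection
#'
#' Among candidate thresholds whose specificity meets `min_specificity`,
#' returns the one with maximal sensitivity; ties on sensitivity are
#' broken by higher specificity, then by larger threshold (the most
#' conservative call of non-response). With the default
#' `min_specificity = 1` this is the classical "best sensitivity at 100%
#' specificity" operating point: no responder is misclassified. The
#' constraint is always satisfiable because the threshold above the
#' maximum score has specificity 1 (and sensitivity 0).
#'
#' @param roc a [roc_curve()].
#' @param min_specificity minimum specificity demanded, in [0, 1].
#' @return list (class `cutoff_selection`) with `cutoff`, `sensitivity`,
#'   `specificity`, `constraint`.
#' @export
select_cutoff <- function(roc, min_specificity = 1.0) {
  stopifnot(inherits(roc, "roc_curve"),
            min_specificity >= 0, min_specificity <= 1)
  p <- roc$points
  ok <- p$specificity >= min_specificity - 1e-12
  p <- p[ok, , drop = FALSE]
  p <- p[order(-p$sensitivity, -p$specificity, -p$threshold), , drop = FALSE]
  structure(list(cutoff = p$threshold[1L],
                 sensitivity = p$sensitivity[1L],
                 specificity = p$specificity[1L],
                 constraint = min_specificity),
            class = "cutoff_selection")
}

#' Confusion counts at a fixed cut-off
#'
#' Applies the rule "score > cutoff predicts non-responder" (strict by
#' default; a score exactly at the cut-off is called responder) and
#' tabulates the confusion cells with non-responder as the positive
#' class.
#'
#' @param scores `score_table` or named numeric vector.
#' @param cutoff numeric threshold in IFN-score units.
#' @param labels output of [classify_response()] or named logical.
#' @param strict logical; strict `>` at the boundary.
#' @return list with integer `TP`, `FP`, `TN`, `FN` plus `sensitivity`
#'   and `specificity`.
#' @export
apply_cutoff <- function(scores, cutoff, labels, strict = TRUE) {
  al <- align_scores_labels(scores, labels)
  pred <- if (strict) al$score > cutoff else al$score >= cutoff
  pos <- al$nonresp
  out <- list(TP = as.integer(sum(pred & pos)),
              FP = as.integer(sum(pred & !pos)),
              TN = as.integer(sum(!pred & !pos)),
              FN = as.integer(sum(!pred & pos)))
  out$sensitivity <- if (out$TP + out$FN > 0) out$TP / (out$TP + out$FN) else NA_real_
  out$specificity <- if (out$TN + out$FP > 0) out$TN / (out$TN + out$FP) else NA_real_
  out
}

#' Round a proportion to integer percent, half away from zero
#'
#' Matches the reporting convention for sensitivities (e.g. 7/8 -> 88,
#' 9/22 -> 41, 5/8 -> 63).
#'
#' @param p proportion in [0, 1].
#' @return integer percent.
#' @export
percent <- function(p) as.integer(floor(abs(p) * 100 + 0.5) * sign(p))

#' Prednisone-stratified non-response prediction
#'
#' Runs the full per-stratum pipeline — ROC, specificity-constrained
#' cut-off selection, confusion counts — separately within each level of
#' the stratifying variable (prednisone use by default), then aggregates
#' the confusion cells across strata; the unstratified analysis is
#' included for comparison. Strata lacking both a responder and a
#' non-responder are reported as unevaluable and excluded from the
#' aggregate.
#'
#' @param scores `score_table` or named numeric vector.
#' @param cohort a `cohort_table` supplying the stratifying column.
#' @param labels output of [classify_response()].
#' @param stratify_by column of `cohort` to stratify on.
#' @param min_specificity specificity constraint for cut-off selection.
#' @return list (class `stratified_report`) with elements `strata` (per
#'   level: n, n_responders, n_non_responders, roc, cutoff, confusion,
#'   evaluable), `unstratified` (same fields on the pooled data) and
#'   `aggregate` (summed confusion cells, overall sensitivity and
#'   specificity, per-stratum and pooled correct-classification
#'   fractions).
#' @export
stratified_predict <- function(scores, cohort, labels,
                               stratify_by = "prednisone_use",
                               min_specificity = 1.0) {
  cohort <- cohort_table(as.data.frame(cohort))
  if (!stratify_by %in% names(cohort))
    stop("unknown stratification column: ", stratify_by)
  al <- align_scores_labels(scores, labels)
  strat <- stats::setNames(cohort[[stratify_by]], cohort$patient_id)
  unmatched <- setdiff(names(al$score), names(strat))
  if (length(unmatched))
    stop("scored samples absent from clinical table: ",
         paste(utils::head(unmatched, 10L), collapse = ", "))
  strat <- strat[names(al$score)]
  if (stratify_by == "prednisone_use")
    strat <- ifelse(strat, "PREDN+", "PREDN-")

  analyse <- function(ids) {
    s <- al$score[ids]; pos <- al$nonresp[ids]
    block <- list(n = length(ids), n_responders = sum(!pos),
                  n_non_responders = sum(pos))
    if (block$n_responders == 0L || block$n_non_responders == 0L) {
      block$evaluable <- FALSE
      return(block)
    }
    block$evaluable <- TRUE
    block$roc <- roc_curve(s, stats::setNames(!pos, ids))
    block$cutoff <- select_cutoff(block$roc, min_specificity)
    block$confusion <- apply_cutoff(s, block$cutoff$cutoff,
                                    stats::setNames(!pos, ids))
    block
  }

  ids <- names(al$score)
  strata <- lapply(split(ids, strat), analyse)
  unstrat <- analyse(ids)

  evaluable <- Filter(function(b) isTRUE(b$evaluable), strata)
  cells <- c("TP", "FP", "TN", "FN")
  agg <- as.list(stats::setNames(
    vapply(cells, function(cl) sum(vapply(evaluable,
      function(b) b$confusion[[cl]], integer(1L))), integer(1L)),
    cells))
  agg$sensitivity <- if (agg$TP + agg$FN > 0) agg$TP / (agg$TP + agg$FN) else NA_real_
  agg$specificity <- if (agg$TN + agg$FP > 0) agg$TN / (agg$TN + agg$FP) else NA_real_
  agg$correct_fraction_by_stratum <- vapply(evaluable, function(b)
    (b$confusion$TP + b$confusion$TN) / b$n, numeric(1L))
  agg$correct_fraction_pooled <-
    (agg$TP + agg$TN) / sum(vapply(evaluable, function(b) b$n, integer(1L)))

  structure(list(strata = strata, unstratified = unstrat, aggregate = agg,
                 stratify_by = stratify_by,
                 min_specificity = min_specificity),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  fmt <- function(b, name) {
    if (!isTRUE(b$evaluable)) {
      cat(sprintf("  %s: n=%d, unevaluable (single response class)\n",
                  name, b$n))
    } else {
      cat(sprintf(
        "  %s: n=%d, AUC=%.3f, cutoff=%.3g, sens=%d%% (%d/%d), spec=%d%%\n",
        name, b$n, b$roc$auc, b$cutoff$cutoff,
        percent(b$confusion$sensitivity), b$confusion$TP,
        b$confusion$TP + b$confusion$FN, percent(b$confusion$specificity)))
    }
  }
  cat(sprintf("stratified_report (by %s, min specificity %.2f)\n",
              x$stratify_by, x$min_specificity))
  fmt(x$unstratified, "unstratified")
  for (nm in names(x$strata)) fmt(x$strata[[nm]], nm)
  cat(sprintf("  aggregate: sens=%d%% (%d/%d), spec=%d%%\n",
              percent(x$aggregate$sensitivity), x$aggregate$TP,
              x$aggregate$TP + x$aggregate$FN,
              percent(x$aggregate$specificity)))
  invisible(x)
}

#' Serialize a stratified report to JSON
#'
#' @param x a `stratified_report`.
#' @param path output JSON path.
#' @param roc_csv_dir optional directory; when given, each evaluable
#'   block's ROC points are also written as `roc_<name>.csv` for plotting.
#' @return `path`, invisibly.
#' @export
write_stratified_report <- function(x, path, roc_csv_dir = NULL) {
  block_json <- function(b) {
    out <- list(n = b$n, n_responders = b$n_responders,
                n_non_responders = b$n_non_responders,
                evaluable = isTRUE(b$evaluable))
    if (out$evaluable) {
      out$auc <- b$roc$auc
      out$cutoff <- b$cutoff$cutoff
      out$confusion <- b$confusion[c("TP", "FP", "TN", "FN")]
      out$sensitivity <- b$confusion$sensitivity
      out$specificity <- b$confusion$specificity
    }
    out
  }
  payload <- list(stratify_by = x$stratify_by,
                  min_specificity = x$min_specificity,
                  unstratified = block_json(x$unstratified),
                  strata = lapply(x$strata, block_json),
                  aggregate = x$aggregate)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc_csv_dir)) {
    dir.create(roc_csv_dir, showWarnings = FALSE, recursive = TRUE)
    blocks <- c(list(unstratified = x$unstratified), x$strata)
    for (nm in names(blocks)) {
      b <- blocks[[nm]]
      if (isTRUE(b$evaluable))
        utils::write.csv(b$roc$points,
                         file.path(roc_csv_dir,
                                   paste0("roc_", gsub("[^A-Za-z0-9]+", "_", nm),
                                          ".csv")),
                         row.names = FALSE)
    }
  }
  invisible(path)
}
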