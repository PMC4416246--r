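nr <- function(score, nonresp) {
  names(score) <- sprintf("p%02d", seq_along(score))
  list(score = score, resp = setNames(!nonresp, names(score)))
}

test_that("ROC handles separation, overlap and total ties", {
  a <- nr(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_curve(a$score, a$resp)$auc, 1.0)

  b <- nr(c(1, 3, 2), c(TRUE, TRUE, FALSE))
  expect_equal(roc_curve(b$score, b$resp)$auc, 0.5)

  d <- nr(rep(1.5, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_curve(d$score, d$resp)$auc, 0.5)
})

test_that("ROC rejects degenerate or mismatched input", {
  one <- nr(c(1, 2), c(TRUE, TRUE))
  expect_error(roc_curve(one$score, one$resp), "at least one")
  s <- setNames(c(1, 2), c("a", "b"))
  expect_error(roc_curve(s, setNames(c(TRUE, FALSE), c("a", "zzz"))), "b")
})

test_that("cut-off selection maximizes sensitivity under the constraint", {
  a <- nr(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))
  sel <- select_cutoff(roc_curve(a$score, a$resp))
  expect_equal(sel$cutoff, 1.5)
  expect_equal(sel$sensitivity, 1.0)
  expect_equal(sel$specificity, 1.0)

  b <- nr(c(1, 3, 2), c(TRUE, TRUE, FALSE))
  selb <- select_cutoff(roc_curve(b$score, b$resp))
  expect_equal(selb$cutoff, 2.5)
  expect_equal(selb$sensitivity, 0.5)

  # reversed separation: the constraint forces zero sensitivity
  c_ <- nr(c(0, 1, 2, 3), c(TRUE, TRUE, FALSE, FALSE))
  selc <- select_cutoff(roc_curve(c_$score, c_$resp))
  expect_equal(selc$sensitivity, 0.0)
  expect_equal(selc$specificity, 1.0)
})

test_that("apply_cutoff uses a strict boundary with non-responder positive", {
  a <- nr(c(0, 2), c(FALSE, TRUE))
  cc <- apply_cutoff(a$score, 1, a$resp)
  expect_equal(cc[c("TP", "FP", "TN", "FN")],
               list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))

  # a score exactly at the cut-off is called responder
  b <- nr(c(1.5, 2.0), c(TRUE, TRUE))
  cb <- apply_cutoff(b$score, 1.5, b$resp)
  expect_equal(cb$TP, 1L)
  expect_equal(cb$FN, 1L)

  d <- nr(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))
  cd <- apply_cutoff(d$score, 1.5, d$resp)
  expect_equal(cd[c("TP", "FP", "TN", "FN")],
               list(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
})

test_that("trapezoidal AUC equals exhaustive pair concordance", {
  set.seed(101)
  for (i in 1:100) {
    inst <- random_roc_instance()
    r <- roc_curve(inst$score, setNames(!inst$nonresp, names(inst$score)))
    expect_equal(r$auc, oracle_auc(inst$score, inst$nonresp),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(77)
  for (i in 1:25) {
    inst <- random_roc_instance()
    mine <- roc_curve(inst$score, setNames(!inst$nonresp, names(inst$score)))
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = inst$nonresp, predictor = unname(inst$score),
      direction = "<", quiet = TRUE)))
    expect_equal(mine$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("AUC and selected operating point survive monotone transforms", {
  set.seed(55)
  for (i in 1:20) {
    inst <- random_roc_instance()
    resp <- setNames(!inst$nonresp, names(inst$score))
    r1 <- roc_curve(inst$score, resp)
    s1 <- select_cutoff(r1)
    f <- function(x) exp(1.3 * x) - 2
    r2 <- roc_curve(f(inst$score), resp)
    s2 <- select_cutoff(r2)
    expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
    expect_equal(s1$sensitivity, s2$sensitivity)
    expect_equal(s1$specificity, s2$specificity)
  }
})

test_that("stratification on a single stratum matches the pooled analysis", {
  ex <- example_rtx_cohort()
  clin <- ex$clinical
  clin$prednisone_use <- FALSE
  clin$prednisone_dose_mg_day <- 0
  rep1 <- stratified_predict(ex$scores, clin, ex$labels)
  expect_length(rep1$strata, 1L)
  expect_equal(rep1$strata[[1]]$confusion, rep1$unstratified$confusion)
  expect_equal(rep1$aggregate$sensitivity,
               rep1$unstratified$confusion$sensitivity)
})

test_that("per-stratum cut-offs can recover suppressed non-responders", {
  # stratum 1: responder 0, non-responder 1; stratum 2: responder 2, nr 3
  clin <- cohort_table(data.frame(
    patient_id = c("a", "b", "c", "d"),
    prednisone_use = c(1L, 1L, 0L, 0L),
    prednisone_dose_mg_day = c(5, 5, 0, 0),
    das28_baseline = 5.8,
    das28_month6 = c(3.8, 5.3, 3.8, 5.3)))
  scores <- setNames(c(0, 1, 2, 3), clin$patient_id)
  labels <- classify_response(clin)
  rep <- stratified_predict(scores, clin, labels)
  expect_equal(rep$unstratified$confusion$TP, 1L)
  expect_equal(rep$aggregate$TP, 2L)
  expect_equal(rep$aggregate$specificity, 1.0)
})

test_that("single-class strata are unevaluable, not merged", {
  clin <- cohort_table(data.frame(
    patient_id = c("a", "b", "c", "d"),
    prednisone_use = c(1L, 1L, 0L, 0L),
    prednisone_dose_mg_day = c(5, 5, 0, 0),
    das28_baseline = 5.8,
    das28_month6 = c(3.8, 3.8, 3.8, 5.3)))  # both users respond
  scores <- setNames(c(0, 1, 2, 3), clin$patient_id)
  rep <- stratified_predict(scores, clin, classify_response(clin))
  expect_false(rep$strata[["PREDN+"]]$evaluable)
  expect_true(rep$strata[["PREDN-"]]$evaluable)
  # aggregate covers only evaluable strata
  cf <- rep$strata[["PREDN-"]]$confusion
  expect_equal(rep$aggregate$TP, cf$TP)
})

test_that("confusion cells are conserved per stratum and in aggregate", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(8:20, 1)
    clin <- cohort_table(data.frame(
      patient_id = sprintf("q%02d", 1:n),
      prednisone_use = rbinom(n, 1, 0.5),
      prednisone_dose_mg_day = 0,
      das28_baseline = 5.8,
      das28_month6 = sample(c(3.8, 5.3), n, replace = TRUE)))
    clin$prednisone_dose_mg_day[clin$prednisone_use == 1] <- 5
    scores <- setNames(runif(n, 0, 3), clin$patient_id)
    labels <- classify_response(clin)
    if (length(unique(labels$responder)) < 2) next
    rep <- stratified_predict(scores, clin, labels)
    for (b in Filter(function(x) isTRUE(x$evaluable), rep$strata)) {
      expect_equal(b$confusion$TP + b$confusion$FN, b$n_non_responders)
      expect_equal(b$confusion$TN + b$confusion$FP, b$n_responders)
    }
    ev <- Filter(function(x) isTRUE(x$evaluable), rep$strata)
    expect_equal(rep$aggregate$TP + rep$aggregate$FP + rep$aggregate$TN +
                   rep$aggregate$FN,
                 sum(vapply(ev, function(b) b$n, integer(1))))
    # stratified TP never falls below the best single stratum
    expect_gte(rep$aggregate$TP,
               max(vapply(ev, function(b) b$confusion$TP, integer(1))))
  }
})

test_that("stratified reports serialize with unstratified, strata, aggregate", {
  ex <- example_rtx_cohort()
  rep <- stratified_predict(ex$scores, ex$clinical, ex$labels)
  path <- tempfile(fileext = ".json")
  roc_dir <- tempfile()
  write_stratified_report(rep, path, roc_csv_dir = roc_dir)
  j <- jsonlite::read_json(path)
  expect_named(j, c("stratify_by", "min_specificity", "unstratified",
                    "strata", "aggregate"))
  expect_equal(j$unstratified$confusion$TP, 9L)
  expect_true(file.exists(file.path(roc_dir, "roc_PREDN_.csv")))
})

test_that("percent rounds half away from zero", {
  expect_equal(percent(7 / 8), 88L)
  expect_equal(percent(9 / 22), 41L)
  expect_equal(percent(5 / 8), 63L)
  expect_equal(percent(0.5), 50L)
})
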