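#' Configuration for the synthetic RA cohort generator
#'
#' The generator encodes the data structure the IFN-score analysis
#' assumes: a bimodal "genuine" signature (a two-component Gaussian
#' mixture, the signature being present in roughly half of RA patients),
#' dose-dependent suppression of the observed score in prednisone users,
#' and a response probability driven by the latent IFN class rather than
#' the observed score — so suppression creates apparent IFN-low patients
#' who nevertheless fail to respond.
#'
#' Suppression families: `saturating` gives
#' `delta(d) = delta_max * d / (d + d50)` (most pronounced at high doses);
#' `linear` gives `delta(d) = min(delta_max, slope * d)`.
#'
#' @param n number of patients.
#' @param seed integer seed; identical configuration and seed give a
#'   bit-identical cohort.
#' @param p_prednisone probability of current prednisone use (default
#'   0.675, i.e. 27/40 as in a rituximab-starting cohort).
#' @param dose_choices data.frame with columns `dose` (mg/day) and
#'   `prob`; default uniform over 2.5, 5, 7.5, 10, 15, 20 mg/day.
#' @param p_ifn_high prevalence of the latent IFN-high class (default 0.5).
#' @param mu_low,mu_high means of the genuine log2 score in the two
#'   latent classes (`mu_high > mu_low`).
#' @param sigma_score between-patient SD of the genuine score.
#' @param suppression `"saturating"` or `"linear"`.
#' @param delta_max maximal suppression of the score (log2 units).
#' @param d50 dose (mg/day) of half-maximal suppression (saturating).
#' @param slope suppression per mg/day (linear family).
#' @param p_respond_given_high,p_respond_given_low response probabilities
#'   conditional on the latent class.
#' @param genes gene symbols simulated (default the IRG8 panel).
#' @param sigma_gene within-patient, per-gene noise SD (log2 units).
#' @param gene_offsets per-gene additive offsets (default all zero, so
#'   the expected panel mean equals the observed score).
#' @param das28_baseline_mean,das28_baseline_sd baseline DAS28 moments
#'   (default 5.8 and 1.1), truncated to (3.2, 10] as in an active-disease
#'   inclusion criterion.
#' @return list of class `sim_config` with validated fields.
#' @export
simulation_config <- function(n = 200L,
                              seed = 1L,
                              p_prednisone = 0.675,
                              dose_choices = data.frame(
                                dose = c(2.5, 5, 7.5, 10, 15, 20),
                                prob = rep(1 / 6, 6)),
                              p_ifn_high = 0.5,
                              mu_low = 0,
                              mu_high = 1.5,
                              sigma_score = 0.4,
                              suppression = c("saturating", "linear"),
                              delta_max = 1.2,
                              d50 = 5,
                              slope = 0.1,
                              p_respond_given_high = 0.2,
                              p_respond_given_low = 0.8,
                              genes = gene_set("irg8")$genes,
                              sigma_gene = 0.3,
                              gene_offsets = NULL,
                              das28_baseline_mean = 5.8,
                              das28_baseline_sd = 1.1) {
  suppression <- match.arg(suppression)
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              p_prednisone = p_prednisone, dose_choices = dose_choices,
              p_ifn_high = p_ifn_high, mu_low = mu_low, mu_high = mu_high,
              sigma_score = sigma_score, suppression = suppression,
              delta_max = delta_max, d50 = d50, slope = slope,
              p_respond_given_high = p_respond_given_high,
              p_respond_given_low = p_respond_given_low,
              genes = toupper(genes), sigma_gene = sigma_gene,
              gene_offsets = gene_offsets %||% rep(0, length(genes)),
              das28_baseline_mean = das28_baseline_mean,
              das28_baseline_sd = das28_baseline_sd)
  for (f in c("p_prednisone", "p_ifn_high", "p_respond_given_high",
              "p_respond_given_low")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("invalid config field: ", f, " must lie in [0, 1]")
  }
  for (f in c("sigma_score", "sigma_gene", "delta_max")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop("invalid config field: ", f, " must be >= 0")
  }
  if (cfg$n < 1L) stop("invalid config field: n must be >= 1")
  if (!(cfg$mu_high > cfg$mu_low))
    stop("invalid config field: mu_high must exceed mu_low")
  dc <- cfg$dose_choices
  if (!is.data.frame(dc) || !all(c("dose", "prob") %in% names(dc)) ||
      any(dc$dose <= 0) || any(dc$prob < 0) ||
      abs(sum(dc$prob) - 1) > 1e-8)
    stop("invalid config field: dose_choices needs positive doses and probs summing to 1")
  if (length(cfg$gene_offsets) != length(cfg$genes))
    stop("invalid config field: gene_offsets length must match genes")
  if (cfg$d50 <= 0) stop("invalid config field: d50 must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dose-dependent suppression of the IFN-score
#'
#' @param dose dose vector (mg/day).
#' @param cfg a [simulation_config()].
#' @return suppression in log2 units (0 at dose 0).
#' @export
suppression_delta <- function(dose, cfg) {
  switch(cfg$suppression,
         saturating = cfg$delta_max * dose / (dose + cfg$d50),
         linear = pmin(cfg$delta_max, cfg$slope * dose))
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [simulation_config()]; absent keys take
#' their defaults. `dose_choices` may be given as parallel lists `dose`
#' and `prob`.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file (e.g. `seed`).
#' @return A `sim_config`.
#' @export
read_simulation_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key `n` as boolean FALSE; map it back
  names(raw)[names(raw) == "FALSE"] <- "n"
  if (!is.null(raw$dose_choices))
    raw$dose_choices <- data.frame(dose = unlist(raw$dose_choices$dose),
                                   prob = unlist(raw$dose_choices$prob))
  over <- list(...)
  raw[names(over)] <- over
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(simulation_config, raw)
}

#' Simulate a synthetic RA cohort
#'
#' Per patient: a latent IFN class is drawn (Bernoulli `p_ifn_high`); the
#' genuine score is Normal around the class mean; prednisone use and dose
#' are drawn; the expected observed score is the genuine score minus the
#' dose-dependent suppression for users; each panel gene's log2 value is
#' the expected observed score plus its offset plus Gaussian noise;
#' the response label is Bernoulli conditional on the latent class; and a
#' DAS28 baseline/month-6 pair is generated to realize that label under
#' the strict dDAS28 > 1.2 rule (the DAS28 values are cosmetic
#' realizations carrying no information beyond the label).
#'
#' @param cfg a [simulation_config()].
#' @return list of class `sim_cohort` with `expression` (an `ifn_expr`,
#'   platform `"qpcr"`), `clinical` (a `cohort_table`) and `truth`
#'   (data.frame with `patient_id`, `latent_class`, `genuine_score`,
#'   `observed_score_expected`, `dose`, `responder`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  ids <- sprintf("P%04d", seq_len(n))

  high <- stats::runif(n) < cfg$p_ifn_high
  genuine <- stats::rnorm(n, ifelse(high, cfg$mu_high, cfg$mu_low),
                          cfg$sigma_score)
  predn <- stats::runif(n) < cfg$p_prednisone
  dose <- numeric(n)
  if (any(predn)) {
    idx <- sample.int(nrow(cfg$dose_choices), sum(predn), replace = TRUE,
                      prob = cfg$dose_choices$prob)
    dose[predn] <- cfg$dose_choices$dose[idx]
  }
  observed <- genuine - suppression_delta(dose, cfg) * predn

  vals <- matrix(stats::rnorm(length(cfg$genes) * n, sd = cfg$sigma_gene),
                 nrow = length(cfg$genes), ncol = n,
                 dimnames = list(cfg$genes, ids))
  vals <- vals + outer(cfg$gene_offsets, observed, `+`)

  p_resp <- ifelse(high, cfg$p_respond_given_high, cfg$p_respond_given_low)
  responder <- stats::runif(n) < p_resp

  baseline <- stats::rnorm(n, cfg$das28_baseline_mean, cfg$das28_baseline_sd)
  baseline <- pmin(pmax(baseline, 3.2 + 1e-3), 10)
  delta <- ifelse(responder,
                  stats::runif(n, 1.3, 3.2),
                  stats::runif(n, -1.0, 1.2))
  month6 <- pmin(pmax(baseline - delta, 0), 10)

  clinical <- cohort_table(data.frame(
    patient_id = ids,
    prednisone_use = as.integer(predn),
    prednisone_dose_mg_day = dose,
    das28_baseline = baseline,
    das28_month6 = month6,
    stringsAsFactors = FALSE))
  truth <- data.frame(
    patient_id = ids,
    latent_class = ifelse(high, "IFN-high", "IFN-low"),
    genuine_score = genuine,
    observed_score_expected = observed,
    dose = dose,
    responder = responder,
    stringsAsFactors = FALSE)
  structure(list(expression = expression_matrix(vals, platform = "qpcr"),
                 clinical = clinical, truth = truth, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: n=%d (seed %d), %d prednisone users, %d responders\n",
    x$config$n, x$config$seed, sum(x$clinical$prednisone_use),
    sum(x$truth$responder)))
  invisible(x)
}

#' Estimate mean prednisone suppression of the IFN-score
#'
#' Difference of mean scores between prednisone non-users and users,
#' with a pooled-variance standard error. In a cohort simulated with a
#' single fixed dose d, the estimand is the configured suppression
#' delta(d), because the genuine score is independent of prednisone use.
#'
#' @param cohort a `sim_cohort` (or any `cohort_table`).
#' @param scores a `score_table` for the same patients.
#' @return list with `estimate` (log2 units) and `se`.
#' @export
recover_suppression <- function(cohort, scores) {
  clin <- if (inherits(cohort, "sim_cohort")) cohort$clinical else
    cohort_table(as.data.frame(cohort))
  s <- score_vector(scores)
  use <- stats::setNames(clin$prednisone_use, clin$patient_id)[names(s)]
  a <- s[!use]; b <- s[use]  # non-users minus users
  if (length(a) == 0L || length(b) == 0L)
    stop("both prednisone strata must be non-empty")
  est <- mean(a) - mean(b)
  if (length(a) + length(b) > 2L) {
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2L)
    se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  } else se <- NA_real_
  list(estimate = est, se = se)
}

#' Write a simulated cohort as its file trio
#'
#' Writes the expression table (TSV + JSON provenance sidecar), the
#' clinical CSV, and a truth CSV (latent class, genuine score, dose).
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if absent).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             truth = file.path(dir, "truth.csv"))
  write_expression_table(cohort$expression, paths[["expression"]],
                         provenance_path = file.path(dir, "expression_platforms.json"))
  utils::write.csv(as.data.frame(cohort$clinical), paths[["clinical"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$truth[, c("patient_id", "latent_class",
                                    "genuine_score", "dose")],
                   paths[["truth"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
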