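# Independent oracles and fixture builders used across the suite.

# Exhaustive concordance-probability AUC: fraction of (non-responder,
# responder) pairs with the non-responder scoring higher, ties counting 1/2.
oracle_auc <- function(score, nonresp) {
  pos <- score[nonresp]
  neg <- score[!nonresp]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Brute-force specificity-constrained cut-off: enumerate every candidate
# threshold (midpoints of consecutive distinct scores plus sentinels below
# the minimum and above the maximum), count operating points directly, and
# apply the tie-break chain by explicit comparison.
oracle_cutoff <- function(score, nonresp, min_spec = 1.0) {
  d <- sort(unique(score))
  cands <- c(d[1] - 1, if (length(d) > 1) (d[-length(d)] + d[-1]) / 2,
             d[length(d)] + 1)
  best <- NULL
  for (c in cands) {
    sens <- mean(score[nonresp] > c)
    spec <- mean(score[!nonresp] <= c)
    if (spec < min_spec) next
    if (is.null(best) ||
        sens > best$sens ||
        (sens == best$sens && spec > best$spec) ||
        (sens == best$sens && spec == best$spec && c > best$cutoff))
      best <- list(cutoff = c, sens = sens, spec = spec)
  }
  best
}

# Random small ROC instance with ties (scores on a coarse grid) and at
# least one member of each response class.
random_roc_instance <- function(n_max = 12L) {
  repeat {
    n <- sample(2:n_max, 1L)
    score <- sample(seq(0, 3, by = 0.25), n, replace = TRUE)
    nonresp <- runif(n) < 0.5
    if (any(nonresp) && any(!nonresp)) break
  }
  names(score) <- sprintf("s%02d", seq_len(n))
  list(score = score, nonresp = stats::setNames(nonresp, names(score)))
}

# Minimal expression matrix fixture: genes x samples from a named list.
make_expr <- function(values, platform = "microarray", centered = FALSE) {
  expression_matrix(values, platform = platform, centered = centered)
}

# Expression matrix with every IRG8 gene at the given per-sample values.
irg8_matrix <- function(sample_values, genes = gene_set("irg8")$genes) {
  vals <- matrix(rep(sample_values, each = length(genes)),
                 nrow = length(genes),
                 dimnames = list(genes, names(sample_values)))
  expression_matrix(vals, platform = "qpcr")
}

write_temp_table <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
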