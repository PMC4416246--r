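#' Interferon response gene panels
#'
#' The IFN-score is the per-sample mean of log2 expression over a panel of
#' type I interferon response genes (IRGs). Three panels are built in:
#'
#' * `irg8` — EPSTI1, HERC5, IFI44L, ISG15, LY6E, MX1, MX2, RSAD2;
#' * `irg7` — `irg8` without HERC5 (the historical microarray fallback
#'   used when HERC5 was not represented on the array);
#' * `irg3` — EPSTI1, MX1, RSAD2, the compact high-performance panel.
#'
#' @param name `"irg8"`, `"irg7"`, `"irg3"`, or a path to a plain-text
#'   file with one gene symbol per line (a user-defined panel).
#' @return An object of class `gene_set`: list with `name` and `genes`
#'   (uppercase, duplicate-free, order preserved).
#' @export
gene_set <- function(name) {
  irg8 <- c("EPSTI1", "HERC5", "IFI44L", "ISG15", "LY6E", "MX1", "MX2",
            "RSAD2")
  genes <- switch(name,
    irg8 = irg8,
    irg7 = setdiff(irg8, "HERC5"),
    irg3 = c("EPSTI1", "MX1", "RSAD2"),
    {
      if (!file.exists(name))
        stop("unknown gene set and no such file: ", name)
      g <- toupper(trimws(readLines(name)))
      g[nzchar(g)]
    })
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s) in panel: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %s\n", x$name, paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Compute the per-sample IFN-score
#'
#' The score for a sample is the arithmetic mean of the log2 expression
#' values of the panel genes that are present in the matrix and measured
#' for that sample. Samples for which fewer than `min_gene_fraction` of
#' the panel genes are available are excluded from the result and listed
#' in the `"excluded"` attribute. The default 0.75 admits the classical
#' 7-of-8 case where HERC5 is absent from the platform while rejecting
#' panels missing more than a quarter of their genes.
#'
#' @param x an `ifn_expr` on the log2 scale.
#' @param gs a [gene_set()] (or a name/path accepted by it).
#' @param min_gene_fraction minimum fraction of panel genes that must be
#'   measured for a sample to receive a score; in (0, 1].
#' @return A `data.frame` (class `score_table`) with columns `sample_id`,
#'   `ifn_score`, `genes_used`, `genes_missing` (semicolon-joined
#'   symbols); attribute `excluded` holds the dropped sample ids.
#' @export
compute_ifn_score <- function(x, gs = gene_set("irg8"),
                              min_gene_fraction = 0.75) {
  stopifnot(inherits(x, "ifn_expr"))
  if (is.character(gs)) gs <- gene_set(gs)
  stopifnot(inherits(gs, "gene_set"),
            min_gene_fraction > 0, min_gene_fraction <= 1)
  if (ncol(x$values) == 0L || nrow(x$values) == 0L)
    stop("empty expression matrix")
  present <- intersect(gs$genes, genes_of(x))
  if (length(present) == 0L)
    stop("none of the panel genes (", paste(gs$genes, collapse = ", "),
         ") are present in the matrix")
  sub <- x$values[present, , drop = FALSE]
  n_panel <- length(gs$genes)
  measured <- !is.na(sub)
  used <- colSums(measured)
  zeroed <- sub
  zeroed[!measured] <- 0
  score <- ifelse(used > 0, colSums(zeroed) / used, NA_real_)
  absent <- setdiff(gs$genes, present)
  missing_of <- vapply(seq_len(ncol(sub)), function(j)
    paste(c(absent, present[!measured[, j]]), collapse = ";"), character(1L))
  out <- data.frame(sample_id = samples_of(x), ifn_score = unname(score),
                    genes_used = as.integer(used),
                    genes_missing = missing_of, stringsAsFactors = FALSE)
  keep <- out$genes_used / n_panel >= min_gene_fraction
  excluded <- out$sample_id[!keep]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "gene_set") <- gs$name
  class(out) <- c("score_table", "data.frame")
  out
}

#' Dichotomize IFN status at a cut-off
#'
#' Labels each scored sample `IFN-high` when its score exceeds the
#' cut-off and `IFN-low` otherwise. The boundary uses a strict `>` by
#' default, consistent with the prediction module's cut-off rule; set
#' `strict = FALSE` for `>=`.
#'
#' @param scores a `score_table` from [compute_ifn_score()].
#' @param cutoff finite numeric cut-off in IFN-score (log2) units.
#' @param strict logical; strict inequality at the boundary.
#' @return Named character vector (`"IFN-high"`/`"IFN-low"`) keyed by
#'   sample id; empty input gives an empty vector.
#' @export
dichotomize_ifn_status <- function(scores, cutoff, strict = TRUE) {
  stopifnot(is.finite(cutoff))
  s <- score_vector(scores)
  high <- if (strict) s > cutoff else s >= cutoff
  stats::setNames(c("IFN-low", "IFN-high")[high + 1L], names(s) %||% character(0))
}

#' Write a score table to CSV
#'
#' @param scores a `score_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#' @param path CSV path.
#' @return A `score_table` data.frame.
#' @export
read_score_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character"))
  if (!all(c("sample_id", "ifn_score") %in% names(out)))
    stop("score table needs columns sample_id, ifn_score")
  class(out) <- c("score_table", "data.frame")
  out
}

# Named numeric score vector from a score_table or an already-named vector.
score_vector <- function(scores) {
  if (is.numeric(scores)) {
    if (length(scores) && is.null(names(scores)))
      stop("numeric scores must be named by sample id")
    return(scores)
  }
  stats::setNames(scores$ifn_score, scores$sample_id)
}
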