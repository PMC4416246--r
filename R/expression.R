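#' Gene-by-sample expression matrix with platform provenance
#'
#' Container for log2-scale expression values destined for IFN-score
#' computation. Gene symbols are uppercased and unique; sample ids are
#' unique; platform provenance is recorded per sample so matrices from
#' different measurement technologies can be merged after median-centering.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = sample ids), log2 scale, `NA` allowed.
#' @param platform character scalar (`"microarray"` or `"qpcr"`) or a
#'   per-sample character vector named by sample id.
#' @param centered logical; `TRUE` once per-gene medians have been removed.
#' @return An object of class `ifn_expr`: a list with elements `values`,
#'   `platform` (per-sample named character vector) and `centered`.
#' @export
expression_matrix <- function(values, platform, centered = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("`values` must have gene rownames and sample colnames")
  genes <- toupper(genes)
  rownames(values) <- genes
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (length(platform) == 1L) {
    platform <- stats::setNames(rep(platform, length(samples)), samples)
  } else {
    if (is.null(names(platform)) || !setequal(names(platform), samples))
      stop("per-sample `platform` must be named by sample id")
    platform <- platform[samples]
  }
  if (!all(platform %in% c("microarray", "qpcr")))
    stop("platform must be 'microarray' or 'qpcr'")
  structure(list(values = values, platform = platform,
                 centered = isTRUE(centered)),
            class = "ifn_expr")
}

#' @export
print.ifn_expr <- function(x, ...) {
  cat(sprintf("ifn_expr: %d genes x %d samples (%s; %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$platform), collapse = "+"),
              if (x$centered) "median-centered" else "not centered"))
  invisible(x)
}

#' @export
dim.ifn_expr <- function(x) dim(x$values)

genes_of <- function(x) rownames(x$values)
samples_of <- function(x) colnames(x$values)

#' Read a delimited expression table
#'
#' Reads a gene-by-sample table (first column = gene symbol, one header
#' row) and places it on the log2 scale. Microarray intensities may arrive
#' already log2-transformed (`scale = "log2"`) or linear
#' (`scale = "linear"`, log2 applied); qPCR dCt values
#' (`scale = "delta_ct"`) are mapped to relative log2 expression as -dCt,
#' so lower dCt (more transcript) gives a higher value.
#'
#' @param path path to a TSV (default) or CSV file; the delimiter is
#'   inferred from the header line.
#' @param platform `"microarray"` or `"qpcr"`.
#' @param scale one of `"log2"`, `"linear"`, `"delta_ct"`.
#' @param offset optional value added to all cells before log2 when
#'   `scale = "linear"`; by default non-positive values are an error
#'   rather than silently shifted.
#' @return An [expression_matrix()] with `centered = FALSE`. Gene rows
#'   that are entirely missing are dropped with a warning.
#' @export
read_expression_table <- function(path, platform = c("microarray", "qpcr"),
                                  scale = c("log2", "linear", "delta_ct"),
                                  offset = NULL) {
  platform <- match.arg(platform)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression table needs a gene column plus >=1 sample")
  genes <- toupper(trimws(raw[[1L]]))
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s) after uppercasing: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(sample_ids),
                 dimnames = list(genes, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- trimws(raw[[j + 1L]])
    empty <- is.na(cell) | !nzchar(cell) | toupper(cell) %in% c("NA", "NAN")
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !empty)
    if (length(bad))
      stop(sprintf("unparseable cell at row %d, column '%s': '%s'",
                   bad[1L], sample_ids[j], cell[bad[1L]]))
    num[empty] <- NA_real_
    vals[, j] <- num
  }
  vals <- switch(scale,
    log2 = vals,
    linear = {
      v <- if (is.null(offset)) vals else vals + offset
      if (any(v <= 0, na.rm = TRUE)) {
        idx <- which(v <= 0, arr.ind = TRUE)[1L, ]
        stop(sprintf(
          "non-positive linear value at gene %s, sample %s; supply `offset` to shift",
          genes[idx[1L]], sample_ids[idx[2L]]))
      }
      log2(v)
    },
    delta_ct = -vals)
  all_missing <- rowSums(!is.na(vals)) == 0L
  if (any(all_missing)) {
    warning("dropping gene row(s) with no measurements: ",
            paste(genes[all_missing], collapse = ", "))
    vals <- vals[!all_missing, , drop = FALSE]
  }
  expression_matrix(vals, platform = platform, centered = FALSE)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_table()] at `scale = "log2"`; values
#' round-trip to full double precision. A sidecar JSON provenance record
#' (sample id to platform) can be written alongside.
#'
#' @param x an `ifn_expr`.
#' @param path output file; `.csv` extension selects comma, otherwise tab.
#' @param provenance_path optional path for the JSON sample-to-platform map.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, provenance_path = NULL) {
  stopifnot(inherits(x, "ifn_expr"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = genes_of(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(provenance_path))
    jsonlite::write_json(as.list(x$platform), provenance_path,
                         auto_unbox = TRUE)
  invisible(path)
}

#' Median-center each gene row
#'
#' Subtracts each gene's own median (across that platform's samples,
#' ignoring missing values) so that matrices from different platforms
#' become comparable before merging. Even sample counts use the
#' conventional median, the mean of the two middle order statistics.
#' Centering an already-centered matrix is an error to prevent silent
#' double-centering.
#'
#' @param x an uncentered `ifn_expr`.
#' @return The centered `ifn_expr` (`centered = TRUE`); every gene row
#'   with at least one measurement has median 0.
#' @export
median_center <- function(x) {
  stopifnot(inherits(x, "ifn_expr"))
  if (x$centered) stop("matrix is already median-centered")
  all_missing <- rowSums(!is.na(x$values)) == 0L
  if (any(all_missing)) {
    warning("dropping gene row(s) with no measurements: ",
            paste(genes_of(x)[all_missing], collapse = ", "))
    x$values <- x$values[!all_missing, , drop = FALSE]
  }
  med <- apply(x$values, 1L, stats::median, na.rm = TRUE)
  x$values <- x$values - med
  x$centered <- TRUE
  x
}

#' Merge median-centered matrices from several platforms
#'
#' Joins per-platform matrices on the intersection of their gene sets,
#' concatenating sample columns in input order. All inputs must already
#' be centered (per gene, within platform) and their sample id sets must
#' be disjoint; platform provenance is carried per sample.
#'
#' @param matrices list of centered `ifn_expr` objects.
#' @return A single centered `ifn_expr` whose genes are the intersection
#'   of the input gene sets.
#' @export
merge_platforms <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1L), "ifn_expr")))
  if (!all(vapply(matrices, function(m) m$centered, logical(1L))))
    stop("all inputs must be median-centered before merging")
  ids <- unlist(lapply(matrices, samples_of))
  if (anyDuplicated(ids))
    stop("overlapping sample id(s) across platforms: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  common <- Reduce(intersect, lapply(matrices, genes_of))
  if (length(common) == 0L) stop("no genes shared by all platforms")
  vals <- do.call(cbind, lapply(matrices,
                                function(m) m$values[common, , drop = FALSE]))
  platform <- do.call(c, lapply(matrices, function(m) m$platform))
  expression_matrix(vals, platform = platform, centered = TRUE)
}
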