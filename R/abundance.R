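#' Protein (or glycan) abundance matrix container
#'
#' A lightweight container for a features-by-samples matrix of log2
#' abundances or ratios, with optional per-sample batch and dataset labels.
#' Missing values (`NA`) are first-class citizens throughout the pipeline:
#' no operation imputes them unless its contract says so.
#'
#' @param values numeric matrix, features x samples, with unique rownames
#'   (UniProt accessions for proteomes) and unique colnames (sample ids).
#' @param batch optional character/factor vector of per-sample batch labels
#'   (TMT plexes), length `ncol(values)`.
#' @param dataset optional per-sample source-dataset labels, length
#'   `ncol(values)`.
#'
#' @return An object of class `abundance_matrix`: a list with elements
#'   `values`, `batch`, `dataset`.
#' @export
abundance_matrix <- function(values, batch = NULL, dataset = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (feature ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(is.infinite(values)))
    stop("`values` must be finite or NA")
  n <- ncol(values)
  for (nm in c("batch", "dataset")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n)
      stop("`", nm, "` must have one entry per sample (", n, ")")
  }
  structure(
    list(values = values,
         batch = if (is.null(batch)) NULL else as.character(batch),
         dataset = if (is.null(dataset)) NULL else as.character(dataset)),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("abundance_matrix: %d features x %d samples (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  if (!is.null(x$batch))
    cat("  batches: ", paste(names(table(x$batch)), table(x$batch),
                             sep = "=", collapse = ", "), "\n", sep = "")
  if (!is.null(x$dataset))
    cat("  datasets: ", paste(unique(x$dataset), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

# Accept either an abundance_matrix or a bare named matrix; return the matrix.
as_values <- function(m) {
  if (inherits(m, "abundance_matrix")) m$values
  else if (is.matrix(m) && is.numeric(m)) m
  else stop("expected an abundance_matrix or a numeric matrix")
}

# Rebuild an abundance_matrix around new values, keeping labels where the
# sample set is unchanged.
rewrap <- function(m, values) {
  if (inherits(m, "abundance_matrix"))
    abundance_matrix(values, batch = m$batch, dataset = m$dataset)
  else values
}
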