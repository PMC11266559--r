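#' Read / write feature-by-sample matrices as TSV
#'
#' Rows are features (first column `feature_id`), columns samples. Missing
#' values are empty fields.
#'
#' @param m matrix or [abundance_matrix()].
#' @param path file path.
#' @return `read_matrix_tsv` returns a numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  v <- as_values(m)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Read / write SEG-format segment tables
#'
#' Standard SEG columns: `ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean`; mapped to the package's internal `unit`, `chrom`, `start`,
#' `end`, `n_markers`, `seg_mean`.
#'
#' @param segs segment data.frame from [segment_signal()].
#' @param path file path.
#' @export
write_seg <- function(segs, path) {
  out <- data.frame(ID = segs$unit, chrom = segs$chrom,
                    loc.start = segs$start, loc.end = segs$end,
                    num.mark = segs$n_markers, seg.mean = segs$seg_mean,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  data.frame(unit = df[["ID"]], chrom = as.character(df[["chrom"]]),
             start = df[["loc.start"]], end = df[["loc.end"]],
             n_markers = df[["num.mark"]], seg_mean = df[["seg.mean"]],
             stringsAsFactors = FALSE)
}

#' Read / write gene annotation as BED
#'
#' BED is 0-based half-open; internal gene coordinates are 1-based closed.
#' Columns: chrom, start, end, gene, score (unused, 0), strand (unused),
#' with the arm carried in column 7.
#'
#' @param genes gene annotation data.frame (`gene`, `uniprot`, `chrom`,
#'   `start`, `end`, `arm`).
#' @param path file path.
#' @export
write_gene_bed <- function(genes, path) {
  out <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$end, name = genes$gene, score = 0,
                    strand = ".", arm = genes$arm, uniprot = genes$uniprot)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:8] <- c("chrom", "start", "end", "gene", "score", "strand",
                      "arm", "uniprot")
  data.frame(gene = df$gene, uniprot = df$uniprot,
             chrom = as.character(df$chrom), start = df$start + 1L,
             end = df$end, arm = df$arm, stringsAsFactors = FALSE)
}
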