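#' Read and write pipeline file formats
#'
#' Plain-text interchange formats: counts as TSV with a leading feature-id
#' column, metadata as TSV, peak coordinates as 4-column BED (0-based,
#' half-open), gene TSS tables as TSV, and configurations as YAML.
#'
#' @param path file path.
#' @return \code{read_counts} a [count_matrix()]; \code{read_meta} a
#'   validated data.frame; \code{read_bed} a data.frame with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{peak}; \code{read_tss} a
#'   data.frame with columns \code{gene}, \code{chrom}, \code{tss},
#'   \code{strand}.
#' @name epimem_io
NULL

#' @rdname epimem_io
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts file needs a feature column plus samples")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  count_matrix(m)
}

#' @rdname epimem_io
#' @param x object to write.
#' @export
write_counts <- function(x, path) {
  m <- as_count_mat(x)
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname epimem_io
#' @param counts optional counts to cross-check samples against.
#' @export
read_meta <- function(path, counts = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_meta(df, counts)
  df
}

#' @rdname epimem_io
#' @export
write_meta <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname epimem_io
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED file needs chrom, start, end, name columns")
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "peak")
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("malformed BED interval(s): require 0 <= start < end")
  if (anyDuplicated(df$peak))
    stop("duplicated peak ids: ",
         paste(unique(df$peak[duplicated(df$peak)]), collapse = ", "))
  df
}

#' @rdname epimem_io
#' @export
write_bed <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end", "peak")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname epimem_io
#' @export
read_tss <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("TSS table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (anyDuplicated(df$gene))
    stop("duplicated gene ids: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  df[, need]
}

#' @rdname epimem_io
#' @export
write_tss <- function(x, path) {
  utils::write.table(x[, c("gene", "chrom", "tss", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname epimem_io
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(sim_config, lst)
}

#' @rdname epimem_io
#' @export
write_config_yaml <- function(x, path) {
  stopifnot(inherits(x, "sim_config"))
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}
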