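# Tab-separated count tables, truth tables and GMT gene-set collections.
# Count TSV dialect: header row of sample IDs, first column gene IDs,
# integer cells, UTF-8, no quoting; gzip accepted transparently by the
# readers (R connections handle .gz).

#' Write a count matrix as TSV
#'
#' @param x a [count_matrix()].
#' @param path output file; a second file `<path>.groups` is written with
#'   the two-column sample_id / group annotation.
#' @param write_groups also write the group annotation file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, write_groups = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = x$gene_ids, x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (write_groups) {
    ann <- data.frame(sample_id = x$sample_ids, group = as.character(x$group))
    utils::write.table(ann, paste0(path, ".groups"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' Rejects ragged rows, non-integer cells and duplicate gene identifiers
#' with messages naming the offending location.
#'
#' @param path counts TSV (first column gene IDs, header of sample IDs).
#' @param group optional group labels, or a path to a two-column
#'   sample_id / group TSV; defaults to `<path>.groups` when that exists.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, group = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2) stop("counts file needs a gene column plus >= 1 sample")
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifier: ",
         gene_ids[duplicated(gene_ids)][1], " in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    badcol <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric counts in column '", names(df[-1])[badcol],
         "' of ", path)
  }
  if (any(m != round(m) | m < 0, na.rm = TRUE) || anyNA(m)) {
    bad <- which(is.na(m) | m != round(m) | m < 0, arr.ind = TRUE)[1, ]
    stop("non-integer or negative count at row ", bad[1], " (gene ",
         gene_ids[bad[1]], "), column ", bad[2], " of ", path)
  }
  if (is.null(group) && file.exists(paste0(path, ".groups")))
    group <- paste0(path, ".groups")
  if (is.character(group) && length(group) == 1 && file.exists(group)) {
    ann <- utils::read.delim(group, stringsAsFactors = FALSE)
    group <- ann[[2]][match(colnames(m), ann[[1]])]
    if (anyNA(group)) stop("group annotation misses some samples of ", path)
  }
  if (is.null(group))
    stop("no group labels: pass 'group' or provide ", path, ".groups")
  count_matrix(m, group = group, gene_ids = gene_ids)
}

#' Write / read a simulation truth table
#' @param truth a `sim_truth` data.frame from [inject_de()].
#' @param path TSV path.
#' @return `path` (write) or the truth data.frame (read).
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(truth) <- c("sim_truth", "data.frame")
  truth
}

#' Write gene-sets in GMT format
#'
#' One set per line: name, description, then member gene IDs, tab-separated.
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("'sets' must be a named list")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene-sets from GMT format
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop("malformed GMT line ", short[1], " in ", path,
         " (need name, description, >= 1 gene)")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}
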