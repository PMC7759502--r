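#' Read / write a feature table as TSV
#'
#' Feature tables are TSV with feature ids in the first column
#' (`feature_id`) and one column per sample; values round-trip at full
#' precision.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature table needs an id column and >= 1 sample")
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("missing cell at feature '", ids[idx[1]], "', sample '",
         colnames(mat)[idx[2]], "' in ", path)
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

#' @rdname read_feature_table
#' @param mat features x samples matrix.
#' @export
write_feature_table <- function(mat, path) {
  # %.17g round-trips doubles exactly
  chr <- apply(mat, 2, function(v) sprintf("%.17g", v))
  df <- data.frame(feature_id = rownames(mat), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata as TSV
#'
#' Columns `sample_id`, `status` (0/1), `sex` (0/1), `age`. Malformed rows
#' abort with the offending row number.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "status", "sex", "age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !complete.cases(df[need]) | !(df$status %in% c(0, 1)) |
    !(df$sex %in% c(0, 1)) | !is.finite(suppressWarnings(as.numeric(df$age)))
  if (any(bad)) stop("malformed metadata row(s): ",
                     paste(which(bad), collapse = ", "))
  df$age <- as.numeric(df$age)
  df
}

#' @rdname read_metadata
#' @param metadata data frame to write.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write taxonomy as TSV
#'
#' Seven columns: `species_id`, the five ancestor ranks, `genome_length`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_id", "phylum", "class", "order", "family", "genus",
            "genome_length")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("taxonomy missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$genome_length <= 0)) stop("nonpositive genome_length")
  df
}

#' @rdname read_taxonomy
#' @param taxonomy data frame to write.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene-set catalogs in GMT format
#'
#' One set per line: set id, description, then member ids, tab-separated.
#' Lines with fewer than three fields are rejected; duplicate members within
#' a set are removed with a warning.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions kept in the
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  sets <- lapply(parts, function(p) p[-(1:2)])
  dup <- vapply(sets, anyDuplicated, integer(1)) > 0
  if (any(dup)) {
    warning("duplicate member ids deduplicated in set(s): ",
            paste(ids[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  names(sets) <- ids
  attr(sets, "description") <- setNames(desc, ids)
  sets
}

#' @rdname read_gmt
#' @param catalog named list of character vectors.
#' @export
write_gmt <- function(catalog, path) {
  desc <- attr(catalog, "description") %||%
    setNames(names(catalog), names(catalog))
  lines <- vapply(names(catalog), function(id)
    paste(c(id, desc[[id]] %||% id, catalog[[id]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a two-column pathway P-value list as TSV
#'
#' Columns `pathway_id` and `p`.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_pathway_pvals <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "p") %in% names(df)))
    stop("expected columns pathway_id, p")
  setNames(as.numeric(df$p), df$pathway_id)
}

#' @rdname read_pathway_pvals
#' @param pvals named numeric vector.
#' @export
write_pathway_pvals <- function(pvals, path) {
  write.table(data.frame(pathway_id = names(pvals), p = unname(pvals)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
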