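## Readers and writers for the plain-text interchange formats used across
## the analyses: genes x samples count TSVs, MatrixMarket coordinate
## matrices with row/column id sidecars, GMT gene-set collections, result
## TSVs and a provenance sidecar.

#' Read a count matrix
#'
#' TSV (genes x samples, first column = gene id, header row of sample
#' ids) or MatrixMarket coordinate format; for `.mtx` the row and column
#' ids are read from `<path>.rownames` / `<path>.colnames` sidecars (one
#' id per line).
#'
#' @param path file path (`.mtx` triggers MatrixMarket parsing).
#' @return Integer matrix with gene row names and sample column names.
#' @export
readCounts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    dimnames(m) <- list(rn, cn)
    counts <- m
  } else {
    df <- read.delim(path, check.names = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df[[1]]
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in ", path)
  bad <- which(!is.finite(counts) | counts < 0 |
                 counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-integer or negative count at gene '",
         rownames(counts)[bad[1, 1]], "', sample '",
         colnames(counts)[bad[1, 2]], "'")
  storage.mode(counts) <- "integer"
  counts
}

#' Write a count matrix
#'
#' @param counts gene x sample integer matrix.
#' @param path output path; `.mtx` writes MatrixMarket plus
#'   `.rownames`/`.colnames` sidecars, anything else a genes x samples
#'   TSV with a leading `gene_id` column.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(counts, path) {
  counts <- as.matrix(counts)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rownames"))
    writeLines(colnames(counts), paste0(path, ".colnames"))
  } else {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member ids. Duplicate members within a set are deduplicated with
#' a warning; empty sets are retained with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions in attribute
#'   `"description"`.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0)
    stop("GMT parse error at line ", short[1],
         ": fewer than 3 tab-separated fields")
  sets <- lapply(parts, function(p) {
    members <- p[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", p[1], "' deduplicated")
      members <- unique(members)
    }
    if (length(members) == 0)
      warning("empty set '", p[1], "' retained")
    members
  })
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table with a provenance sidecar
#'
#' Writes a TSV (floats at 6 significant digits, stable column order) and
#' a `<stem>.provenance.json` sidecar recording the package version, the
#' seed/parameters supplied and a timestamp.
#'
#' @param table data.frame or DataFrame.
#' @param path output TSV path.
#' @param params named list recorded in the provenance sidecar.
#' @param force overwrite an existing file (default FALSE errors on
#'   collision).
#' @return `path`, invisibly.
#' @export
writeResultsTSV <- function(table, path, params = list(), force = FALSE) {
  if (file.exists(path) && !force)
    stop("output file exists (use force = TRUE): ", path)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(table)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(package = "sdvar",
               version = as.character(packageVersion("sdvar")),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               rows = nrow(df), params = params)
  provPath <- sub("\\.[^.]+$", "", path)
  writeLines(.asJSON(prov), paste0(provPath, ".provenance.json"))
  invisible(path)
}

## minimal JSON serializer for the provenance sidecar (scalars, vectors,
## named lists)
.asJSON <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  if (is.list(x)) {
    if (is.null(names(x)))
      return(paste0("[", paste(vapply(x, .asJSON, ""), collapse = ","),
                    "]"))
    paste0("{", paste(sprintf('"%s":%s', esc(names(x)),
                              vapply(x, .asJSON, "")), collapse = ","),
           "}")
  } else if (length(x) != 1) {
    paste0("[", paste(vapply(x, .asJSON, ""), collapse = ","), "]")
  } else if (is.character(x)) {
    sprintf('"%s"', esc(x))
  } else if (is.logical(x)) {
    if (x) "true" else "false"
  } else {
    format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
}
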