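#' Read a gene expression matrix (GEM)
#'
#' Parses a tab-delimited GEM with genes as rows and samples as columns.
#' The first row is the sample header, the first column holds gene ids.
#' Expression values are expected on a log scale and already normalized;
#' batch correction, low-count filtering and sample outlier removal are
#' upstream concerns and are not performed here.
#'
#' @param path Path to a tab-delimited text file.
#' @param missing_tokens Character vector of cell tokens treated as missing.
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames; missing cells are `NA`.
#' @examples
#' f <- tempfile()
#' writeLines(c("S1\tS2\tS3", "g1\t1\t2\tNA", "g2\t0.5\t1.5\t2.5"), f)
#' gem <- load_gem(f)
#' dim(gem)
#' @export
load_gem <- function(path, missing_tokens = c("NA", "nan", "")) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty GEM file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  # tolerate an optional leading corner label when the header has one more
  # field than the data rows have values
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("GEM file has no data rows: ", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nval <- lengths(fields) - 1L
  sample_ids <- header
  if (length(header) == nval[[1L]] + 1L) sample_ids <- header[-1L]
  n <- length(sample_ids)
  bad <- which(nval != n)
  if (length(bad) > 0L) {
    stop(sprintf("ragged GEM row at line %d: expected %d values, found %d",
                 bad[[1L]] + 1L, n, nval[[bad[[1L]]]]))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id in GEM header: ",
         sample_ids[duplicated(sample_ids)][[1L]])
  }
  gene_ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id in GEM: ", gene_ids[duplicated(gene_ids)][[1L]])
  }
  cells <- unlist(lapply(fields, `[`, -1L), use.names = FALSE)
  cells[cells %in% missing_tokens] <- NA_character_
  vals <- suppressWarnings(as.numeric(cells))
  bad_cell <- which(is.na(vals) & !is.na(cells))
  if (length(bad_cell) > 0L) {
    stop("non-numeric expression value '", cells[bad_cell[[1L]]],
         "' at line ", (bad_cell[[1L]] - 1L) %/% n + 2L)
  }
  gem <- matrix(vals, nrow = length(gene_ids), ncol = n, byrow = TRUE,
                dimnames = list(gene_ids, sample_ids))
  gem
}

#' Write a GEM to a tab-delimited file
#'
#' Inverse of [load_gem()]; missing cells are written as `NA`.
#'
#' @param gem Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gem <- function(gem, path) {
  stopifnot(is.matrix(gem), !is.null(rownames(gem)), !is.null(colnames(gem)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(gem), collapse = "\t"), con)
  body <- apply(gem, 1L, function(v) {
    s <- sprintf("%.17g", v)  # shortest-safe: doubles round trip exactly
    s[is.na(v)] <- "NA"
    paste(s, collapse = "\t")
  })
  writeLines(paste(rownames(gem), body, sep = "\t"), con)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Parses a tab-delimited table with one row per sample (first column =
#' sample id) and one column per experimental variable. Columns declared
#' quantitative are parsed as numerics; all other columns are categorical
#' labels. Rows are reindexed to the GEM's sample order, which is canonical.
#'
#' @param path Path to the annotation file.
#' @param gem GEM matrix the annotations accompany (defines sample order).
#' @param declared_types Named character vector mapping variable names to
#'   `"categorical"` or `"quantitative"`. Undeclared variables default to
#'   categorical.
#' @param missing_tokens Tokens treated as missing in quantitative columns.
#' @return A `data.frame` with rownames = GEM sample ids, character columns
#'   for categorical variables and numeric columns for quantitative ones,
#'   plus a `"variable_types"` attribute naming each column's kind.
#' @export
load_annotations <- function(path, gem, declared_types = character(),
                             missing_tokens = c("NA", "nan", "")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 1L) stop("annotation table has no columns")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in annotations: ", ids[duplicated(ids)][[1L]])
  }
  samples <- colnames(gem)
  missing_samples <- setdiff(samples, ids)
  if (length(missing_samples) > 0L) {
    stop("sample(s) in GEM absent from annotations: ",
         paste(utils::head(missing_samples, 5L), collapse = ", "))
  }
  extra <- setdiff(ids, samples)
  if (length(extra) > 0L) {
    stop("annotation sample id(s) absent from GEM: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  tab <- tab[match(samples, ids), -1L, drop = FALSE]
  rownames(tab) <- samples
  kinds <- vapply(colnames(tab), function(v) {
    k <- unname(declared_types[v])
    if (length(k) != 1L || is.na(k)) "categorical" else k
  }, character(1))
  unknown <- setdiff(kinds, c("categorical", "quantitative"))
  if (length(unknown) > 0L) stop("unknown variable kind: ", unknown[[1L]])
  for (v in colnames(tab)) {
    if (kinds[[v]] == "quantitative") {
      raw <- tab[[v]]
      raw[raw %in% missing_tokens] <- NA_character_
      num <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(num) & !is.na(raw))
      if (length(bad) > 0L) {
        stop("non-numeric value '", raw[bad[[1L]]],
             "' in quantitative variable '", v, "' (sample ",
             rownames(tab)[bad[[1L]]], ")")
      }
      tab[[v]] <- num
    }
  }
  attr(tab, "variable_types") <- kinds
  tab
}

#' Write a sample annotation table
#'
#' @param annotations Annotation `data.frame` as returned by
#'   [load_annotations()] (rownames are sample ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  out <- data.frame(sample = rownames(annotations), annotations,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Variable kinds of an annotation table
#'
#' @param annotations Annotation table.
#' @return Named character vector (`"categorical"` / `"quantitative"`).
#'   Falls back to column classes when the attribute is absent.
#' @export
variable_types <- function(annotations) {
  kinds <- attr(annotations, "variable_types")
  if (is.null(kinds)) {
    kinds <- vapply(annotations, function(col) {
      if (is.numeric(col)) "quantitative" else "categorical"
    }, character(1))
  }
  kinds
}
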