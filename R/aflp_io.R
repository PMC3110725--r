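#' Construct a dominant genotype matrix
#'
#' A `genotype_matrix` holds binary AFLP band calls (1 = band present,
#' 0 = band absent, `NA` = not scored) for N samples at L loci. Samples are
#' rows, loci are columns; row names are sample identifiers and column names
#' are locus identifiers.
#'
#' @param calls integer matrix of 0/1/`NA` calls with unique row and column
#'   names.
#' @return An object of class `genotype_matrix` (an integer matrix).
#' @export
genotype_matrix <- function(calls) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) < 1L || ncol(calls) < 1L)
    stop("genotype matrix must have at least one sample and one locus")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("genotype matrix requires sample (row) and locus (column) names")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    stop("duplicate locus ids: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]), collapse = ", "))
  bad <- !(calls %in% c(0L, 1L, NA_integer_))
  if (any(bad)) {
    idx <- which(bad)[1L]
    rc <- arrayInd(idx, dim(calls))
    stop(sprintf("invalid call '%s' for sample '%s', locus '%s' (calls must be 0, 1 or NA)",
                 calls[idx], rownames(calls)[rc[1L]], colnames(calls)[rc[2L]]))
  }
  structure(calls, class = c("genotype_matrix", class(calls)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d missing calls)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Read a dominant genotype matrix from delimited text
#'
#' The first row is the locus header, the first column holds sample ids and
#' the remaining cells are 0 (band absent), 1 (band present) or `NA`.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", na.strings = "NA",
                          comment.char = "", quote = "")
  if (ncol(df) < 2L) stop("genotype file must have a sample_id column and at least one locus")
  sample_ids <- trimws(df[[1L]])
  locus_ids <- colnames(df)[-1L]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  cells_t <- trimws(cells)
  ok <- is.na(cells_t) | cells_t %in% c("0", "1")
  if (!all(ok)) {
    idx <- which(!ok)[1L]
    rc <- arrayInd(idx, dim(cells_t))
    stop(sprintf("cannot parse cell '%s' at sample '%s', locus '%s': expected 0, 1 or NA",
                 cells[idx], sample_ids[rc[1L]], locus_ids[rc[2L]]))
  }
  calls <- matrix(as.integer(cells_t), nrow = nrow(cells_t),
                  dimnames = list(sample_ids, locus_ids))
  genotype_matrix(calls)
}

#' Write a genotype matrix to delimited text
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a delimited file with columns `sample_id`, `morphotype`,
#' `location`. A (morphotype, location) pair defines a morphotype population;
#' a morphotype alone defines a global morphotype population.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A data.frame with columns `sample_id`, `morphotype`, `location`.
#' @export
read_sample_metadata <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", comment.char = "", quote = "")
  sample_metadata(df)
}

#' Validate sample metadata
#'
#' @param df data.frame with columns `sample_id`, `morphotype`, `location`.
#' @return The validated data.frame (whitespace-trimmed, character columns).
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "morphotype", "location")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  df[] <- lapply(df, function(col) trimws(as.character(col)))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df
}

#' @export
write_sample_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retain only polymorphic loci
#'
#' A locus is polymorphic when its non-missing calls include both 0 and 1,
#' i.e. it is scored differently in at least one individual. Column order is
#' preserved. The operation is idempotent.
#'
#' @param x a [genotype_matrix()].
#' @return A [genotype_matrix()] containing the polymorphic loci. May have
#'   zero columns.
#' @export
filter_polymorphic <- function(x) {
  has0 <- colSums(x == 0L, na.rm = TRUE) > 0L
  has1 <- colSums(x == 1L, na.rm = TRUE) > 0L
  out <- unclass(x)[, has0 & has1, drop = FALSE]
  structure(out, class = c("genotype_matrix", class(out)))
}

#' Tabulate morphotype populations
#'
#' @param meta metadata as returned by [sample_metadata()].
#' @return A data.frame with one row per (morphotype, location) population:
#'   columns `morphotype`, `location`, `population` (label
#'   `"morphotype@location"`) and `n`.
#' @export
morphotype_populations <- function(meta) {
  meta <- sample_metadata(meta)
  tab <- as.data.frame(table(morphotype = meta$morphotype,
                             location = meta$location),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  out <- data.frame(morphotype = tab$morphotype, location = tab$location,
                    population = paste0(tab$morphotype, "@", tab$location),
                    n = tab$Freq, stringsAsFactors = FALSE)
  out <- out[order(out$location, out$morphotype), ]
  rownames(out) <- NULL
  out
}

#' Drop small morphotype populations
#'
#' Populations with fewer than `min_n` individuals are removed. The default
#' (7) excludes populations of six or fewer individuals, which carry too
#' little information for outlier detection.
#'
#' @param populations data.frame from [morphotype_populations()].
#' @param min_n minimum retained sample size (default 7).
#' @return The filtered data.frame.
#' @export
filter_min_population_size <- function(populations, min_n = 7L) {
  stopifnot(min_n >= 1L)
  out <- populations[populations$n >= min_n, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a population pair by sampling design
#'
#' Two morphotype populations form one of three comparison classes:
#' `"sympatric-different"` (same location, different morphotype),
#' `"allopatric-same"` (different location, same morphotype) or
#' `"allopatric-different"` (both differ). Two populations from the same
#' (morphotype, location) cell are not a valid pair.
#'
#' @param pop_a,pop_b lists or one-row data.frames with elements
#'   `morphotype` and `location`.
#' @return One of `"sympatric-different"`, `"allopatric-same"`,
#'   `"allopatric-different"`.
#' @export
classify_pair <- function(pop_a, pop_b) {
  ma <- trimws(pop_a$morphotype); mb <- trimws(pop_b$morphotype)
  la <- trimws(pop_a$location);   lb <- trimws(pop_b$location)
  same_m <- identical(ma, mb); same_l <- identical(la, lb)
  if (same_m && same_l)
    stop("invalid pair: both populations are '", ma, "@", la, "'")
  if (same_l) "sympatric-different"
  else if (same_m) "allopatric-same"
  else "allopatric-different"
}

#' Enumerate population pairs with design classes
#'
#' @param populations data.frame from [morphotype_populations()] (after any
#'   size filtering).
#' @param design_class optional subset of classes to keep.
#' @return data.frame with columns `pop_a`, `pop_b` (population labels),
#'   `morphotype_a`, `morphotype_b`, `location_a`, `location_b`,
#'   `design_class`.
#' @export
population_pairs <- function(populations,
                             design_class = c("sympatric-different",
                                              "allopatric-same",
                                              "allopatric-different")) {
  design_class <- match.arg(design_class, several.ok = TRUE)
  n <- nrow(populations)
  if (n < 2L) return(data.frame())
  idx <- utils::combn(n, 2L)
  rows <- lapply(seq_len(ncol(idx)), function(j) {
    a <- populations[idx[1L, j], ]; b <- populations[idx[2L, j], ]
    data.frame(pop_a = a$population, pop_b = b$population,
               morphotype_a = a$morphotype, morphotype_b = b$morphotype,
               location_a = a$location, location_b = b$location,
               design_class = classify_pair(a, b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$design_class %in% design_class, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subset a genotype matrix to the members of one population
#'
#' @param x a [genotype_matrix()].
#' @param meta sample metadata.
#' @param morphotype,location population labels; `location = NULL` selects
#'   the global morphotype population.
#' @return A [genotype_matrix()] of the selected samples.
#' @export
population_calls <- function(x, meta, morphotype, location = NULL) {
  meta <- sample_metadata(meta)
  keep <- meta$morphotype == morphotype
  if (!is.null(location)) keep <- keep & meta$location == location
  ids <- intersect(meta$sample_id[keep], rownames(x))
  if (!length(ids)) stop("no samples for population ", morphotype,
                         if (!is.null(location)) paste0("@", location))
  out <- unclass(x)[ids, , drop = FALSE]
  structure(out, class = c("genotype_matrix", class(out)))
}
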