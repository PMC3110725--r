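#' Construct a peak-height table
#'
#' Raw AFLP profiles: relative fluorescence units (RFU) per sample per locus.
#'
#' @param heights non-negative numeric matrix, samples x loci, with row
#'   (sample) and column (locus) names.
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(heights) {
  if (!is.matrix(heights)) heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  if (is.null(rownames(heights)) || is.null(colnames(heights)))
    stop("peak table requires sample and locus names")
  if (any(heights < 0, na.rm = TRUE)) stop("peak heights must be >= 0")
  structure(heights, class = c("peak_table", class(heights)))
}

#' Read a peak-height table from TSV
#' @param path file with a `sample_id` column followed by one column per locus.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", quote = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  peak_table(m)
}

#' @export
write_peak_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scoring thresholds for peak-height genotyping
#'
#' @param locus_threshold minimum mean locus height (RFU) for a locus to be
#'   retained as scorable.
#' @param call_threshold phenotype-calling cutoff: RFU in `"absolute"` mode,
#'   or a fraction of the locus mean height in `"relative"` mode.
#' @param call_mode `"relative"` (default) or `"absolute"`.
#' @return An object of class `scoring_thresholds`.
#' @export
scoring_thresholds <- function(locus_threshold, call_threshold,
                               call_mode = c("relative", "absolute")) {
  call_mode <- match.arg(call_mode)
  if (locus_threshold <= 0 || call_threshold <= 0)
    stop("thresholds must be positive")
  if (call_mode == "relative" && call_threshold > 1)
    stop("relative call_threshold must be in (0, 1]")
  structure(list(locus_threshold = locus_threshold,
                 call_threshold = call_threshold,
                 call_mode = call_mode),
            class = "scoring_thresholds")
}

#' Call presence/absence phenotypes from peak heights
#'
#' Loci whose mean height is below `locus_threshold` are dropped as
#' unscorable. For retained loci a band is called present when its height is
#' at least the cutoff: `call_threshold` RFU in absolute mode, or
#' `call_threshold` times the locus mean height in relative mode.
#'
#' @param peaks a [peak_table()].
#' @param thresholds a [scoring_thresholds()].
#' @return A [genotype_matrix()] over the retained loci.
#' @export
call_phenotypes <- function(peaks, thresholds) {
  stopifnot(inherits(thresholds, "scoring_thresholds"))
  mu <- colMeans(peaks, na.rm = TRUE)
  keep <- mu >= thresholds$locus_threshold
  if (!any(keep)) stop("all loci fall below the locus threshold; nothing to score")
  h <- unclass(peaks)[, keep, drop = FALSE]
  cutoff <- if (thresholds$call_mode == "absolute") {
    rep(thresholds$call_threshold, ncol(h))
  } else {
    thresholds$call_threshold * mu[keep]
  }
  calls <- matrix(0L, nrow(h), ncol(h), dimnames = dimnames(h))
  calls[sweep(h, 2L, cutoff, ">=")] <- 1L
  calls[is.na(h)] <- NA_integer_
  genotype_matrix(calls)
}

#' Scoring error rate between replicated extractions
#'
#' The mismatch error rate is the fraction of locus calls that disagree
#' between the two independent extractions of the same individual, pooled
#' over all replicate pairs and loci where both members are scored.
#' Repeatability is `1 - error`.
#'
#' @param x a [genotype_matrix()] containing both members of every pair.
#' @param replicates data.frame (or 2-column matrix) with columns
#'   `sample_id_a`, `sample_id_b`.
#' @return list with `error` (fraction), `repeatability`, `n_compared`,
#'   `n_mismatch`.
#' @export
mismatch_error_rate <- function(x, replicates) {
  replicates <- as.data.frame(replicates, stringsAsFactors = FALSE)
  a <- as.character(replicates[[1L]]); b <- as.character(replicates[[2L]])
  if (any(duplicated(c(a, b))))
    stop("a sample may appear in at most one replicate pair")
  missing_ids <- setdiff(c(a, b), rownames(x))
  if (length(missing_ids))
    stop("replicate sample(s) not in matrix: ", paste(missing_ids, collapse = ", "))
  ca <- unclass(x)[a, , drop = FALSE]
  cb <- unclass(x)[b, , drop = FALSE]
  comp <- !is.na(ca) & !is.na(cb)
  n_comp <- sum(comp)
  if (n_comp == 0L) stop("no comparable calls between replicates")
  n_mis <- sum(ca != cb, na.rm = TRUE)
  list(error = n_mis / n_comp, repeatability = 1 - n_mis / n_comp,
       n_compared = n_comp, n_mismatch = n_mis)
}

#' Optimise scoring thresholds against replicated extractions
#'
#' Evaluates every candidate threshold combination by scoring the peak table
#' and measuring the replicate mismatch error over the retained loci; returns
#' the candidate with the lowest error. Ties are broken conservatively in
#' favour of the higher locus threshold, then the higher call threshold.
#' Candidates that drop every locus are skipped.
#'
#' @param peaks a [peak_table()].
#' @param replicates replicate pairs (see [mismatch_error_rate()]).
#' @param grid data.frame with columns `locus_threshold`, `call_threshold`,
#'   `call_mode`.
#' @return list with `thresholds` (a [scoring_thresholds()]), `error`, and
#'   `grid` (the evaluated grid with an `error` column).
#' @export
optimize_thresholds <- function(peaks, replicates, grid) {
  grid <- as.data.frame(grid, stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) stop("threshold grid is empty")
  need <- c("locus_threshold", "call_threshold", "call_mode")
  if (!all(need %in% colnames(grid)))
    stop("grid needs columns: ", paste(need, collapse = ", "))
  grid$error <- vapply(seq_len(nrow(grid)), function(i) {
    th <- scoring_thresholds(grid$locus_threshold[i], grid$call_threshold[i],
                             grid$call_mode[i])
    calls <- tryCatch(call_phenotypes(peaks, th), error = function(e) NULL)
    if (is.null(calls)) return(NA_real_)
    mismatch_error_rate(calls, replicates)$error
  }, numeric(1L))
  if (all(is.na(grid$error)))
    stop("no threshold combination retained any locus")
  ord <- order(grid$error, -grid$locus_threshold, -grid$call_threshold,
               na.last = TRUE)
  best <- grid[ord[1L], ]
  list(thresholds = scoring_thresholds(best$locus_threshold,
                                       best$call_threshold, best$call_mode),
       error = best$error, grid = grid)
}
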