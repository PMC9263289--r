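# NanoString-style normalization: counts are divided by the geometric mean
# of the housekeeping genes, then log-transformed.

#' Housekeeping geometric-mean normalization
#'
#' Divides each sample's counts by the geometric mean of that sample's
#' housekeeping-gene counts (`method = "per_sample"`, the standard nSolver
#' behaviour). `method = "per_lane"` instead pools the housekeeping counts
#' of all samples in a lane into one geometric mean applied to every sample
#' in that lane.
#'
#' @param x A [count_matrix()].
#' @param method `"per_sample"` (default) or `"per_lane"`.
#' @return Numeric matrix of normalized values (genes x samples) with
#'   attributes `method` and `housekeeping`.
#' @export
normalize_counts <- function(x, method = c("per_sample", "per_lane")) {
  stopifnot(inherits(x, "count_matrix"))
  method <- match.arg(method)
  counts <- x$counts
  hk <- x$housekeeping
  if (length(hk) < 2)
    stop("need at least 2 housekeeping genes to normalize", call. = FALSE)
  hk_counts <- counts[hk, , drop = FALSE]
  zero <- which(hk_counts <= 0, arr.ind = TRUE)
  if (nrow(zero)) {
    s <- colnames(counts)[zero[1, "col"]]
    stop(sprintf(
      "housekeeping gene '%s' has a non-positive count in sample '%s' (lane %s)",
      hk[zero[1, "row"]], s, x$lane[s]), call. = FALSE)
  }
  gm <- switch(method,
    per_sample = exp(colMeans(log(hk_counts))),
    per_lane = {
      lane_gm <- tapply(seq_along(x$lane), x$lane,
                        function(i) exp(mean(log(hk_counts[, i, drop = FALSE]))))
      as.numeric(lane_gm[x$lane])
    })
  out <- sweep(counts, 2, gm, `/`)
  attr(out, "method") <- method
  attr(out, "housekeeping") <- hk
  out
}

#' Log-transform a normalized expression matrix
#'
#' @param x Numeric matrix of normalized values.
#' @param pseudocount Non-negative offset added before taking logs. The
#'   default of 0 makes zeros a hard error, forcing an explicit choice.
#' @param base `"e"` (natural log, default) or `"2"`. Downstream Pearson
#'   correlations are invariant to this choice; coefficients rescale by
#'   `1/ln 2`.
#' @return A `log_expr` matrix with attributes `base` and `pseudocount`.
#' @export
log_transform <- function(x, pseudocount = 0, base = c("e", "2")) {
  base <- match.arg(as.character(base), c("e", "2"))
  if (pseudocount < 0) stop_bad_arg("pseudocount", "must be >= 0")
  if (any(x + pseudocount <= 0))
    stop("non-positive values after adding the pseudocount; ",
         "increase `pseudocount` or filter the matrix", call. = FALSE)
  out <- if (base == "e") log(x + pseudocount) else log2(x + pseudocount)
  attr(out, "method") <- NULL
  attr(out, "housekeeping") <- NULL
  structure(out, base = base, pseudocount = pseudocount,
            class = c("log_expr", class(out)))
}
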