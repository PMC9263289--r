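# SUVR analysis of volume-of-interest uptake tables: bilateral averaging,
# cerebellum-referenced ratios, PCA-based region selection, per-region
# factor ANOVA. Format, not modality, drives behaviour: PET VOI and
# autoradiography ROI tables use identical code paths.

#' Average bilateral regions
#'
#' Merges left/right records of each region into one arithmetic mean per
#' subject; records already marked `"merged"` pass through unchanged.
#'
#' @param voi Long uptake table: `subject`, factor columns, `region`,
#'   `side` (`"L"`/`"R"`/`"merged"`), `uptake`.
#' @return The same table with one `"merged"` record per subject x region.
#' @export
average_bilateral <- function(voi) {
  merged <- voi[voi$side == "merged", , drop = FALSE]
  paired <- voi[voi$side != "merged", , drop = FALSE]
  if (nrow(paired)) {
    key <- interaction(paired$subject, paired$region, drop = TRUE)
    n_sides <- tapply(paired$side, key, function(s) length(unique(s)))
    if (any(n_sides != 2)) {
      bad <- names(n_sides)[n_sides != 2][1]
      stop(sprintf("missing side for subject x region '%s'", bad),
           call. = FALSE)
    }
    keep <- !duplicated(key)
    avg <- paired[keep, , drop = FALSE]
    avg$uptake <- as.numeric(tapply(paired$uptake, key, mean)[
      as.character(key[keep])])
    avg$side <- "merged"
    merged <- rbind(merged, avg)
  }
  rownames(merged) <- NULL
  merged[order(merged$subject, merged$region), ]
}

#' Compute standardized uptake value ratios
#'
#' Divides each region's merged uptake by the same subject's reference
#' (cerebellum) uptake, removing injected-dose and global-scale effects.
#' The reference region's own SUVR is exactly 1.
#'
#' @param voi Merged uptake table from [average_bilateral()].
#' @param reference Reference region name (default `"cerebellum"`).
#' @return Data frame: `subject`, factor columns, `region`, `suvr`, with
#'   the reference name in the `"reference"` attribute.
#' @export
compute_suvr <- function(voi, reference = "cerebellum") {
  if (any(voi$side != "merged"))
    stop("`voi` must be bilateral-averaged first (see average_bilateral)",
         call. = FALSE)
  ref <- voi[voi$region == reference, ]
  if (!nrow(ref))
    stop(sprintf("reference region '%s' not found", reference), call. = FALSE)
  ref_val <- stats::setNames(ref$uptake, ref$subject)
  missing_ref <- setdiff(unique(voi$subject), names(ref_val))
  if (length(missing_ref))
    stop("subject(s) lacking a reference value: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  if (any(ref_val <= 0))
    stop("non-positive reference uptake for subject(s): ",
         paste(names(ref_val)[ref_val <= 0], collapse = ", "), call. = FALSE)
  out <- voi
  out$suvr <- voi$uptake / ref_val[voi$subject]
  out$uptake <- NULL
  out$side <- NULL
  rownames(out) <- NULL
  structure(out, reference = reference)
}

#' Select regions explaining the top share of SUVR variance
#'
#' PCA of the subject x region SUVR matrix (centered, unscaled by default).
#' Each region's contribution is its eigenvalue-weighted squared loading
#' summed over all components, normalized to 1 (for centered, unscaled PCA
#' this equals the region's share of total variance). Regions are added in
#' decreasing contribution until the cumulative share reaches `threshold`
#' (inclusive). `mode = "components"` restricts the contribution sum to the
#' leading components whose cumulative eigenvalue fraction reaches the
#' threshold.
#'
#' @param suvr SUVR table from [compute_suvr()].
#' @param threshold Cumulative variance share in (0, 1].
#' @param mode `"contribution"` (default) or `"components"`.
#' @param scale. Unit-scale regions before PCA (default FALSE).
#' @return List with `selection` (data frame `region`, `contribution`,
#'   `cumulative`, `selected`), `regions` (selected names in order) and
#'   `pca` (variance fractions and loadings).
#' @export
select_regions_by_variance <- function(suvr, threshold = 0.80,
                                       mode = c("contribution", "components"),
                                       scale. = FALSE) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1)
    stop_bad_arg("threshold", "must be in (0, 1]")
  wide <- stats::xtabs(suvr ~ subject + region, data = suvr)
  counts <- stats::xtabs(~ subject + region, data = suvr)
  if (any(counts > 1))
    stop("duplicate subject x region records", call. = FALSE)
  complete <- rowSums(counts) == ncol(counts)
  if (any(!complete))
    warning(sprintf("dropping %d subject(s) with missing regions",
                    sum(!complete)), call. = FALSE)
  m <- as.matrix(wide[complete, , drop = FALSE])
  if (nrow(m) < 2) stop("need at least 2 complete subjects", call. = FALSE)
  keep <- apply(m, 2, stats::sd) > 0
  dropped_const <- colnames(m)[!keep]
  pc <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  lambda <- pc$sdev^2
  contrib_comp <- sweep(pc$rotation^2, 2, lambda, `*`)   # region x comp

  if (mode == "components") {
    k <- which(cumsum(lambda) / sum(lambda) >= threshold)[1]
    contrib <- rowSums(contrib_comp[, seq_len(k), drop = FALSE])
  } else {
    contrib <- rowSums(contrib_comp)
  }
  contrib <- contrib / sum(contrib)
  # constant regions (e.g. the reference itself) contribute zero variance
  if (length(dropped_const))
    contrib <- c(contrib, stats::setNames(rep(0, length(dropped_const)),
                                          dropped_const))
  ord <- order(-contrib, names(contrib))
  contrib <- contrib[ord]
  cum <- cumsum(contrib)
  n_sel <- which(cum >= threshold - 1e-12)[1]
  selected <- seq_along(contrib) <= n_sel
  sel <- data.frame(region = names(contrib), contribution = unname(contrib),
                    cumulative = unname(cum), selected = selected,
                    stringsAsFactors = FALSE)
  rownames(sel) <- NULL
  list(selection = sel, regions = sel$region[sel$selected],
       pca = list(var_frac = lambda / sum(lambda), loadings = pc$rotation))
}

#' Per-region two-way ANOVA of SUVRs
#'
#' Runs [anova_two_way()] on each selected region with the two requested
#' subject factors, flagging regions with any factor p < alpha. No
#' across-region multiple-testing correction is applied by default.
#'
#' @param suvr SUVR table from [compute_suvr()].
#' @param regions Regions to test (e.g. from
#'   [select_regions_by_variance()]).
#' @param factors Length-2 character vector of factor column names.
#' @param alpha Significance level (default 0.05).
#' @param adjust Apply Benjamini-Hochberg across regions per term
#'   (default FALSE, matching the per-region convention).
#' @return Data frame: `region`, `term`, `df`, `sumsq`, `F`, `p`,
#'   (`padj` if `adjust`), `significant`.
#' @export
region_anova <- function(suvr, regions, factors = c("diet", "genotype"),
                         alpha = 0.05, adjust = FALSE) {
  if (length(factors) != 2)
    stop_bad_arg("factors", "must name exactly two factor columns")
  miss <- setdiff(factors, names(suvr))
  if (length(miss))
    stop("factor column(s) not in SUVR table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  rows <- lapply(regions, function(rg) {
    d <- suvr[suvr$region == rg, ]
    tab <- anova_two_way(d$suvr, d[[factors[1]]], d[[factors[2]]],
                         names = factors)
    tab$region <- rg
    tab
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    out$padj <- NA_real_
    for (tm in unique(out$term)) {
      i <- out$term == tm & !is.na(out$p)
      out$padj[i] <- stats::p.adjust(out$p[i], method = "BH")
    }
    out$significant <- !is.na(out$padj) & out$padj < alpha
  } else {
    out$significant <- !is.na(out$p) & out$p < alpha
  }
  rownames(out) <- NULL
  out[, c("region", setdiff(names(out), "region"))]
}
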