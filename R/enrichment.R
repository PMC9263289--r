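# Preranked gene-set enrichment (weighted Kolmogorov-Smirnov running sum
# with a gene-label permutation null), hypergeometric over-representation,
# and PCA of normalized enrichment scores.

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member genes.
#' Symbols are upper-cased at load.
#'
#' @param file Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           f[1], call. = FALSE)
    toupper(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param file Output path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, file, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, file)
  invisible(file)
}

# weighted-KS enrichment score for hit positions `idx` (sorted ascending)
# in a ranking of length N with per-position weights absw = |score|^p.
# The running sum is evaluated only at its candidate extrema: just after
# each hit (maxima) and just before each hit (minima).
.gsea_es <- function(idx, absw, N) {
  n <- length(idx)
  w <- absw[idx]
  W <- sum(w)
  if (W == 0) { w <- rep(1, n); W <- n }   # all-zero scores: unweighted KS
  cumw <- cumsum(w)
  dec <- (idx - seq_len(n)) / (N - n)
  r_after <- cumw / W - dec
  r_before <- (cumw - w) / W - dec
  i_max <- which.max(r_after)
  i_min <- which.min(r_before)
  if (r_after[i_max] >= -r_before[i_min])
    list(es = r_after[i_max], at = i_max, positive = TRUE)
  else
    list(es = r_before[i_min], at = i_min, positive = FALSE)
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic: hits increment the
#' sum proportionally to `|score|^weight`, misses decrement it by
#' `1/(N - n_set)`; the enrichment score (ES) is the extremum of the
#' running sum. The null distribution comes from random gene-label
#' assignments of each set; NES is the ES divided by the mean |null ES| of
#' matching sign, and the nominal p-value is one-sided within the sign
#' class. Benjamini-Hochberg FDR is applied across sets. Ties in scores are
#' broken deterministically by gene symbol.
#'
#' @param ranking Named numeric vector, gene -> ranking score (e.g. a
#'   model coefficient). Names are upper-cased; duplicates are an error.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param weight Exponent on |score| for hit increments (1 = classic GSEA).
#' @param n_perm Number of gene-label permutations (>= 100).
#' @param seed Optional RNG seed.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   ranking; out-of-bounds sets are dropped with a warning.
#' @return An `enrichment_table` data frame: `set`, `size`, `es`, `nes`,
#'   `p`, `padj`, `leading_edge` (comma-separated).
#' @export
gsea_preranked <- function(ranking, sets, weight = 1, n_perm = 10000,
                           seed = NULL, min_size = 5, max_size = 500) {
  if (!length(sets)) stop("empty gene-set collection", call. = FALSE)
  if (n_perm < 100) stop_bad_arg("n_perm", "must be >= 100")
  names(ranking) <- toupper(names(ranking))
  if (anyDuplicated(names(ranking)))
    stop("duplicate genes in ranking after upper-casing", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  # decreasing score, ties broken by symbol for exact reproducibility
  ord <- order(-ranking, names(ranking))
  scores <- ranking[ord]
  genes <- names(scores)
  N <- length(scores)
  absw <- abs(scores)^weight

  dropped <- character()
  rows <- list()
  for (nm in names(sets)) {
    idx <- sort(match(unique(toupper(sets[[nm]])), genes))
    idx <- idx[!is.na(idx)]
    n <- length(idx)
    if (n < 2 && min_size >= 2) {
      dropped <- c(dropped, nm)
      warning(sprintf("set '%s' has <2 members in the ranking; dropped", nm),
              call. = FALSE)
      next
    }
    if (n < max(1, min_size) || n > min(max_size, N - 1)) {
      dropped <- c(dropped, nm)
      next
    }
    obs <- .gsea_es(idx, absw, N)
    null_es <- vapply(seq_len(n_perm), function(b) {
      .gsea_es(sort.int(sample.int(N, n)), absw, N)$es
    }, 0)

    if (obs$es >= 0) {
      same <- null_es[null_es >= 0]
      nes <- if (length(same) && mean(same) > 0) obs$es / mean(same) else NA_real_
      p <- (1 + sum(same >= obs$es)) / (1 + length(same))
      le <- genes[idx[seq_len(obs$at)]]
    } else {
      same <- null_es[null_es < 0]
      nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
      p <- (1 + sum(same <= obs$es)) / (1 + length(same))
      le <- genes[idx[seq(obs$at, n)]]
    }
    rows[[nm]] <- data.frame(set = nm, size = n, es = obs$es, nes = nes,
                             p = p, leading_edge = paste(le, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no gene set passed the size bounds", call. = FALSE)
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("set", "size", "es", "nes", "p", "padj", "leading_edge")]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"),
            n_perm = n_perm, weight = weight, dropped = dropped)
}

#' Over-representation analysis (hypergeometric test)
#'
#' Upper-tail hypergeometric p-value for the overlap between a hit list and
#' each gene set (both restricted to the universe), with Benjamini-Hochberg
#' correction across sets.
#'
#' @param hits Character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param universe Character vector, the gene universe (e.g. the panel).
#' @param sets Named list of gene sets.
#' @return Data frame: `set`, `set_size`, `overlap`, `p`, `padj`, `genes`.
#' @export
ora <- function(hits, universe, sets) {
  hits <- unique(toupper(hits))
  universe <- unique(toupper(universe))
  outside <- setdiff(hits, universe)
  if (length(outside))
    stop("hit gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  U <- length(universe); m <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(toupper(sets[[nm]]), universe)
    k <- length(set_u)
    ov <- intersect(hits, set_u)
    x <- length(ov)
    p <- stats::phyper(x - 1, k, U - k, m, lower.tail = FALSE)
    data.frame(set = nm, set_size = k, overlap = x, p = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out[, c("set", "set_size", "overlap", "p", "padj", "genes")]
}

#' PCA of normalized enrichment scores
#'
#' Centered (optionally unit-scaled) principal component analysis of a
#' factors x sets NES matrix, summarising how the model terms separate in
#' pathway-enrichment space.
#'
#' @param nes Numeric matrix, factors (rows) x gene sets (columns).
#' @param scale. Unit-scale columns (default FALSE: NES are already
#'   comparable across sets).
#' @param na_action `"error"` (default) or `"drop"` columns containing
#'   missing values.
#' @return List with `var_frac` (named variance fractions, summing to 1),
#'   `scores` (factor coordinates), `loadings` (set loadings), `sdev`.
#' @export
nes_pca <- function(nes, scale. = FALSE, na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  if (nrow(nes) < 2 || ncol(nes) < 2)
    stop("need at least 2 factors and 2 sets", call. = FALSE)
  if (anyNA(nes)) {
    if (na_action == "error")
      stop("NES matrix has missing cells; drop or impute them first",
           call. = FALSE)
    keep <- colSums(is.na(nes)) == 0
    warning(sprintf("dropping %d set(s) with missing NES", sum(!keep)),
            call. = FALSE)
    nes <- nes[, keep, drop = FALSE]
  }
  if (scale.) {
    const <- apply(nes, 2, stats::sd) == 0
    if (any(const)) {
      warning(sprintf("dropping %d constant column(s) before scaling",
                      sum(const)), call. = FALSE)
      nes <- nes[, !const, drop = FALSE]
    }
  }
  pc <- stats::prcomp(nes, center = TRUE, scale. = scale.)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(var_frac = stats::setNames(vf, colnames(pc$x)),
       scores = pc$x, loadings = pc$rotation, sdev = pc$sdev)
}
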