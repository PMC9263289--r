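# Cross-species alignment: Pearson correlation of mouse per-term effect
# vectors against human module / subtype log2 fold-change references, and
# extraction of directionally coherent genes.

#' Correlate mouse effects with human reference sets
#'
#' For every model term and every reference set (co-expression module or
#' disease subtype), computes the Pearson correlation between the term's
#' per-gene coefficients and the reference's per-gene log2 fold changes over
#' the overlapping genes, with the p-value from `stats::cor.test` (Student-t
#' approximation, n - 2 df). Cells with fewer than `min_overlap` overlapping
#' genes are reported as missing rather than computed.
#'
#' @param effects An `effect_table` from [fit_effects()].
#' @param reference Data frame with columns `module`, `cluster`, `region`,
#'   `gene`, `log2fc` (subtype references use the same layout, with the
#'   subtype label in `module`).
#' @param terms Model terms to correlate (default: every non-intercept
#'   term in `effects`).
#' @param min_overlap Minimum overlapping genes per cell (>= 3).
#' @param alpha Per-cell significance level (uncorrected, matching the
#'   convention of circling cells with p < 0.05).
#' @param gene_map Optional data frame (`mouse`, `human`) overriding the
#'   default uppercase symbol mapping.
#' @return A `correlation_grid`: long data frame with columns `term`,
#'   `reference`, `cluster`, `region`, `r`, `p`, `n`, `significant`.
#' @export
correlate_effects <- function(effects, reference, terms = NULL,
                              min_overlap = 5, alpha = 0.05,
                              gene_map = NULL) {
  if (!nrow(reference)) stop("empty reference table", call. = FALSE)
  if (min_overlap < 3) stop_bad_arg("min_overlap", "must be >= 3")
  all_terms <- unique(effects$term)
  if (is.null(terms)) terms <- setdiff(all_terms, "(Intercept)")
  missing_terms <- setdiff(terms, all_terms)
  if (length(missing_terms))
    stop("term(s) absent from effect table: ",
         paste(missing_terms, collapse = ", "), call. = FALSE)

  dup <- duplicated(reference[, c("module", "gene")])
  if (any(dup))
    stop("duplicate gene within module: ",
         paste(unique(reference$module[dup]), collapse = ", "), call. = FALSE)

  genes <- unique(effects$gene)
  hum <- human_symbols(genes, gene_map)
  mods <- unique(reference$module)

  rows <- list()
  for (term in terms) {
    beta <- stats::setNames(effect_vector(effects, term), hum)
    for (mod in mods) {
      ref <- reference[reference$module == mod, ]
      idx <- match(ref$gene, names(beta))
      keep <- !is.na(idx)
      n <- sum(keep)
      if (n >= min_overlap) {
        ct <- stats::cor.test(ref$log2fc[keep], beta[idx[keep]],
                              method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      } else {
        r <- NA_real_; p <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        term = term, reference = mod, cluster = ref$cluster[1],
        region = ref$region[1], r = r, p = p, n = n,
        significant = !is.na(p) && p < alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("correlation_grid", "data.frame"),
            alpha = alpha, min_overlap = min_overlap)
}

#' Reshape a correlation grid to matrix form
#'
#' @param grid A `correlation_grid` from [correlate_effects()].
#' @param value Cell value to extract (`"r"`, `"p"` or `"n"`).
#' @return Matrix with terms as rows and reference sets as columns.
#' @export
grid_matrix <- function(grid, value = "r") {
  terms <- unique(grid$term); mods <- unique(grid$reference)
  m <- matrix(NA_real_, length(terms), length(mods),
              dimnames = list(terms, mods))
  m[cbind(match(grid$term, terms), match(grid$reference, mods))] <-
    grid[[value]]
  m
}

#' Extract directionally coherent genes for a consensus cluster
#'
#' A panel gene is directionally coherent with a human module when the sign
#' of its mouse coefficient for `term` agrees with the sign of its human
#' log2 fold change in that module. Returns the union over all modules in
#' the requested cluster, keeping per-module provenance; the unique gene
#' list is in the `"genes"` attribute.
#'
#' @param effects An `effect_table`.
#' @param reference Module reference table (see [correlate_effects()]).
#' @param term Model term whose coefficient signs are compared.
#' @param cluster Consensus-cluster label to restrict to.
#' @param p_max Optional per-gene p-value filter on the mouse coefficient
#'   (no filter by default: the criterion is sign agreement only).
#' @param gene_map Optional mouse-to-human symbol map.
#' @return Data frame `gene`, `human`, `module`, `beta`, `log2fc` with a
#'   `"genes"` attribute (unique mouse symbols).
#' @export
extract_coherent_genes <- function(effects, reference, term, cluster,
                                   p_max = NULL, gene_map = NULL) {
  if (!cluster %in% reference$cluster)
    stop(sprintf("unknown cluster '%s' (reference has: %s)", cluster,
                 paste(unique(reference$cluster), collapse = ", ")),
         call. = FALSE)
  sub <- effects[effects$term == term, ]
  if (!nrow(sub))
    stop(sprintf("term '%s' not present in effect table", term),
         call. = FALSE)
  if (!is.null(p_max)) sub <- sub[sub$p <= p_max, ]
  hum <- human_symbols(sub$gene, gene_map)

  ref <- reference[reference$cluster == cluster, ]
  idx <- match(ref$gene, hum)
  keep <- !is.na(idx)
  ref <- ref[keep, ]; idx <- idx[keep]
  beta <- sub$beta[idx]
  coh <- sign(beta) == sign(ref$log2fc) & beta != 0 & ref$log2fc != 0
  out <- data.frame(gene = sub$gene[idx][coh], human = ref$gene[coh],
                    module = ref$module[coh], beta = beta[coh],
                    log2fc = ref$log2fc[coh], stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  structure(out, genes = unique(out$gene))
}
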