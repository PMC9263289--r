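# Per-gene factorial linear model: treatment-coded design with
# diet-by-variant interactions, ordinary least squares per gene.

#' Model term labels
#'
#' The seven columns of the factorial design matrix, in order: intercept,
#' sex indicator, diet indicator, the two variant indicators, and the two
#' diet-by-variant interactions. These labels are used consistently in
#' effect tables, correlation grids and rankings.
#'
#' @param ref_sex,ref_diet Reference levels used when labelling the sex and
#'   diet indicator columns.
#' @return Character vector of length 7.
#' @export
model_terms <- function(ref_sex = "F", ref_diet = "CD") {
  sex_lab <- if (ref_sex == "F") "Sex(Male)" else "Sex(Female)"
  diet_lab <- if (ref_diet == "CD") "HFD" else "CD"
  c("(Intercept)", sex_lab, diet_lab, "Mthfr.C677T", "Plcg2.M28L",
    paste0(diet_lab, "*Mthfr.C677T"), paste0(diet_lab, "*Plcg2.M28L"))
}

#' Build the factorial design matrix
#'
#' Treatment (dummy) coding of the 2 (sex) x 2 (diet) x 3 (genotype) study
#' design. The baseline genotype (carrying both core risk alleles) is always
#' the genotype reference; interaction columns are elementwise products of
#' the diet column with each variant column.
#'
#' @param samples Data frame with columns `sample`, `sex` (`"F"`/`"M"`),
#'   `diet` (`"CD"`/`"HFD"`), `genotype` (`"LOAD1"`, `"LOAD1.Mthfr"`,
#'   `"LOAD1.Plcg2"`).
#' @param ref_sex,ref_diet Reference levels; the indicator is 1 for the
#'   non-reference level.
#' @return Numeric matrix (samples x 7) with row names from
#'   `samples$sample`; reference levels stored in the `"references"`
#'   attribute.
#' @export
build_design <- function(samples, ref_sex = "F", ref_diet = "CD") {
  req <- c("sample", "sex", "diet", "genotype")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("`samples` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!ref_sex %in% c("F", "M")) stop_bad_arg("ref_sex", "must be 'F' or 'M'")
  if (!ref_diet %in% c("CD", "HFD"))
    stop_bad_arg("ref_diet", "must be 'CD' or 'HFD'")

  check_levels <- function(col, allowed) {
    bad <- !samples[[col]] %in% allowed
    if (any(bad))
      stop(sprintf("unknown %s level(s) %s for sample(s): %s", col,
                   paste(unique(samples[[col]][bad]), collapse = ", "),
                   paste(samples$sample[bad], collapse = ", ")),
           call. = FALSE)
  }
  check_levels("sex", c("F", "M"))
  check_levels("diet", c("CD", "HFD"))
  check_levels("genotype", c("LOAD1", "LOAD1.Mthfr", "LOAD1.Plcg2"))

  sex <- as.numeric(samples$sex != ref_sex)
  diet <- as.numeric(samples$diet != ref_diet)
  mthfr <- as.numeric(samples$genotype == "LOAD1.Mthfr")
  plcg2 <- as.numeric(samples$genotype == "LOAD1.Plcg2")
  X <- cbind(1, sex, diet, mthfr, plcg2, diet * mthfr, diet * plcg2)
  dimnames(X) <- list(samples$sample, model_terms(ref_sex, ref_diet))
  attr(X, "references") <-
    list(sex = ref_sex, diet = ref_diet, genotype = "LOAD1")
  X
}

#' Fit per-gene effect coefficients by ordinary least squares
#'
#' Fits `log(expr) = X beta + eps` independently for every gene, sharing one
#' QR decomposition of the design across genes. Standard errors come from
#' the per-gene residual variance and the diagonal of the normal-equations
#' inverse; t statistics use Student's t with `n - p` degrees of freedom.
#' No per-gene multiple-testing correction is applied.
#'
#' @param expr Matrix of log expression, genes in rows, samples in columns
#'   (typically the output of [log_transform()]).
#' @param design Design matrix from [build_design()]; rows must cover the
#'   sample columns of `expr`.
#' @return An `effect_table`: long data frame with columns `gene`, `term`,
#'   `beta`, `se`, `t`, `p`, plus attributes `df_residual`, `sigma2`
#'   (named per-gene residual variance) and `references`.
#' @export
fit_effects <- function(expr, design) {
  E <- unclass(expr)
  if (is.null(rownames(E)) || is.null(colnames(E)))
    stop("`expr` must have gene row names and sample column names",
         call. = FALSE)
  if (!all(colnames(E) %in% rownames(design)))
    stop("samples in `expr` missing from `design`: ",
         paste(setdiff(colnames(E), rownames(design)), collapse = ", "),
         call. = FALSE)
  X <- design[colnames(E), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    stop(sprintf("need more samples (%d) than model parameters (%d)", n, p),
         call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p)
    stop("design matrix is rank deficient; cannot fit the full model",
         call. = FALSE)

  Y <- t(E)                                   # samples x genes
  cf <- qr.coef(qx, Y)                        # p x genes
  res <- Y - X %*% cf
  dfres <- n - p
  s2 <- colSums(res^2) / dfres
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(outer(diag(xtx_inv), s2))
  tval <- cf / se
  pval <- 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE)

  genes <- rownames(E)
  terms <- colnames(X)
  out <- data.frame(
    gene = rep(genes, each = p),
    term = rep(terms, times = length(genes)),
    beta = as.vector(cf),
    se = as.vector(se),
    t = as.vector(tval),
    p = as.vector(pval),
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("effect_table", "data.frame"),
            df_residual = dfres,
            sigma2 = stats::setNames(s2, genes),
            references = attr(design, "references"))
}

#' Extract one term's coefficients as a named vector
#'
#' @param effects An `effect_table` from [fit_effects()].
#' @param term One of the table's term labels.
#' @param value Which column to extract (default `"beta"`).
#' @return Named numeric vector (names are gene IDs).
#' @export
effect_vector <- function(effects, term, value = "beta") {
  if (!term %in% effects$term)
    stop(sprintf("term '%s' not present in effect table (has: %s)", term,
                 paste(unique(effects$term), collapse = ", ")),
         call. = FALSE)
  sub <- effects[effects$term == term, ]
  stats::setNames(sub[[value]], sub$gene)
}
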