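# Synthetic-data generators: every input the pipeline consumes can be
# simulated with known planted structure, giving downstream stages ground
# truth to recover.

#' Construct a complete factorial study design
#'
#' One row per sample of the 2 (sex) x 2 (diet) x 3 (genotype) design with a
#' fixed number of replicates per cell. Samples are assigned to lanes of
#' `lane_size` consecutive samples (a NanoString cartridge holds 12).
#'
#' @param n_per_cell Replicates per sex/diet/genotype cell (default 6, the
#'   study's transcriptomics group size).
#' @param sexes,diets,genotypes Factor levels.
#' @param lane_size Samples per lane.
#' @param site Site label attached to every sample.
#' @return Data frame with columns `sample`, `sex`, `diet`, `genotype`,
#'   `lane`, `site`.
#' @export
study_design <- function(n_per_cell = 6,
                         sexes = c("F", "M"),
                         diets = c("CD", "HFD"),
                         genotypes = c("LOAD1", "LOAD1.Mthfr", "LOAD1.Plcg2"),
                         lane_size = 12,
                         site = "IU") {
  if (n_per_cell < 1) stop_bad_arg("n_per_cell", "must be >= 1")
  cells <- expand.grid(sex = sexes, diet = diets, genotype = genotypes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(cells)), each = n_per_cell)
  out <- cells[idx, , drop = FALSE]
  n <- nrow(out)
  out$sample <- sprintf("S%03d", seq_len(n))
  out$lane <- sprintf("L%02d", (seq_len(n) - 1L) %/% lane_size + 1L)
  out$site <- site
  rownames(out) <- NULL
  out[, c("sample", "sex", "diet", "genotype", "lane", "site")]
}

#' Define planted per-gene true effects
#'
#' Builds the ground-truth coefficient matrix (genes x model terms, on the
#' natural-log scale) for the count generator. Housekeeping genes carry a
#' zero coefficient for every non-intercept term, by construction.
#'
#' @param n_genes Number of panel genes excluding housekeeping genes.
#' @param n_housekeeping Number of housekeeping genes (>= 2), named
#'   `Hk01`, `Hk02`, ...
#' @param intercept Baseline log expression; scalar or length `n_genes +
#'   n_housekeeping` vector.
#' @param planted Named list: term label -> either a full-length numeric
#'   vector of true coefficients, or a named vector assigning coefficients
#'   to specific genes (all other genes 0). Term labels must match
#'   [model_terms()].
#' @param dispersion Negative-binomial dispersion (variance = mu + d mu^2);
#'   `0` selects the deterministic zero-noise limit.
#' @param lane_scales Optional positive technical scale factor per lane
#'   (named by lane ID, or unnamed and recycled in lane order).
#' @return A `planted_effects` list with elements `beta` (matrix), `genes`,
#'   `housekeeping`, `dispersion`, `lane_scales`.
#' @export
planted_effects <- function(n_genes = 200,
                            n_housekeeping = 10,
                            intercept = log(500),
                            planted = list(),
                            dispersion = 0.05,
                            lane_scales = NULL) {
  if (n_housekeeping < 2) stop_bad_arg("n_housekeeping", "must be >= 2")
  if (n_genes < n_housekeeping)
    stop_bad_arg("n_genes", "must be >= number of housekeeping genes")
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion < 0)
    stop_bad_arg("dispersion", "must be a single non-negative number")
  if (!is.null(lane_scales) && any(lane_scales <= 0))
    stop_bad_arg("lane_scales", "must all be > 0")

  genes <- sprintf("Gm%04d", seq_len(n_genes))
  hk <- sprintf("Hk%02d", seq_len(n_housekeeping))
  all_genes <- c(genes, hk)
  terms <- model_terms()
  beta <- matrix(0, nrow = length(all_genes), ncol = length(terms),
                 dimnames = list(all_genes, terms))
  beta[, "(Intercept)"] <- intercept

  for (term in names(planted)) {
    if (!term %in% terms)
      stop(sprintf("planted term '%s' is not a model term (expected one of: %s)",
                   term, paste(terms, collapse = ", ")), call. = FALSE)
    v <- planted[[term]]
    if (!is.null(names(v))) {
      unknown <- setdiff(names(v), all_genes)
      if (length(unknown))
        stop("planted genes not in panel: ", paste(unknown, collapse = ", "),
             call. = FALSE)
      beta[names(v), term] <- v
    } else {
      if (length(v) == 1) v <- rep(v, n_genes)
      if (length(v) != n_genes)
        stop_bad_arg("planted", sprintf(
          "unnamed vector for '%s' must have length 1 or n_genes", term))
      beta[genes, term] <- v
    }
  }
  # housekeeping genes are expression-stable by definition
  beta[hk, setdiff(terms, "(Intercept)")] <- 0

  structure(list(beta = beta, genes = genes, housekeeping = hk,
                 dispersion = dispersion, lane_scales = lane_scales),
            class = "planted_effects")
}

#' Count matrix container
#'
#' Raw gene x sample counts plus the metadata normalization needs: lane
#' assignment per sample and the housekeeping-gene flags.
#'
#' @param counts Non-negative numeric matrix, genes x samples, with
#'   dimnames.
#' @param lane Character vector of lane IDs, one per sample (named or in
#'   column order).
#' @param housekeeping Character vector of housekeeping gene IDs (>= 2,
#'   all present among the row names).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, lane, housekeeping) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have gene and sample dimnames", call. = FALSE)
  if (any(counts < 0))
    stop("`counts` contains negative values", call. = FALSE)
  if (length(lane) != ncol(counts))
    stop("`lane` must give one lane per sample", call. = FALSE)
  if (is.null(names(lane))) names(lane) <- colnames(counts)
  if (length(housekeeping) < 2)
    stop("need at least 2 housekeeping genes", call. = FALSE)
  if (!all(housekeeping %in% rownames(counts)))
    stop("housekeeping genes missing from counts: ",
         paste(setdiff(housekeeping, rownames(counts)), collapse = ", "),
         call. = FALSE)
  structure(list(counts = counts, lane = lane[colnames(counts)],
                 housekeeping = housekeeping),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d housekeeping, %d lanes)\n",
              nrow(x$counts), ncol(x$counts), length(x$housekeeping),
              length(unique(x$lane))))
  invisible(x)
}

#' Simulate a NanoString-like factorial study
#'
#' Counts are drawn from a gamma-Poisson (negative binomial) around
#' `lane_scale * exp(X beta_true)`; `dispersion = 0` gives the
#' deterministic limit `round(mu)`.
#'
#' @param design Sample table from [study_design()].
#' @param effects A [planted_effects()] object.
#' @param seed Optional RNG seed for reproducibility.
#' @return List with elements `counts` (a [count_matrix()]) and `samples`
#'   (the design table).
#' @export
generate_study <- function(design, effects, seed = NULL) {
  stopifnot(inherits(effects, "planted_effects"))
  if (!is.null(seed)) set.seed(seed)
  X <- build_design(design)
  beta <- effects$beta
  if (!identical(colnames(beta), colnames(X)))
    stop("planted effect terms do not match the design matrix terms",
         call. = FALSE)

  lanes <- unique(design$lane)
  ls <- effects$lane_scales
  if (is.null(ls)) ls <- rep(1, length(lanes))
  if (is.null(names(ls))) ls <- stats::setNames(rep_len(ls, length(lanes)), lanes)
  if (any(ls <= 0)) stop_bad_arg("lane_scales", "must all be > 0")
  scale_per_sample <- ls[design$lane]

  mu <- exp(beta %*% t(X))                       # genes x samples
  mu <- sweep(mu, 2, scale_per_sample, `*`)
  if (effects$dispersion == 0) {
    counts <- round(mu)
  } else {
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / effects$dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
  }
  colnames(counts) <- design$sample
  cm <- count_matrix(counts, stats::setNames(design$lane, design$sample),
                     effects$housekeeping)
  list(counts = cm, samples = design)
}

#' Simulate human module / subtype references with planted correlation
#'
#' For each requested module, per-gene human log2 fold changes are drawn so
#' that their correlation with the chosen mouse term's true coefficients has
#' expectation `rho`; `rho = 0` modules are independent of every term.
#' Gene symbols are upper-cased (the default mouse-to-human mapping).
#'
#' @param effects A [planted_effects()] object (source of the true
#'   coefficients and the panel gene universe).
#' @param module_spec Data frame with columns `module`, `cluster`, `region`,
#'   `term`, `n_genes`, `rho`.
#' @param log2fc_sd Marginal spread of the simulated log2 fold changes.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `module`, `cluster`, `region`, `gene`,
#'   `log2fc`.
#' @export
generate_human_reference <- function(effects, module_spec, log2fc_sd = 0.5,
                                     seed = NULL) {
  stopifnot(inherits(effects, "planted_effects"))
  req <- c("module", "cluster", "region", "term", "n_genes", "rho")
  miss <- setdiff(req, names(module_spec))
  if (length(miss))
    stop("`module_spec` missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(abs(module_spec$rho) > 1))
    stop_bad_arg("rho", "must satisfy |rho| <= 1")
  panel <- effects$genes
  if (any(module_spec$n_genes > length(panel)))
    stop("module larger than panel", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  parts <- lapply(seq_len(nrow(module_spec)), function(i) {
    ms <- module_spec[i, ]
    g <- sample(panel, ms$n_genes)
    rho <- ms$rho
    if (rho == 0) {
      lfc <- stats::rnorm(ms$n_genes, 0, log2fc_sd)
    } else {
      b <- effects$beta[g, ms$term]
      if (stats::sd(b) == 0)
        stop(sprintf(
          "cannot plant rho != 0 for module '%s': term '%s' is constant over its genes",
          ms$module, ms$term), call. = FALSE)
      xs <- (b - mean(b)) / stats::sd(b)
      noise <- if (abs(rho) == 1) 0 else stats::rnorm(ms$n_genes)
      lfc <- (rho * xs + sqrt(1 - rho^2) * noise) * log2fc_sd
    }
    data.frame(module = ms$module, cluster = ms$cluster, region = ms$region,
               gene = toupper(g), log2fc = lfc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Simulate a volume-of-interest uptake table
#'
#' Paired regions get left/right records; the reference region (cerebellum)
#' is emitted once, pre-merged. Uptake is log-normal around a region mean, a
#' per-subject dose scale (which cancels in the SUVR), and any planted
#' multiplicative group effects.
#'
#' @param subjects Data frame with columns `subject`, `sex`, `diet`,
#'   `genotype`.
#' @param regions Character vector of region names, including the reference.
#' @param reference Reference region name (must appear in `regions`).
#' @param region_means Optional named vector of baseline region means
#'   (default 1 for every region).
#' @param planted Optional data frame with columns `region`, `factor`,
#'   `level`, `effect`: subjects whose `factor` equals `level` have the
#'   region mean multiplied by `effect`.
#' @param cv Within-region coefficient of variation of the log-normal noise.
#' @param subject_scale_sd SD (log scale) of the per-subject dose factor.
#' @param seed Optional RNG seed.
#' @return Long data frame: `subject`, `sex`, `diet`, `genotype`, `region`,
#'   `side` (`"L"`/`"R"`/`"merged"`), `uptake`.
#' @export
generate_voi_dataset <- function(subjects, regions, reference = "cerebellum",
                                 region_means = NULL, planted = NULL,
                                 cv = 0.1, subject_scale_sd = 0.2,
                                 seed = NULL) {
  if (!reference %in% regions)
    stop(sprintf("reference region '%s' missing from `regions`", reference),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(region_means))
    region_means <- stats::setNames(rep(1, length(regions)), regions)
  sdlog <- sqrt(log(1 + cv^2))

  paired <- setdiff(regions, reference)
  grid <- rbind(
    expand.grid(region = paired, side = c("L", "R"),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    data.frame(region = reference, side = "merged", stringsAsFactors = FALSE)
  )
  dose <- exp(stats::rnorm(nrow(subjects), 0, subject_scale_sd))

  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    m <- region_means[grid$region]
    if (!is.null(planted) && nrow(planted)) {
      for (j in seq_len(nrow(planted))) {
        pl <- planted[j, ]
        if (identical(as.character(s[[pl$factor]]), as.character(pl$level)))
          m[grid$region == pl$region] <- m[grid$region == pl$region] * pl$effect
      }
    }
    up <- dose[i] * m * exp(stats::rnorm(nrow(grid), 0, sdlog))
    data.frame(subject = s$subject, sex = s$sex, diet = s$diet,
               genotype = s$genotype, region = grid$region, side = grid$side,
               uptake = up, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a multiplex cytokine measurement table
#'
#' Log-normal analyte values; a configurable fraction of records is flagged
#' below the analyte's lower limit of detection (LLOD), with the recorded
#' raw value drawn below the LLOD.
#'
#' @param groups Data frame with one row per group: columns `sex`, `diet`,
#'   `genotype`.
#' @param analytes Named numeric vector of LLODs (> 0), one per analyte.
#' @param n_per_group Subjects per group.
#' @param frac_below_llod Probability a record falls below the LLOD.
#' @param meanlog,sdlog Log-normal parameters of the detectable values;
#'   `meanlog` defaults to `log(4 * llod)` per analyte.
#' @param seed Optional RNG seed.
#' @return Data frame: `subject`, `sex`, `diet`, `genotype`, `analyte`,
#'   `value`, `below_llod`, `llod`.
#' @export
generate_cytokine_table <- function(groups, analytes, n_per_group = 6,
                                    frac_below_llod = 0.1, meanlog = NULL,
                                    sdlog = 0.5, seed = NULL) {
  if (is.null(names(analytes)) || any(analytes <= 0))
    stop_bad_arg("analytes", "must be a named vector of positive LLODs")
  if (frac_below_llod < 0 || frac_below_llod > 1)
    stop_bad_arg("frac_below_llod", "must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(meanlog)) meanlog <- log(4 * analytes)
  meanlog <- rep_len(meanlog, length(analytes))

  subj <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    data.frame(subject = sprintf("G%02dM%02d", i, seq_len(n_per_group)),
               sex = g$sex, diet = g$diet, genotype = g$genotype,
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, lapply(seq_along(analytes), function(k) {
    n <- nrow(subj)
    flagged <- stats::runif(n) < frac_below_llod
    value <- stats::rlnorm(n, meanlog[k], sdlog)
    value[flagged] <- analytes[k] * stats::runif(sum(flagged))
    data.frame(subj, analyte = names(analytes)[k], value = value,
               below_llod = flagged, llod = unname(analytes[k]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a KEGG-like gene-set collection
#'
#' Null sets are random draws from the panel; planted sets take the genes
#' with the most extreme true coefficients of a chosen term (in a chosen
#' direction), so that a preranked enrichment on that term's estimated
#' coefficients should flag them.
#'
#' @param effects A [planted_effects()] object.
#' @param n_null Number of random (null) sets.
#' @param set_size Length-2 range of null set sizes.
#' @param planted Optional data frame with columns `name`, `term`, `size`,
#'   `direction` (+1 for top, -1 for bottom of the ranking).
#' @param seed Optional RNG seed.
#' @return Named list of upper-cased gene symbol vectors.
#' @export
generate_gene_sets <- function(effects, n_null = 25, set_size = c(10, 40),
                               planted = NULL, seed = NULL) {
  stopifnot(inherits(effects, "planted_effects"))
  if (!is.null(seed)) set.seed(seed)
  panel <- effects$genes
  sets <- list()
  if (!is.null(planted) && nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      pl <- planted[i, ]
      b <- effects$beta[panel, pl$term] * pl$direction
      top <- panel[order(b, decreasing = TRUE)][seq_len(pl$size)]
      sets[[pl$name]] <- toupper(top)
    }
  }
  for (i in seq_len(n_null)) {
    sz <- sample(seq(set_size[1], set_size[2]), 1)
    sets[[sprintf("NullSet%02d", i)]] <- toupper(sample(panel, sz))
  }
  sets
}
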