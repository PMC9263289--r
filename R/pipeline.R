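# End-to-end orchestration: generate or load every input, run the stages in
# order, persist all intermediates, and emit a reproducible run manifest.

#' Generate a complete synthetic input bundle
#'
#' Writes every file the pipeline consumes, with known planted structure:
#' a factorial count study whose diet-by-Plcg2 interaction carries real
#' per-gene effects while the diet-by-Mthfr interaction is null; human
#' module references in which the immune (cluster B) modules are positively
#' correlated with the planted interaction and all other modules are null;
#' subtype references with correlated inflammatory ("A") subtypes;
#' a KEGG-like GMT with interaction-loaded immune sets; a VOI table with a
#' planted diet effect on the hippocampus; and a cytokine table with a
#' below-LLOD fraction.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master RNG seed for the bundle.
#' @param n_genes Panel size excluding housekeeping genes.
#' @param n_per_cell Transcriptomics replicates per factor cell.
#' @param interaction_sd SD of the planted diet-by-Plcg2 true coefficients.
#' @param rho_immune Planted correlation of immune modules with the
#'   interaction term.
#' @return A pipeline config list (see [run_pipeline()]).
#' @export
demo_inputs <- function(dir, seed = 1, n_genes = 150, n_per_cell = 6,
                        interaction_sd = 0.35, rho_immune = 0.8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  planted <- list(
    "Sex(Male)" = stats::rnorm(n_genes, 0, 0.10),
    "HFD" = stats::rnorm(n_genes, 0, 0.15),
    "Mthfr.C677T" = stats::rnorm(n_genes, 0, 0.10),
    "Plcg2.M28L" = stats::rnorm(n_genes, 0, 0.10),
    "HFD*Plcg2.M28L" = stats::rnorm(n_genes, 0, interaction_sd)
    # HFD*Mthfr.C677T left null on purpose
  )
  eff <- planted_effects(n_genes = n_genes, n_housekeeping = 8,
                         intercept = log(500), planted = planted,
                         dispersion = 0.05,
                         lane_scales = exp(stats::rnorm(12, 0, 0.1)))
  design <- study_design(n_per_cell = n_per_cell)
  study <- generate_study(design, eff, seed = seed + 1)

  regions7 <- c("DLPFC", "STG", "FP", "PHG", "TCX", "IFG", "CBE")
  module_n <- min(40, n_genes %/% 2)
  subtype_n <- min(60, n_genes %/% 2)
  module_spec <- rbind(
    data.frame(module = sprintf("ImmuneB%d", 1:5), cluster = "B",
               region = regions7[1:5], term = "HFD*Plcg2.M28L",
               n_genes = module_n, rho = rho_immune,
               stringsAsFactors = FALSE),
    data.frame(module = c("ECMA1", "ECMA2", "NeuroC1", "NeuroC2",
                          "CellCycleD1", "CellCycleD2", "StressE1",
                          "StressE2"),
               cluster = rep(c("A", "C", "D", "E"), each = 2),
               region = regions7[c(1, 2, 3, 4, 5, 6, 7, 1)],
               term = "HFD*Plcg2.M28L", n_genes = module_n, rho = 0,
               stringsAsFactors = FALSE))
  modules <- generate_human_reference(eff, module_spec, seed = seed + 2)

  subtype_spec <- data.frame(
    module = c("ROSMAP.A", "ROSMAP.B", "Mayo.A", "Mayo.B", "Mayo.C",
               "MSBB.A", "MSBB.B"),
    cluster = c("inflammatory", "non-inflammatory", "inflammatory",
                "non-inflammatory", "non-inflammatory", "inflammatory",
                "non-inflammatory"),
    region = "none", term = "HFD*Plcg2.M28L", n_genes = subtype_n,
    rho = c(0.7, 0, 0.7, 0, 0, 0.7, 0), stringsAsFactors = FALSE)
  subtypes <- generate_human_reference(eff, subtype_spec, seed = seed + 3)

  set_spec <- data.frame(name = sprintf("ImmuneSet%d", 1:3),
                         term = "HFD*Plcg2.M28L", size = 25, direction = 1,
                         stringsAsFactors = FALSE)
  sets <- generate_gene_sets(eff, n_null = 20, set_size = c(10, 40),
                             planted = set_spec, seed = seed + 4)

  cells <- expand.grid(sex = c("F", "M"), diet = c("CD", "HFD"),
                       genotype = c("LOAD1", "LOAD1.Mthfr", "LOAD1.Plcg2"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  subjects <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(subject = sprintf("V%02d%02d", i, 1:10),
               sex = cells$sex[i], diet = cells$diet[i],
               genotype = cells$genotype[i], stringsAsFactors = FALSE)
  }))
  pet_regions <- c("cerebellum", "hippocampus", "thalamus",
                   "primary_motor_cortex", "cingulate_cortex",
                   "caudate_putamen", "visual_cortex", "auditory_cortex",
                   "entorhinal_cortex", "parietal_cortex", "corpus_callosum")
  voi <- generate_voi_dataset(
    subjects, pet_regions,
    region_means = stats::setNames(seq(0.8, 1.8,
                                       length.out = length(pet_regions)),
                                   pet_regions),
    planted = data.frame(region = "hippocampus", factor = "diet",
                         level = "HFD", effect = 1.3,
                         stringsAsFactors = FALSE),
    seed = seed + 5)

  analytes <- c(IFNg = 0.16, IL1b = 0.11, IL2 = 0.45, IL4 = 0.07,
                IL6 = 0.61, IL8 = 0.26, IL10 = 0.95, IL12p70 = 25.1,
                IL13 = 3.44, TNFa = 0.13)
  cyto <- generate_cytokine_table(cells, analytes, n_per_group = 6,
                                  frac_below_llod = 0.15, seed = seed + 6)

  paths <- list(counts = file.path(dir, "counts.tsv"),
                samples = file.path(dir, "samples.tsv"),
                modules = file.path(dir, "modules.tsv"),
                subtypes = file.path(dir, "subtypes.tsv"),
                gmt = file.path(dir, "genesets.gmt"),
                voi = file.path(dir, "voi.csv"),
                cytokines = file.path(dir, "cytokines.csv"))
  write_study(study, paths$counts, paths$samples)
  write_module_reference(modules, paths$modules)
  write_module_reference(subtypes, paths$subtypes)
  write_gmt(sets, paths$gmt)
  write_voi(voi, paths$voi)
  write_cytokines(cyto, paths$cytokines)

  c(paths,
    list(ref_sex = "F", ref_diet = "CD", log_base = "e", pseudocount = 0,
         min_overlap = 5, alpha = 0.05, gsea_weight = 1, n_perm = 1000,
         coherent_term = "HFD*Plcg2.M28L", coherent_clusters = c("A", "B"),
         suvr_reference = "cerebellum", suvr_threshold = 0.80,
         sex_stratified = FALSE, seed = seed))
}

pipeline_defaults <- function() {
  list(ref_sex = "F", ref_diet = "CD", log_base = "e", pseudocount = 0,
       min_overlap = 5, alpha = 0.05, gsea_weight = 1, n_perm = 10000,
       coherent_term = "HFD*Plcg2.M28L", coherent_clusters = "B",
       suvr_reference = "cerebellum", suvr_threshold = 0.80,
       sex_stratified = FALSE, seed = 1)
}

#' Validate pipeline input files
#'
#' Schema checks for every reader; returns an itemized report rather than
#' failing on the first problem.
#'
#' @param paths Named list of file paths (any subset of `counts` +
#'   `samples`, `modules`, `subtypes`, `gmt`, `voi`, `cytokines`).
#' @return Data frame `input`, `level` (`"error"`/`"warning"`), `message`;
#'   the `"ok"` attribute is TRUE when no errors were found.
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  add <- function(input, level, msg)
    issues[[length(issues) + 1L]] <<- data.frame(
      input = input, level = level, message = msg, stringsAsFactors = FALSE)

  try_read <- function(input, fn) {
    tryCatch(fn(), error = function(e) {
      add(input, "error", conditionMessage(e)); NULL
    })
  }

  for (key in intersect(names(paths),
                        c("counts", "samples", "modules", "subtypes",
                          "gmt", "voi", "cytokines"))) {
    if (!file.exists(paths[[key]])) {
      add(key, "error", sprintf("file not found: %s", paths[[key]]))
    }
  }

  if (!is.null(paths$counts) && file.exists(paths$counts) &&
      !is.null(paths$samples) && file.exists(paths$samples)) {
    raw <- try_read("counts", function()
      utils::read.delim(paths$counts, check.names = FALSE))
    has_neg <- FALSE
    if (!is.null(raw) && all(c("gene", "housekeeping") %in% names(raw))) {
      m <- as.matrix(raw[, setdiff(names(raw), c("gene", "housekeeping")),
                         drop = FALSE])
      neg <- which(m < 0, arr.ind = TRUE)
      if (nrow(neg)) {
        has_neg <- TRUE
        add("counts", "error", sprintf(
          "negative count for gene '%s' in sample '%s'",
          raw$gene[neg[1, 1]], colnames(m)[neg[1, 2]]))
      }
      if (sum(raw$housekeeping) < 2)
        add("counts", "error", "fewer than 2 housekeeping genes")
    }
    if (!has_neg)
      try_read("counts", function()
        read_study(paths$counts, paths$samples))
  }
  for (key in c("modules", "subtypes")) {
    if (!is.null(paths[[key]]) && file.exists(paths[[key]])) {
      ref <- try_read(key, function() read_module_reference(paths[[key]]))
      if (!is.null(ref) && any(!is.finite(ref$log2fc)))
        add(key, "error", "non-finite log2fc value(s)")
    }
  }
  if (!is.null(paths$gmt) && file.exists(paths$gmt))
    try_read("gmt", function() read_gmt(paths$gmt))
  if (!is.null(paths$voi) && file.exists(paths$voi)) {
    voi <- try_read("voi", function() read_voi(paths$voi))
    if (!is.null(voi) && any(voi$uptake <= 0))
      add("voi", "error", "non-positive uptake value(s)")
  }
  if (!is.null(paths$cytokines) && file.exists(paths$cytokines))
    try_read("cytokines", function() read_cytokines(paths$cytokines))

  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(input = character(), level = character(),
               message = character(), stringsAsFactors = FALSE)
  structure(out, ok = !any(out$level == "error"))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order — normalization, per-gene modelling,
#' module and subtype correlation grids, coherent-gene extraction,
#' preranked GSEA plus ORA, NES-PCA, SUVR region selection and ANOVA, and
#' cytokine statistics — persisting each intermediate to `out_dir` and
#' writing a JSON run manifest (package version, seed, config hash, output
#' checksums). Deterministic for a fixed config and seed.
#'
#' @param config Named list (as returned by [demo_inputs()]) or the path
#'   of a YAML file with the same keys.
#' @param out_dir Output directory.
#' @return Invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(pipeline_defaults(), config)
  req_paths <- c("counts", "samples", "modules", "subtypes", "gmt", "voi",
                 "cytokines")
  for (key in req_paths) {
    if (is.null(config[[key]]))
      stop(sprintf("config is missing input path '%s'", key), call. = FALSE)
    if (!file.exists(config[[key]]))
      stop(sprintf("input '%s' not found: %s", key, config[[key]]),
           call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  outputs <- character()
  save_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  study <- stage("read", function()
    read_study(config$counts, config$samples))
  norm <- stage("normalize", function() normalize_counts(study$counts))
  logexpr <- stage("log_transform", function()
    log_transform(norm, config$pseudocount, config$log_base))
  design <- stage("design", function()
    build_design(study$samples, config$ref_sex, config$ref_diet))
  effects <- stage("fit", function() fit_effects(logexpr, design))
  save_tsv(effects, "effects.tsv")

  modules <- stage("read_modules", function()
    read_module_reference(config$modules))
  subtypes <- stage("read_subtypes", function()
    read_module_reference(config$subtypes))
  grid_modules <- stage("correlate_modules", function()
    correlate_effects(effects, modules, min_overlap = config$min_overlap,
                      alpha = config$alpha))
  grid_subtypes <- stage("correlate_subtypes", function()
    correlate_effects(effects, subtypes, min_overlap = config$min_overlap,
                      alpha = config$alpha))
  outputs <- c(outputs,
               write_grid(grid_modules, file.path(out_dir, "grid_modules.tsv")),
               write_grid(grid_subtypes, file.path(out_dir, "grid_subtypes.tsv")))

  grids_sex <- NULL
  if (isTRUE(config$sex_stratified)) {
    grids_sex <- stage("sex_stratified", function() {
      lapply(c(F_only = "F", M_only = "M"), function(sx) {
        keep <- study$samples$sex == sx
        Xs <- design[study$samples$sample[keep],
                     setdiff(colnames(design), model_terms(
                       config$ref_sex, config$ref_diet)[2]), drop = FALSE]
        eff_s <- fit_effects(unclass(logexpr)[, study$samples$sample[keep],
                                              drop = FALSE], Xs)
        correlate_effects(eff_s, modules, min_overlap = config$min_overlap,
                          alpha = config$alpha)
      })
    })
    for (nm in names(grids_sex))
      outputs <- c(outputs, write_grid(
        grids_sex[[nm]], file.path(out_dir, sprintf("grid_modules_%s.tsv", nm))))
  }

  coherent <- stage("coherent", function() {
    out <- lapply(config$coherent_clusters, function(cl)
      extract_coherent_genes(effects, modules, config$coherent_term, cl))
    names(out) <- config$coherent_clusters
    out
  })
  for (cl in names(coherent))
    save_tsv(coherent[[cl]], sprintf("coherent_cluster_%s.tsv", cl))

  sets <- stage("read_gmt", function() read_gmt(config$gmt))
  terms <- setdiff(unique(effects$term), "(Intercept)")
  gsea <- stage("gsea", function() {
    res <- lapply(seq_along(terms), function(i)
      gsea_preranked(effect_vector(effects, terms[i]), sets,
                     weight = config$gsea_weight, n_perm = config$n_perm,
                     seed = config$seed + i))
    names(res) <- terms
    res
  })
  gsea_long <- do.call(rbind, lapply(terms, function(tm)
    cbind(term = tm, gsea[[tm]])))
  save_tsv(gsea_long, "gsea.tsv")

  pca <- stage("nes_pca", function() {
    common <- Reduce(intersect, lapply(gsea, function(g) g$set))
    nes <- do.call(rbind, lapply(gsea, function(g)
      g$nes[match(common, g$set)]))
    dimnames(nes) <- list(names(gsea), common)
    nes_pca(nes, na_action = "drop")
  })
  save_tsv(data.frame(component = names(pca$var_frac),
                      var_frac = unname(pca$var_frac),
                      pca$scores, check.names = FALSE), "nes_pca.tsv")

  ora_tab <- stage("ora", function() {
    hits <- unique(unlist(lapply(coherent, function(x) x$human)))
    ora(hits, human_symbols(unique(effects$gene)), sets)
  })
  save_tsv(ora_tab, "ora.tsv")

  voi <- stage("read_voi", function() read_voi(config$voi))
  suvr <- stage("suvr", function()
    compute_suvr(average_bilateral(voi), config$suvr_reference))
  sel <- stage("select_regions", function()
    select_regions_by_variance(suvr, config$suvr_threshold))
  save_tsv(sel$selection, "suvr_selection.tsv")
  suvr_tests <- stage("region_anova", function()
    region_anova(suvr, setdiff(sel$regions, config$suvr_reference),
                 factors = c("diet", "genotype"), alpha = config$alpha))
  save_tsv(suvr_tests, "suvr_anova.tsv")

  cyto <- stage("cytokines", function()
    suppressMessages(impute_llod(read_cytokines(config$cytokines))))
  cyto_tests <- stage("cytokine_stats", function() {
    do.call(rbind, lapply(split(cyto, cyto$analyte), function(d) {
      tab <- anova_two_way(d$value, d$diet, d$genotype,
                           names = c("diet", "genotype"))
      cbind(analyte = d$analyte[1], tab)
    }))
  })
  save_tsv(cyto_tests, "cytokine_anova.tsv")

  # manifest: versions, seed, config hash, output checksums
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config[order(names(config))], cfg_file)
  outputs <- c(outputs, cfg_file)
  manifest <- list(
    package = "loadalign",
    version = as.character(utils::packageVersion("loadalign")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    outputs = lapply(stats::setNames(nm = basename(outputs)), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(effects = effects, grid_modules = grid_modules,
                 grid_subtypes = grid_subtypes, grids_sex = grids_sex,
                 coherent = coherent, gsea = gsea, nes_pca = pca,
                 ora = ora_tab, suvr = suvr, selection = sel,
                 suvr_anova = suvr_tests, cytokine_anova = cyto_tests,
                 manifest = manifest))
}
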