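# Shared fixture builders. All fixtures are generated in code, seeded per
# test, so the suite carries no stored data.

# small factorial study with deterministic integer counts: every planted
# coefficient is the log of a dyadic rational, so round(mu) is exact and the
# whole normalize -> log -> fit path is noise-free
exact_study <- function() {
  planted <- list("Sex(Male)" = log(2), "HFD" = log(1.5),
                  "Mthfr.C677T" = log(1.25), "Plcg2.M28L" = log(2),
                  "HFD*Mthfr.C677T" = log(1.5), "HFD*Plcg2.M28L" = log(1.25))
  eff <- planted_effects(n_genes = 6, n_housekeeping = 3,
                         intercept = log(512), planted = planted,
                         dispersion = 0, lane_scales = NULL)
  design <- study_design(n_per_cell = 2, lane_size = 8)
  list(effects = eff, design = design,
       study = generate_study(design, eff))
}

# small noisy study for generic downstream use
noisy_study <- function(seed = 11, n_genes = 60, dispersion = 0.05,
                        planted = list()) {
  eff <- planted_effects(n_genes = n_genes, n_housekeeping = 5,
                         planted = planted, dispersion = dispersion,
                         lane_scales = c(1, 1.3, 0.8, 1.1, 1, 1.2))
  design <- study_design(n_per_cell = 6)
  list(effects = eff, design = design,
       study = generate_study(design, eff, seed = seed))
}

# reference table built directly from chosen per-gene values
manual_reference <- function(genes, log2fc, module = "M1", cluster = "B",
                             region = "DLPFC") {
  data.frame(module = module, cluster = cluster, region = region,
             gene = toupper(genes), log2fc = log2fc,
             stringsAsFactors = FALSE)
}

# independent full running-sum GSEA oracle (O(N) walk, no shortcuts)
oracle_es <- function(scores_sorted, hit_positions, weight) {
  N <- length(scores_sorted)
  inset <- seq_len(N) %in% hit_positions
  w <- abs(scores_sorted)^weight
  W <- sum(w[inset])
  n <- sum(inset)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (inset[i]) w[i] / W else -1 / (N - n)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# independent combinatorial hypergeometric upper tail
oracle_hyper_tail <- function(x, k, U, m) {
  j <- seq(x, min(k, m))
  sum(choose(k, j) * choose(U - k, m - j)) / choose(U, m)
}
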