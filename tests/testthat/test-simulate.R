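# Synthetic-data generators: determinism, planted-structure recovery,
# parameter validation.

test_that("zero-dispersion limit gives deterministic counts at the planted mean", {
  eff <- planted_effects(n_genes = 5, n_housekeeping = 2,
                         intercept = log(100), dispersion = 0)
  design <- study_design(n_per_cell = 1)
  study <- generate_study(design, eff)
  expect_true(all(study$counts$counts == 100))
})

test_that("the same seed reproduces the study byte-for-byte", {
  a <- noisy_study(seed = 42)
  b <- noisy_study(seed = 42)
  expect_identical(a$study$counts$counts, b$study$counts$counts)
  expect_identical(a$study$samples, b$study$samples)
})

test_that("generator rejects invalid dispersion and lane scales by name", {
  expect_error(planted_effects(dispersion = -1), "dispersion")
  expect_error(planted_effects(lane_scales = c(1, 0)), "lane_scales")
  expect_error(planted_effects(n_housekeeping = 1), "n_housekeeping")
})

test_that("housekeeping genes carry no group differences", {
  # lane-scaled, dispersed study: housekeeping cell means must agree up to
  # Monte-Carlo error once lane effects are normalized out
  fix <- noisy_study(seed = 7, n_genes = 40)
  expr <- log_transform(normalize_counts(fix$study$counts), pseudocount = 0)
  hk <- fix$effects$housekeeping
  hfd <- fix$study$samples$diet == "HFD"
  diffs <- rowMeans(unclass(expr)[hk, hfd]) - rowMeans(unclass(expr)[hk, !hfd])
  # per-gene contrast sd ~ sqrt(2 * (d + 1/mu) / 36)
  tol <- 4 * sqrt(2 * (0.05 + 1 / 500) / 36)
  expect_true(all(abs(diffs) < tol))
})

test_that("planted interaction coefficient is recovered by cell-mean arithmetic", {
  # Monte-Carlo over simulated studies: the (diet x Plcg2) log cell-mean
  # contrast estimates the planted interaction of 1.0
  n_rep <- 300
  eff <- planted_effects(n_genes = 4, n_housekeeping = 2,
                         planted = list("HFD*Plcg2.M28L" = c(Gm0001 = 1.0)),
                         dispersion = 0.05)
  design <- study_design(n_per_cell = 6)
  grp <- interaction(design$diet, design$genotype)
  contrasts <- vapply(seq_len(n_rep), function(i) {
    st <- generate_study(design, eff, seed = 5000 + i)
    lc <- log(st$counts$counts["Gm0001", ])
    m <- tapply(lc, grp, mean)
    (m[["HFD.LOAD1.Plcg2"]] - m[["CD.LOAD1.Plcg2"]]) -
      (m[["HFD.LOAD1"]] - m[["CD.LOAD1"]])
  }, 0)
  mc_err <- 3 * stats::sd(contrasts) / sqrt(n_rep)
  expect_lt(abs(mean(contrasts) - 1.0), mc_err + 0.01)
})

test_that("reference generator plants exact, null, and intermediate correlations", {
  eff <- planted_effects(n_genes = 100, n_housekeeping = 5,
                         planted = list("HFD" = stats::rnorm(100, 0, 0.3)))

  # degenerate planting: rho = 1 with no noise is exactly proportional
  spec1 <- data.frame(module = "M", cluster = "B", region = "DLPFC",
                      term = "HFD", n_genes = 30, rho = 1)
  ref1 <- generate_human_reference(eff, spec1, seed = 1)
  b <- eff$beta[match(ref1$gene, toupper(rownames(eff$beta))), "HFD"]
  expect_equal(unname(stats::cor(ref1$log2fc, b)), 1, tolerance = 1e-12)

  # null Monte-Carlo: mean correlation of rho = 0 modules is centred on 0
  n_mod <- 400; n_genes <- 25
  spec0 <- data.frame(module = sprintf("M%03d", 1:n_mod), cluster = "C",
                      region = "TCX", term = "HFD", n_genes = n_genes,
                      rho = 0)
  ref0 <- generate_human_reference(eff, spec0, seed = 2)
  r0 <- vapply(split(ref0, ref0$module), function(m) {
    stats::cor(m$log2fc,
               eff$beta[match(m$gene, toupper(rownames(eff$beta))), "HFD"])
  }, 0)
  expect_lt(abs(mean(r0)), 3 / sqrt(n_genes * n_mod))

  # Fisher-z oracle: mean sample r of rho = 0.6 modules sits in the 99% band
  n_rep <- 500
  spec6 <- data.frame(module = sprintf("R%03d", 1:n_rep), cluster = "B",
                      region = "PHG", term = "HFD", n_genes = 50, rho = 0.6)
  ref6 <- generate_human_reference(eff, spec6, seed = 3)
  z6 <- vapply(split(ref6, ref6$module), function(m) {
    atanh(stats::cor(m$log2fc,
                     eff$beta[match(m$gene, toupper(rownames(eff$beta))), "HFD"]))
  }, 0)
  band <- 2.576 / sqrt((50 - 3) * n_rep) + 0.6 / (2 * 49)  # se + E[z] bias
  expect_lt(abs(mean(z6) - atanh(0.6)), band)
})

test_that("reference generator validates rho and module size", {
  eff <- planted_effects(n_genes = 10, n_housekeeping = 2)
  bad_rho <- data.frame(module = "M", cluster = "A", region = "FP",
                        term = "HFD", n_genes = 5, rho = 1.5)
  expect_error(generate_human_reference(eff, bad_rho), "rho")
  too_big <- data.frame(module = "M", cluster = "A", region = "FP",
                        term = "HFD", n_genes = 50, rho = 0)
  expect_error(generate_human_reference(eff, too_big), "larger than panel")
})

test_that("VOI generator plants recoverable regional diet effects", {
  subjects <- data.frame(subject = sprintf("V%03d", 1:80),
                         sex = "F", diet = rep(c("CD", "HFD"), each = 40),
                         genotype = "LOAD1", stringsAsFactors = FALSE)
  regions <- c("cerebellum", "hippocampus", "thalamus")

  # null: no planted effect, group mean SUVRs agree within MC error
  voi0 <- generate_voi_dataset(subjects, regions, cv = 0.05, seed = 21)
  suvr0 <- compute_suvr(average_bilateral(voi0))
  hip0 <- suvr0[suvr0$region == "hippocampus", ]
  ratio0 <- mean(hip0$suvr[hip0$diet == "HFD"]) /
    mean(hip0$suvr[hip0$diet == "CD"])
  expect_lt(abs(ratio0 - 1), 0.05)

  # planted x1.5: the downstream HFD/CD SUVR ratio recovers it
  pl <- data.frame(region = "hippocampus", factor = "diet", level = "HFD",
                   effect = 1.5, stringsAsFactors = FALSE)
  voi1 <- generate_voi_dataset(subjects, regions, planted = pl, cv = 0.05,
                               seed = 22)
  suvr1 <- compute_suvr(average_bilateral(voi1))
  hip1 <- suvr1[suvr1$region == "hippocampus", ]
  ratio1 <- mean(hip1$suvr[hip1$diet == "HFD"]) /
    mean(hip1$suvr[hip1$diet == "CD"])
  expect_lt(abs(ratio1 - 1.5), 0.08)

  # reproducibility and reference validation
  expect_identical(voi1,
                   generate_voi_dataset(subjects, regions, planted = pl,
                                        cv = 0.05, seed = 22))
  expect_error(generate_voi_dataset(subjects, c("hippocampus", "thalamus")),
               "cerebellum")
})

test_that("cytokine generator hits the requested below-LLOD fraction", {
  groups <- data.frame(sex = "F", diet = "CD", genotype = "LOAD1")
  llods <- c(IL1b = 0.11, TNFa = 0.13)

  none <- generate_cytokine_table(groups, llods, n_per_group = 20,
                                  frac_below_llod = 0, seed = 1)
  expect_false(any(none$below_llod))
  all_f <- generate_cytokine_table(groups, llods, n_per_group = 20,
                                   frac_below_llod = 1, seed = 1)
  expect_true(all(all_f$below_llod))

  big <- generate_cytokine_table(groups, llods, n_per_group = 5000,
                                 frac_below_llod = 0.3, seed = 2)
  expect_equal(mean(big$below_llod), 0.3, tolerance = 0.02 / 0.3)
  expect_true(all(big$value[big$below_llod] < big$llod[big$below_llod]))
})
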