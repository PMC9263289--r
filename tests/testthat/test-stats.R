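# Half-LLOD imputation, two-way ANOVA, Tukey HSD, repeated-measures ANOVA.

test_that("below-LLOD values are replaced with half the LLOD, idempotently", {
  tbl <- data.frame(value = c(5, 0.01, 3, 0.02),
                    below_llod = c(FALSE, TRUE, FALSE, TRUE),
                    llod = c(2, 2, 4, 4))
  out <- suppressMessages(impute_llod(tbl))
  expect_equal(out$value, c(5, 1, 3, 2))
  expect_equal(attr(out, "n_imputed"), 2L)
  # unflagged tables pass through unchanged; the operation is idempotent
  clean <- tbl; clean$below_llod <- FALSE
  expect_equal(suppressMessages(impute_llod(clean))$value, clean$value)
  expect_equal(suppressMessages(impute_llod(out))$value, out$value)
  # all-flagged table
  allf <- tbl; allf$below_llod <- TRUE; allf$llod <- 4
  expect_true(all(suppressMessages(impute_llod(allf))$value == 2))
  # flagged record without an LLOD is an error
  bad <- tbl; bad$llod[2] <- NA
  expect_error(suppressMessages(impute_llod(bad)), "LLOD")
})

test_that("two-way ANOVA matches the balanced cell-means oracle", {
  set.seed(89)
  n <- 5
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                   rep = seq_len(n), stringsAsFactors = FALSE)
  d$y <- stats::rnorm(nrow(d))
  res <- anova_two_way(d$y, d$A, d$B)

  # independent cell-means algebra for the balanced 2x2
  cell <- tapply(d$y, list(d$A, d$B), mean)
  grand <- mean(d$y)
  am <- rowMeans(cell); bm <- colMeans(cell)
  ss_a <- 2 * n * sum((am - grand)^2)
  ss_b <- 2 * n * sum((bm - grand)^2)
  ss_ab <- n * sum((sweep(sweep(cell, 1, am), 2, bm) + grand)^2)
  ss_res <- sum((d$y - cell[cbind(d$A, d$B)])^2)
  expect_equal(res$sumsq[res$term == "A"], ss_a, tolerance = 1e-9)
  expect_equal(res$sumsq[res$term == "B"], ss_b, tolerance = 1e-9)
  expect_equal(res$sumsq[res$term == "A:B"], ss_ab, tolerance = 1e-9)
  expect_equal(res$sumsq[res$term == "Residuals"], ss_res, tolerance = 1e-9)
  f_a <- (ss_a / 1) / (ss_res / (4 * n - 4))
  expect_equal(res$F[res$term == "A"], f_a, tolerance = 1e-9)

  # balanced decomposition: SS terms add up to the total
  expect_equal(ss_a + ss_b + ss_ab + ss_res, sum((d$y - grand)^2),
               tolerance = 1e-9)
})

test_that("a pure factor-A shift loads on SS_A only", {
  set.seed(97)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                   rep = 1:6, stringsAsFactors = FALSE)
  d$y <- stats::rnorm(nrow(d), 0, 1e-3) + ifelse(d$A == "a2", 10, 0)
  res <- anova_two_way(d$y, d$A, d$B)
  expect_gt(res$sumsq[res$term == "A"], 100)
  expect_lt(res$sumsq[res$term == "B"], 1e-3)
  expect_lt(res$p[res$term == "A"], 1e-10)
})

test_that("ANOVA F statistics are invariant to affine response maps", {
  set.seed(101)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                   rep = 1:4, stringsAsFactors = FALSE)
  d$y <- stats::rnorm(nrow(d))
  r1 <- anova_two_way(d$y, d$A, d$B)
  r2 <- anova_two_way(3 * d$y - 7, d$A, d$B)
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})

test_that("empty cells drop the interaction (or error when strict)", {
  d <- data.frame(A = c("a1", "a1", "a2", "a2", "a1", "a1"),
                  B = c("b1", "b1", "b1", "b1", "b2", "b2"),
                  y = stats::rnorm(6))
  expect_warning(res <- anova_two_way(d$y, d$A, d$B), "interaction dropped")
  expect_false("A:B" %in% res$term)
  expect_error(anova_two_way(d$y, d$A, d$B, strict = TRUE), "empty")
})

test_that("Tukey with two groups equals the pooled t-test", {
  set.seed(103)
  y <- c(stats::rnorm(8, 0), stats::rnorm(8, 0.7))
  g <- rep(c("g1", "g2"), each = 8)
  th <- tukey_hsd(y, g)
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(th$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(th$q, sqrt(2) * abs(unname(tt$statistic)), tolerance = 1e-9)
  expect_error(tukey_hsd(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("Tukey adjusted p-values are conservative relative to raw pairwise t", {
  set.seed(107)
  y <- stats::rnorm(24)
  g <- rep(c("g1", "g2", "g3"), each = 8)
  th <- tukey_hsd(y, g)
  fit <- stats::aov(y ~ factor(g))
  mse <- stats::deviance(fit) / fit$df.residual
  for (i in seq_len(nrow(th))) {
    pr <- strsplit(th$pair[i], "-")[[1]]
    diff <- mean(y[g == pr[1]]) - mean(y[g == pr[2]])
    t <- diff / sqrt(mse * (2 / 8))
    p_raw <- 2 * stats::pt(abs(t), fit$df.residual, lower.tail = FALSE)
    expect_gte(th$p_adj[i] + 1e-12, p_raw)
  }
})

test_that("repeated-measures ANOVA reduces to two-way at one timepoint", {
  set.seed(109)
  d <- expand.grid(subject = sprintf("m%02d", 1:20), month = 4,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$diet <- rep(c("CD", "HFD"), each = 10)[match(d$subject,
                                                 sprintf("m%02d", 1:20))]
  d$sex <- rep(c("F", "M"), 10)[match(d$subject, sprintf("m%02d", 1:20))]
  d$weight <- stats::rnorm(nrow(d), 30, 2)
  expect_message(
    res <- rm_anova(d, "weight", "subject", "month", c("diet", "sex")),
    "single timepoint")
  ref <- anova_two_way(d$weight, d$diet, d$sex, names = c("diet", "sex"))
  expect_equal(res$F[match(ref$term, res$term)], ref$F, tolerance = 1e-10)
})

test_that("a planted diet-dependent weight-gain slope is detected", {
  # split-plot power check mirroring a longitudinal body-weight design
  hits <- vapply(1:40, function(i) {
    set.seed(300 + i)
    months <- seq(2, 12, by = 2)
    subj <- sprintf("m%02d", 1:16)
    diet <- rep(c("CD", "HFD"), each = 8)
    d <- expand.grid(subject = subj, month = months,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d$diet <- diet[match(d$subject, subj)]
    base <- stats::rnorm(16, 25, 1.5)[match(d$subject, subj)]
    slope <- ifelse(d$diet == "HFD", 1.4, 0.7)
    d$weight <- base + slope * (d$month - 2) + stats::rnorm(nrow(d), 0, 1)
    res <- rm_anova(d, "weight", "subject", "month", "diet")
    p_int <- res$p[res$term == "diet:month"]
    !is.na(p_int) && p_int < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("incomplete subjects are dropped with a warning", {
  d <- expand.grid(subject = sprintf("m%d", 1:6), month = c(4, 8),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$diet <- rep(c("CD", "HFD"), 6)[match(d$subject, sprintf("m%d", 1:6))]
  d$weight <- stats::rnorm(nrow(d), 30, 1)
  d <- d[!(d$subject == "m1" & d$month == 8), ]
  expect_warning(res <- rm_anova(d, "weight", "subject", "month", "diet"),
                 "incomplete")
  expect_true(all(c("diet", "month", "diet:month") %in% res$term))
})
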