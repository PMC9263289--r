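# Univariate study statistics: half-LLOD imputation, two-way ANOVA
# (Type II sums of squares), Tukey HSD, and split-plot repeated-measures
# ANOVA.

#' Replace below-LLOD measurements with half the LLOD
#'
#' Records flagged `below_llod` have their value set to `llod / 2`;
#' unflagged records are untouched. The operation is idempotent.
#'
#' @param tbl Measurement table with columns `value`, `below_llod`, `llod`.
#' @return The table with imputed values; the number of imputed records is
#'   in the `"n_imputed"` attribute and reported via `message()`.
#' @export
impute_llod <- function(tbl) {
  req <- c("value", "below_llod", "llod")
  miss <- setdiff(req, names(tbl))
  if (length(miss))
    stop("measurement table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  flag <- which(tbl$below_llod)
  if (any(is.na(tbl$llod[flag])) || any(tbl$llod[flag] <= 0))
    stop("flagged record(s) without a positive LLOD", call. = FALSE)
  tbl$value[flag] <- tbl$llod[flag] / 2
  message(sprintf("imputed %d below-LLOD value(s) as LLOD/2", length(flag)))
  structure(tbl, n_imputed = length(flag))
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Fits `value ~ A * B` and reports Type II sums of squares (which coincide
#' with the textbook decomposition in balanced designs). If any factor cell
#' is empty, the interaction cannot be estimated: it is dropped with a
#' warning (additive model) unless `strict = TRUE`, in which case this is
#' an error.
#'
#' @param values Numeric response.
#' @param a,b Factors (coerced).
#' @param names Labels used for the two factors in the output.
#' @param strict Error on empty cells instead of dropping the interaction.
#' @return Data frame: `term`, `sumsq`, `df`, `F`, `p` (residual row has
#'   NA for `F`/`p`).
#' @export
anova_two_way <- function(values, a, b, names = c("A", "B"),
                          strict = FALSE) {
  a <- factor(a); b <- factor(b)
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("each factor needs at least 2 levels", call. = FALSE)
  cells <- table(a, b)
  has_empty <- any(cells == 0)
  if (has_empty && strict)
    stop("empty factor cell(s); cannot fit the interaction", call. = FALSE)
  d <- data.frame(y = values, A = a, B = b)
  form <- if (has_empty) y ~ A + B else y ~ A * B
  if (has_empty)
    warning("empty factor cell(s): interaction dropped (additive model)",
            call. = FALSE)
  fit <- stats::lm(form, data = d)
  if (fit$df.residual < 1)
    stop("no residual degrees of freedom", call. = FALSE)
  aod <- car::Anova(fit, type = 2)
  tab <- as.data.frame(aod)
  lab <- rownames(tab)
  lab[lab == "A"] <- names[1]
  lab[lab == "B"] <- names[2]
  lab[lab == "A:B"] <- paste(names, collapse = ":")
  out <- data.frame(term = lab, sumsq = tab[["Sum Sq"]], df = tab[["Df"]],
                    F = tab[["F value"]], p = tab[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise group comparisons using the studentized-range distribution
#' with the pooled mean squared error (Tukey-Kramer for unequal group
#' sizes).
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, each with >= 2 observations).
#' @param alpha Significance level for the `significant` flag.
#' @param conf_level Confidence level of the simultaneous intervals.
#' @return Data frame: `pair`, `diff`, `lwr`, `upr`, `q`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05, conf_level = 0.95) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  n_by <- table(g)
  if (any(n_by < 2))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(n_by)[n_by < 2], collapse = ", "), call. = FALSE)
  fit <- stats::aov(values ~ g)
  th <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  mse <- stats::deviance(fit) / fit$df.residual

  pairs <- strsplit(rownames(th), "-", fixed = TRUE)
  q <- vapply(seq_len(nrow(th)), function(i) {
    ni <- n_by[pairs[[i]][1]]; nj <- n_by[pairs[[i]][2]]
    abs(th[i, "diff"]) / sqrt(mse / 2 * (1 / ni + 1 / nj))
  }, 0)
  out <- data.frame(pair = rownames(th), diff = th[, "diff"],
                    lwr = th[, "lwr"], upr = th[, "upr"], q = q,
                    p_adj = th[, "p adj"],
                    significant = th[, "p adj"] < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Split-plot repeated-measures ANOVA
#'
#' Univariate mixed (split-plot) ANOVA: between-subject effects are tested
#' against the subject-within-group mean square, within-subject effects and
#' their interactions with between factors against the subject x time
#' residual. Subjects with incomplete within-subject series are dropped
#' with a warning. With a single timepoint the model reduces to an ordinary
#' ANOVA (a notice is emitted).
#'
#' @param data Data frame in long format.
#' @param value Name of the response column.
#' @param subject Name of the subject ID column.
#' @param within Name of the within-subject factor column (e.g. timepoint).
#' @param between Character vector (1 or 2) of between-subject factor
#'   columns.
#' @return Data frame: `stratum`, `term`, `df`, `sumsq`, `F`, `p`.
#' @export
rm_anova <- function(data, value, subject, within, between) {
  for (col in c(value, subject, within, between))
    if (!col %in% names(data))
      stop(sprintf("column '%s' not in data", col), call. = FALSE)
  if (!length(between) %in% 1:2)
    stop_bad_arg("between", "must name 1 or 2 factor columns")

  tp <- unique(data[[within]])
  n_tp <- tapply(data[[within]], data[[subject]],
                 function(x) length(unique(x)))
  complete <- names(n_tp)[n_tp == length(tp)]
  if (length(complete) < length(n_tp)) {
    warning(sprintf("dropping %d subject(s) with incomplete series",
                    length(n_tp) - length(complete)), call. = FALSE)
    data <- data[data[[subject]] %in% complete, ]
  }

  if (length(tp) == 1) {
    message("single timepoint: reducing to a between-subjects ANOVA")
    if (length(between) == 2)
      return(cbind(stratum = "between",
                   anova_two_way(data[[value]], data[[between[1]]],
                                 data[[between[2]]], names = between)))
    fit <- stats::lm(data[[value]] ~ factor(data[[between]]))
    a <- stats::anova(fit)
    return(data.frame(stratum = "between",
                      term = c(between, "Residuals"),
                      df = a$Df, sumsq = a$`Sum Sq`, F = a$`F value`,
                      p = a$`Pr(>F)`, stringsAsFactors = FALSE))
  }

  d <- data.frame(y = data[[value]],
                  subj = factor(data[[subject]]),
                  w = factor(data[[within]]))
  for (i in seq_along(between)) d[[paste0("b", i)]] <- factor(data[[between[i]]])
  btm <- paste(paste0("b", seq_along(between)), collapse = " * ")
  form <- stats::as.formula(sprintf("y ~ (%s) * w + Error(subj)", btm))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)

  rows <- list()
  for (stratum in names(sm)) {
    tab <- as.data.frame(sm[[stratum]][[1]])
    term <- trimws(rownames(tab))
    for (i in seq_along(between)) {
      term <- gsub(paste0("\\bb", i, "\\b"), between[i], term)
    }
    term <- gsub("\\bw\\b", within, term)
    rows[[stratum]] <- data.frame(
      stratum = gsub("^Error: ", "", stratum), term = term,
      df = tab$Df, sumsq = tab$`Sum Sq`,
      F = if ("F value" %in% names(tab)) tab$`F value` else NA_real_,
      p = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)` else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
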