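## Per-protein, per-treatment differential statistics on relative abundances:
## pooled-variance Student t-test, post-hoc power via the noncentral t
## distribution, fold-change gating, correlation of treatment profiles, and
## export shaping for heat maps and volcano plots.
##
## Tests run on ratios on the natural scale (not log), matching spreadsheet
## practice with ratio-valued thresholds such as 1.15 and 0.85/0.8.

#' Significance thresholds for differential gating
#'
#' Bundles the gates used downstream: the t-test level `alpha`, the type-II
#' rate `beta` (power cutoff is `1 - beta`), the fold-change mode and the
#' p-value cutoff. `fc_mode = "symmetric015"` flags ratios above 1.15 or
#' below 0.85 (a symmetric 0.15-fold change); `fc_mode = "ipa"` uses the
#' asymmetric bounds above 1.15 or below 0.8.
#'
#' @param alpha Significance level of the t-test (default 0.05).
#' @param beta Accepted type-II error rate; power gate is `power > 1 - beta`
#'   (default 0.2, i.e. power > 0.8).
#' @param fc_mode `"symmetric015"` or `"ipa"`.
#' @param p_cutoff p-value gate (default 0.05).
#' @return A `de_thresholds` list with the resolved `fc_lower`/`fc_upper`.
#' @export
de_thresholds <- function(alpha = 0.05, beta = 0.2,
                          fc_mode = c("symmetric015", "ipa"),
                          p_cutoff = 0.05) {
  fc_mode <- match.arg(fc_mode)
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1,
            p_cutoff > 0, p_cutoff <= 1)
  bounds <- switch(fc_mode,
                   symmetric015 = c(lower = 0.85, upper = 1.15),
                   ipa = c(lower = 0.80, upper = 1.15))
  structure(list(alpha = alpha, beta = beta, power_cutoff = 1 - beta,
                 fc_mode = fc_mode, fc_lower = unname(bounds["lower"]),
                 fc_upper = unname(bounds["upper"]), p_cutoff = p_cutoff),
            class = "de_thresholds")
}

#' Two-sample pooled-variance (Student) t-test
#'
#' Two-sided test with the classical pooled variance and
#' `df = length(x) + length(y) - 2`. Degenerate zero-variance input is
#' resolved rather than erroring: equal means give p = 1, unequal means give
#' the p = 0 boundary (flagged via the `zero_variance` field).
#'
#' @param x,y Numeric vectors of replicate relative abundances, each of
#'   length >= 2, all finite.
#' @return List with `statistic`, `df`, `p_value`, `zero_variance`.
#' @export
student_ttest <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * stats::var(x) + (n2 - 1L) * stats::var(y)) / df
  if (sp2 <= 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(statistic = 0, df = df, p_value = 1, zero_variance = TRUE))
    }
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, df = df,
                p_value = 0, zero_variance = TRUE))
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       zero_variance = FALSE)
}

#' Power of the two-sided two-sample t-test at a given effect size
#'
#' Computed from the noncentral t distribution: with noncentrality
#' `ncp = d * sqrt(n1 * n2 / (n1 + n2))` and critical value
#' `t_crit = qt(1 - alpha/2, df)`, power is `P(|T| > t_crit)`. At `d = 0`
#' this equals `alpha` exactly (the size of the test).
#'
#' @param d Cohen's d effect size(s); vectorized.
#' @param n1,n2 Group sizes.
#' @param alpha Test level.
#' @return Power value(s) in `[0, 1]`.
#' @export
t_test_power <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(n1 >= 2L, n2 >= 2L, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2L
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
}

#' Post-hoc power of an observed two-sample comparison
#'
#' Power of the two-sided Student t-test at level `alpha` for the observed
#' effect size `d = |mean(x) - mean(y)| / pooled sd` (Cohen's d) at the
#' realized group sizes. Used as a significance gate (`power > 0.8`
#' corresponds to a type-II rate below 0.2 at the observed effect).
#' With zero pooled variance, power is defined as 1 when the means differ
#' and `alpha` when they are equal.
#'
#' @inheritParams student_ttest
#' @param alpha Test level.
#' @return Scalar power in `[0, 1]`.
#' @export
posthoc_power <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1L) * stats::var(x) + (n2 - 1L) * stats::var(y)) / (n1 + n2 - 2L)
  if (sp2 <= 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) alpha else 1)
  }
  d <- abs(mean(x) - mean(y)) / sqrt(sp2)
  t_test_power(d, n1, n2, alpha)
}

## Row-wise pooled t across matrices (one row per protein). Returns the same
## quantities as the scalar functions; kept internal so the scalar operations
## remain the single documented definition.
.row_student <- function(xm, ym, alpha) {
  n1 <- ncol(xm); n2 <- ncol(ym)
  df <- n1 + n2 - 2L
  mx <- rowMeans(xm); my <- rowMeans(ym)
  vx <- rowSums((xm - mx)^2) / (n1 - 1L)
  vy <- rowSums((ym - my)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * vx + (n2 - 1L) * vy) / df
  zero <- sp2 <= 0
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mx - my) / se
  p <- 2 * stats::pt(-abs(t), df)
  d <- abs(mx - my) / sqrt(sp2)
  power <- t_test_power(ifelse(zero, 0, d), n1, n2, alpha)
  if (any(zero)) {
    eq <- zero & abs(mx - my) < .Machine$double.eps^0.5 * pmax(abs(mx), 1)
    t[zero] <- ifelse(eq[zero], 0, sign(mx - my)[zero] * Inf)
    p[zero] <- ifelse(eq[zero], 1, 0)
    power[zero] <- ifelse(eq[zero], alpha, 1)
  }
  list(t = t, df = df, p = p, power = power, zero_variance = zero)
}

#' Differential-expression table: one record per protein and treatment
#'
#' For every non-control group, computes the ratio of treatment to control
#' (mean of treatment replicate relative abundances over mean of control
#' replicate relative abundances), the pooled-variance Student t-test
#' p-value, the post-hoc power at the observed effect size, and the three
#' gate flags: `pass_power` (power > 1 - beta), `pass_p` (p < p_cutoff) and
#' `pass_fc` (ratio outside the fold-change bounds). Proteins with zero
#' pooled variance in a comparison are flagged `zero_variance` and fail all
#' gates rather than erroring.
#'
#' @param merged A merged `rel_abundance` from [merge_common()].
#' @param control Name of the control group (e.g. `"DMSO"`).
#' @param thresholds A [de_thresholds()] object.
#' @return Data frame with columns `accession`, `treatment`, `ratio`,
#'   `p_value`, `power`, `pass_power`, `pass_p`, `pass_fc`, `direction`,
#'   `zero_variance`.
#' @export
differential_table <- function(merged, control = "DMSO",
                               thresholds = de_thresholds()) {
  groups <- merged$samples$group
  if (!control %in% groups) {
    stop("control group '", control, "' not present", call. = FALSE)
  }
  treatments <- setdiff(unique(groups), control)
  for (g in c(control, treatments)) {
    if (sum(groups == g) < 2L) {
      stop("group '", g, "' has fewer than 2 replicates", call. = FALSE)
    }
  }
  ym <- merged$values[, groups == control, drop = FALSE]
  my <- rowMeans(ym)
  out <- lapply(treatments, function(g) {
    xm <- merged$values[, groups == g, drop = FALSE]
    st <- .row_student(xm, ym, thresholds$alpha)
    ratio <- rowMeans(xm) / my
    pass_fc <- ratio > thresholds$fc_upper | ratio < thresholds$fc_lower
    data.frame(
      accession = merged$accessions, treatment = g, ratio = ratio,
      p_value = st$p, power = st$power,
      pass_power = !st$zero_variance & st$power > thresholds$power_cutoff,
      pass_p = !st$zero_variance & st$p < thresholds$p_cutoff,
      pass_fc = pass_fc,
      direction = ifelse(ratio > 1, "up", ifelse(ratio < 1, "down", "none")),
      zero_variance = st$zero_variance,
      stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Select significantly changed proteins per treatment
#'
#' Applies one of the named gates to a [differential_table()] result and
#' returns the per-treatment accession sets. `"p_fc"` (p-value plus
#' fold-change) reproduces the protein-count filter; `"power"` alone is the
#' gate used for pathway statistics; `"power_fc"` crosses power with
#' fold-change as in enrichment uploads.
#'
#' @param diff A data frame from [differential_table()].
#' @param gate One of `"p"`, `"power"`, `"p_fc"`, `"power_fc"`.
#' @return Named list of character vectors (one per treatment), with the
#'   union of all treatments as attribute `union`.
#' @export
changed_sets <- function(diff, gate = c("p_fc", "power", "power_fc", "p")) {
  gate <- match.arg(gate)
  keep <- switch(gate,
                 p = diff$pass_p,
                 power = diff$pass_power,
                 p_fc = diff$pass_p & diff$pass_fc,
                 power_fc = diff$pass_power & diff$pass_fc)
  sets <- lapply(split(diff$accession[keep], diff$treatment[keep]), unique)
  all_t <- unique(diff$treatment)
  sets <- setNames(lapply(all_t, function(g) sets[[g]] %||% character(0L)), all_t)
  attr(sets, "union") <- unique(unlist(sets))
  sets
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation between two treatments' ratio profiles
#'
#' Correlates the treatment/control ratio vectors of two treatments over a
#' protein subset (e.g. the significantly changed mitochondrial proteins).
#'
#' @param diff A data frame from [differential_table()].
#' @param proteins Character vector of accessions (>= 3).
#' @param a,b Treatment group names.
#' @return Pearson R (scalar); `NA` if either vector has zero variance.
#' @export
treatment_correlation <- function(diff, proteins, a, b) {
  proteins <- unique(proteins)
  if (length(proteins) < 3L) {
    stop("correlation needs at least 3 proteins", call. = FALSE)
  }
  get_ratios <- function(g) {
    sub <- diff[diff$treatment == g, , drop = FALSE]
    i <- match(proteins, sub$accession)
    if (anyNA(i)) stop("treatment '", g, "' missing ratios for some proteins",
                       call. = FALSE)
    sub$ratio[i]
  }
  va <- get_ratios(a); vb <- get_ratios(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero variance in a ratio vector; correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' Pairwise treatment correlation matrix
#'
#' @inheritParams treatment_correlation
#' @return Long data frame with `group_a`, `group_b`, `r`, `n_proteins` for
#'   every unordered treatment pair.
#' @export
correlation_matrix <- function(diff, proteins) {
  treatments <- unique(diff$treatment)
  pairs <- utils::combn(treatments, 2L)
  data.frame(
    group_a = pairs[1L, ], group_b = pairs[2L, ],
    r = apply(pairs, 2L, function(p)
      treatment_correlation(diff, proteins, p[1L], p[2L])),
    n_proteins = length(unique(proteins)),
    stringsAsFactors = FALSE)
}

#' Row-maximum scaling for heat-map display
#'
#' Divides each protein's relative abundances by its maximum across all
#' samples, so the sample with the highest expression is exactly 1 and all
#' values lie in (0, 1].
#'
#' @param merged A merged `rel_abundance`.
#' @param proteins Optional accession subset (default: all proteins).
#' @return Matrix of scaled values.
#' @export
heatmap_scale <- function(merged, proteins = NULL) {
  m <- merged$values
  if (!is.null(proteins)) {
    i <- match(unique(proteins), merged$accessions)
    if (anyNA(i)) stop("subset contains proteins absent from the matrix",
                       call. = FALSE)
    m <- m[i, , drop = FALSE]
  }
  m / apply(m, 1L, max)
}

#' Volcano-plot table
#'
#' Restricts differential records to those passing `p < p_cutoff` and a
#' minimum absolute change (`ratio > 1 + fc_floor` or `< 1 - fc_floor`), and
#' adds `log2_ratio` and `neg_log10_p` for plotting. The conventional
#' significance line sits at `-log10(0.05) ~ 1.30`.
#'
#' @param diff A data frame from [differential_table()].
#' @param fc_floor Minimum absolute fold change (e.g. 0.15, or 0.5 for a
#'   top-hits view).
#' @param p_cutoff p-value cutoff (default 0.05).
#' @return Data frame with `accession`, `treatment`, `ratio`, `log2_ratio`,
#'   `neg_log10_p`.
#' @export
volcano_table <- function(diff, fc_floor = 0.15, p_cutoff = 0.05) {
  stopifnot(fc_floor > 0)
  keep <- diff$p_value < p_cutoff &
    (diff$ratio > 1 + fc_floor | diff$ratio < 1 - fc_floor)
  sub <- diff[keep, c("accession", "treatment", "ratio", "p_value"),
              drop = FALSE]
  data.frame(accession = sub$accession, treatment = sub$treatment,
             ratio = sub$ratio, log2_ratio = log2(sub$ratio),
             neg_log10_p = -log10(sub$p_value),
             stringsAsFactors = FALSE, row.names = NULL)
}
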