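test_that("pooled-variance t-test matches hand computation and stats::t.test", {
  # identical groups: t = 0, p = 1
  same <- student_ttest(c(1.0, 1.1, 0.9), c(1.0, 1.1, 0.9))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  # hand computation: pooled sd = 1, se = sqrt(2/3), t = -1.2247, df = 4
  st <- student_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(st$statistic, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_identical(st$df, 4L)
  expect_equal(st$p_value, 0.2878641, tolerance = 1e-6)

  # agreement with the reference implementation on random input
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(sample(2:6, 1L)); y <- rnorm(sample(2:6, 1L), mean = runif(1L))
    ref <- t.test(x, y, var.equal = TRUE)
    mine <- student_ttest(x, y)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("t-test handles zero variance and obeys symmetry invariances", {
  expect_identical(student_ttest(c(1, 1), c(1, 1))$p_value, 1)
  degenerate <- student_ttest(c(2, 2), c(1, 1))
  expect_identical(degenerate$p_value, 0)
  expect_true(degenerate$zero_variance)

  set.seed(12)
  x <- rnorm(4L); y <- rnorm(3L, 0.5)
  # exchanging the groups and shifting both leaves p unchanged
  expect_equal(student_ttest(x, y)$p_value, student_ttest(y, x)$p_value)
  expect_equal(student_ttest(x + 7, y + 7)$p_value,
               student_ttest(x, y)$p_value, tolerance = 1e-9)
})

test_that("null t-test p-values reject at the nominal rate", {
  set.seed(13)
  B <- 10000L
  x <- matrix(rlnorm(3L * B, 0, 0.05), nrow = 3L)
  y <- matrix(rlnorm(3L * B, 0, 0.05), nrow = 3L)
  p <- vapply(seq_len(B), function(i)
    student_ttest(x[, i], y[, i])$p_value, numeric(1L))
  # binomial 99.9% band around 0.05 at B = 10,000: about +/- 0.0072
  expect_gt(mean(p < 0.05), 0.05 - 0.008)
  expect_lt(mean(p < 0.05), 0.05 + 0.008)
})

test_that("noncentral-t power is exact at d = 0 and saturates at large d", {
  expect_equal(t_test_power(0, 3L, 3L, alpha = 0.05), 0.05, tolerance = 1e-12)
  expect_equal(t_test_power(0, 5L, 8L, alpha = 0.10), 0.10, tolerance = 1e-12)
  expect_gt(t_test_power(10, 3L, 3L), 0.999)
})

test_that("power is monotone in effect size and replicate count", {
  d_grid <- c(0, 0.25, 0.5, 1, 2, 4, 8)
  for (n in c(3L, 5L, 10L)) {
    p <- t_test_power(d_grid, n, n)
    expect_true(all(diff(p) > 0))
  }
  for (d in c(0.5, 1, 2)) {
    p <- vapply(c(3L, 5L, 10L, 20L), function(n)
      t_test_power(d, n, n), numeric(1L))
    expect_true(all(diff(p) > 0))
  }
  # decreasing in pooled sd: d = delta / sd
  expect_true(all(diff(t_test_power(1 / c(0.5, 1, 2, 4), 3L, 3L)) < 0))
})

test_that("power agrees with stats::power.t.test across a grid", {
  for (d in c(0.2, 0.5, 1, 2, 4)) {
    for (n in c(3L, 5L, 10L)) {
      ref <- stats::power.t.test(n = n, delta = d, sd = 1,
                                 sig.level = 0.05, strict = TRUE)$power
      expect_equal(t_test_power(d, n, n), ref, tolerance = 1e-6)
    }
  }
})

test_that("post-hoc power uses the observed effect and handles degeneracy", {
  x <- c(1.0, 1.2, 1.1); y <- c(0.8, 0.9, 0.85)
  sp <- sqrt((2 * var(x) + 2 * var(y)) / 4)
  d <- abs(mean(x) - mean(y)) / sp
  expect_equal(posthoc_power(x, y), t_test_power(d, 3L, 3L))
  expect_identical(posthoc_power(c(1, 1), c(1, 1)), 0.05)
  expect_identical(posthoc_power(c(2, 2), c(1, 1)), 1)
})

test_that("differential table recovers planted effects on a calibrated plex", {
  # single-plex layout: the pooled-reference factor is common to both groups
  # of every comparison, so the t-test runs at its nominal level
  design <- singleplex_design()
  truth <- generate_truth(n_proteins = 1000L, n_pathways = 10L,
                          frac_de = 0.10, effect_range = c(1.5, 1.5),
                          noise_sigma = 0.05, plex_scale = 1, dropout = 0,
                          seed = 915L)
  tab <- simulate_plexes(truth, list(design))
  merged <- merge_common(list(relative_abundance(tab[[1L]], design)))
  diff <- differential_table(merged, "DMSO")
  sets <- changed_sets(diff, "p_fc")
  for (g in truth$treatments) {
    de <- truth$de_sets[[g]]
    recall <- mean(de %in% sets[[g]])
    expect_gte(recall, 0.9)
    nulls <- setdiff(merged$accessions, de)
    sub <- diff[diff$treatment == g, ]
    fpr <- mean(sub$pass_p[match(nulls, sub$accession)])
    expect_lte(fpr, 0.07)
  }
  # estimated ratios track true effects
  all_de <- unlist(truth$de_sets)
  est <- diff$ratio[match(paste(all_de, rep(truth$treatments,
                                            lengths(truth$de_sets))),
                          paste(diff$accession, diff$treatment))]
  tru <- mapply(function(a, g) truth$effects[a, g], all_de,
                rep(truth$treatments, lengths(truth$de_sets)))
  expect_gt(cor(est, tru), 0.95)
})

test_that("power and p gates coexist on one table without interference", {
  design <- singleplex_design()
  truth <- generate_truth(n_proteins = 300L, n_pathways = 10L,
                          frac_de = 0.1, noise_sigma = 0.05, plex_scale = 1,
                          dropout = 0, seed = 916L)
  tab <- simulate_plexes(truth, list(design))
  merged <- merge_common(list(relative_abundance(tab[[1L]], design)))
  diff <- differential_table(merged, "DMSO")
  p_sets <- changed_sets(diff, "p_fc")
  pw_sets <- changed_sets(diff, "power")
  expect_identical(changed_sets(diff, "p_fc"), p_sets)  # idempotent
  # the two gates select different (overlapping) sets from the same table
  expect_false(identical(attr(p_sets, "union"), attr(pw_sets, "union")))
  expect_identical(nrow(diff), 300L * 5L)
})

test_that("degenerate and invalid differential inputs are handled", {
  design <- tiny_design()
  mat <- matrix(100, 2L, 6L, dimnames = list(c("P1", "P2"), NULL))
  mat["P2", 1:2] <- c(150, 160)
  merged <- merge_common(list(relative_abundance(
    table_from_matrix(design, mat), design)))
  diff <- differential_table(merged, "DMSO")
  # a protein identical in all groups fails every gate
  p1 <- diff[diff$accession == "P1", ]
  expect_true(p1$zero_variance)
  expect_false(p1$pass_power || p1$pass_p || p1$pass_fc)
  expect_identical(p1$direction, "none")

  expect_error(differential_table(merged, "missing_group"), "not present")
  one_rep <- merged
  one_rep$samples <- merged$samples[-1L, ]
  one_rep$values <- merged$values[, -1L]
  expect_error(differential_table(one_rep, "DMSO"), "TREAT")
})

test_that("treatment correlations match the trivial cases", {
  diff <- data.frame(
    accession = rep(c("A", "B", "C"), 3L),
    treatment = rep(c("t1", "t2", "t3"), each = 3L),
    ratio = c(1, 2, 3, 1, 2, 3, 3, 2, 1),
    stringsAsFactors = FALSE)
  expect_identical(treatment_correlation(diff, c("A", "B", "C"), "t1", "t2"), 1)
  expect_identical(treatment_correlation(diff, c("A", "B", "C"), "t1", "t3"), -1)
  expect_error(treatment_correlation(diff, c("A", "B"), "t1", "t2"),
               "at least 3")
  flat <- diff; flat$ratio[flat$treatment == "t2"] <- 1
  expect_warning(r <- treatment_correlation(flat, c("A", "B", "C"), "t1", "t2"),
                 "zero variance")
  expect_true(is.na(r))

  cm <- correlation_matrix(diff, c("A", "B", "C"))
  expect_identical(nrow(cm), 3L)
  expect_equal(cm$r[cm$group_a == "t1" & cm$group_b == "t2"], 1)
})

test_that("heat-map scaling sets each protein's maximum to exactly 1", {
  design <- tiny_design()
  mat <- matrix(c(2, 100, 4, 100, 8, 100, 6, 100, 4, 100, 4, 100),
                nrow = 2L, dimnames = list(c("P1", "P2"), NULL))
  merged <- merge_common(list(relative_abundance(
    table_from_matrix(design, mat), design)))
  scaled <- heatmap_scale(merged)
  # forced arithmetic on P1: samples (2,4,8,6)/ref 4 -> (.5,1,2,1.5) -> /2
  expect_equal(unname(scaled["P1", ]), c(0.25, 0.5, 1, 0.75))
  # constant rows become all ones
  expect_identical(unname(scaled["P2", ]), rep(1, 4L))
  expect_true(all(apply(scaled, 1L, max) == 1))
  expect_error(heatmap_scale(merged, "absent"), "absent from the matrix")
})

test_that("volcano tables apply the p and change floors", {
  diff <- data.frame(
    accession = c("A", "B", "C", "D"), treatment = "t",
    ratio = c(1.0, 1.3, 0.7, 1.2), p_value = c(0.001, 0.05, 0.01, 0.02),
    stringsAsFactors = FALSE)
  v <- volcano_table(diff, fc_floor = 0.15)
  # ratio exactly 1 is excluded at any positive floor; p = 0.05 fails p < 0.05
  expect_setequal(v$accession, c("C", "D"))
  expect_equal(v$neg_log10_p[v$accession == "C"], 2)
  # p = 0.05 would sit exactly on the -log10 significance line at ~1.301
  expect_equal(-log10(0.05), 1.30103, tolerance = 1e-5)
  # a stricter floor keeps only the strong change
  expect_identical(volcano_table(diff, fc_floor = 0.25)$accession, "C")
})

test_that("a planted strong hit dominates its treatment's volcano", {
  design <- singleplex_design()
  truth <- generate_truth(n_proteins = 200L, n_pathways = 10L, frac_de = 0.05,
                          noise_sigma = 0.05, plex_scale = 1, dropout = 0,
                          seed = 917L)
  strong <- truth$accessions[1L]
  truth$effects[strong, ] <- 1           # reset any sampled effect
  truth$effects[strong, "FCCP"] <- 3     # one huge, low-noise effect
  tab <- simulate_plexes(truth, list(design))
  merged <- merge_common(list(relative_abundance(tab[[1L]], design)))
  diff <- differential_table(merged, "DMSO")
  v <- volcano_table(diff[diff$treatment == "FCCP", ], fc_floor = 0.15)
  expect_identical(v$accession[which.max(v$neg_log10_p)], strong)
})
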