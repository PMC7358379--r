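make_pathway <- function(id, members, source = "test") {
  structure(list(pathway_id = id, source = source, members = members),
            class = "pathway_annotation")
}

test_that("dysregulation percentages and flags follow the defined formulas", {
  # 40 annotated, 10 detected, treatment A changed 4, treatment B changed 2
  detected <- sprintf("D%02d", 1:10)
  pw <- make_pathway("pw1", c(detected, sprintf("U%02d", 1:30)))
  changed <- list(A = detected[1:4], B = detected[1:2])
  dys <- pathway_dysregulation(list(pw), detected, changed)
  expect_equal(dys$percent_coverage, c(25, 25))
  expect_equal(dys$percent_change[dys$treatment == "A"], 40)
  expect_equal(dys$percent_change[dys$treatment == "B"], 20)
  expect_true(dys$flag[dys$treatment == "A"])
  expect_false(dys$flag[dys$treatment == "B"])
  expect_identical(dys$n_annotated, c(40L, 40L))
  expect_identical(dys$n_detected, c(10L, 10L))
})

test_that("percent change equal to coverage flags under ge but not gt", {
  # 4 of 8 annotated detected (coverage 50%), 2 of 4 changed (change 50%)
  detected <- sprintf("D%02d", 1:4)
  pw <- make_pathway("tie", c(detected, sprintf("U%02d", 1:4)))
  changed <- list(A = detected[1:2])
  tie_ge <- pathway_dysregulation(list(pw), detected, changed, tie = "ge")
  tie_gt <- pathway_dysregulation(list(pw), detected, changed, tie = "gt")
  expect_equal(tie_ge$percent_coverage, tie_ge$percent_change)
  expect_true(tie_ge$flag)
  expect_false(tie_gt$flag)
})

test_that("dysregulation ignores member order and undetected members", {
  detected <- sprintf("D%02d", 1:10)
  members <- c(detected[1:6], sprintf("U%02d", 1:6))
  changed <- list(A = detected[1:3])
  base <- pathway_dysregulation(list(make_pathway("pw", members)),
                                detected, changed)
  shuffled <- pathway_dysregulation(
    list(make_pathway("pw", rev(sample(members)))), detected, changed)
  expect_equal(shuffled[, -1L], base[, -1L])
  # adding more never-detected members only dilutes coverage
  extra <- pathway_dysregulation(
    list(make_pathway("pw", c(members, "U99"))), detected, changed)
  expect_lt(extra$percent_coverage, base$percent_coverage)
  expect_equal(extra$percent_change, base$percent_change)
})

test_that("pathways with no detected member report zero coverage, no flag", {
  dys <- pathway_dysregulation(list(make_pathway("gone", c("U1", "U2"))),
                               c("D1", "D2"), list(A = "D1"))
  expect_identical(dys$n_detected, 0L)
  expect_identical(dys$percent_coverage, 0)
  expect_true(is.na(dys$percent_change))
  expect_false(dys$flag)
})

test_that("changed sets outside the detected universe are rejected", {
  expect_error(
    pathway_dysregulation(list(make_pathway("pw", "D1")), "D1",
                          list(A = c("D1", "X1"))),
    "outside the detected universe")
})

test_that("hypergeometric tail matches enumeration by binomial coefficients", {
  bg10 <- sprintf("B%02d", 1:10)
  # k = K = n = 1, N = 10: the one changed protein is the one member
  res <- fisher_enrichment(make_pathway("pw", bg10[1L]), bg10[1L], bg10)
  expect_equal(res$p_value, 1 - choose(9, 1) / choose(10, 1))
  expect_equal(res$p_value, 0.1)
  # k = 0: the right tail at zero is all of the probability
  res0 <- fisher_enrichment(make_pathway("pw", bg10[1L]), bg10[2L], bg10)
  expect_identical(res0$p_value, 1)

  # N = 20, K = 5, n = 5, k = 3 against the enumeration oracle
  bg20 <- sprintf("B%02d", 1:20)
  pw <- make_pathway("pw", bg20[1:5])
  changed <- c(bg20[1:3], bg20[6:7])
  res3 <- fisher_enrichment(pw, changed, bg20)
  oracle <- sum(vapply(3:5, function(i)
    choose(5, i) * choose(15, 5 - i), numeric(1L))) / choose(20, 5)
  expect_equal(res3$p_value, oracle, tolerance = 1e-12)
  expect_equal(res3$p_value, 0.07262642, tolerance = 1e-7)
  expect_identical(sort(res3$overlap), bg20[1:3])
  expect_identical(c(res3$k, res3$K, res3$n, res3$N), c(3L, 5L, 5L, 20L))
})

test_that("enrichment p-value decreases monotonically in the overlap", {
  bg <- sprintf("B%02d", 1:20)
  pw <- make_pathway("pw", bg[1:8])
  p_at_k <- vapply(1:6, function(k) {
    changed <- c(bg[seq_len(k)], bg[9:(14 - k)])  # always n = 6
    fisher_enrichment(pw, changed, bg)$p_value
  }, numeric(1L))
  expect_true(all(diff(p_at_k) < 0))
})

test_that("enrichment equals full draw enumeration on tiny universes", {
  # enumerate every possible changed-set of size n and count tail outcomes
  bg <- sprintf("B%d", 1:8)
  pw <- make_pathway("pw", bg[1:3])
  n <- 4L
  draws <- combn(bg, n)
  for (k_obs in 1:3) {
    changed <- c(bg[seq_len(k_obs)], bg[4:(4 + n - k_obs - 1L)])
    p <- fisher_enrichment(pw, changed, bg)$p_value
    tail_count <- sum(apply(draws, 2L, function(s)
      length(intersect(s, pw$members)) >= k_obs))
    expect_equal(p, tail_count / ncol(draws), tolerance = 1e-12)
  }
})

test_that("restricting the background to detected proteins raises p", {
  # pathway members are detected preferentially, so a global background
  # makes the pathway look enriched by detection alone
  global_bg <- sprintf("G%03d", 1:100)
  detected <- global_bg[1:20]          # includes all 10 pathway members
  pw <- make_pathway("pw", global_bg[1:10])
  changed <- global_bg[1:5]
  p_user <- fisher_enrichment(pw, changed, detected, "user_dataset")$p_value
  p_global <- fisher_enrichment(pw, changed, global_bg,
                                "global_annotation")$p_value
  expect_gt(p_user, p_global)

  expect_error(fisher_enrichment(pw, changed, character(0L)), "empty")
  expect_error(fisher_enrichment(pw, "X9", detected), "subset")
})

test_that("enrichment tables rank planted pathways first", {
  bg <- sprintf("B%02d", 1:30)
  pws <- list(make_pathway("hit", bg[1:8]), make_pathway("miss", bg[20:27]))
  changed <- list(trt = bg[1:6])
  enr <- enrichment_table(pws, changed, bg, "user_dataset")
  expect_identical(nrow(enr), 2L)
  top <- top_enriched(enr, 1L)
  expect_identical(top$pathway_id, "hit")
  # top lists are ascending in p and bounded in length
  top5 <- top_enriched(enr, 5L)
  expect_lte(nrow(top5), 5L)
  expect_true(!is.unsorted(top5$p_value))
})

test_that("functional classes count each changed protein exactly once", {
  map <- c(A = "OXPHOS", B = "OXPHOS", C = "redox")
  fc <- classify_functional(c("A", "B", "C"), map)
  expect_identical(fc$n_changed[fc$class == "OXPHOS"], 2L)
  expect_identical(fc$n_changed[fc$class == "redox"], 1L)
  expect_identical(sum(fc$n_changed), 3L)

  # empty changed set: empty breakdown
  expect_identical(nrow(classify_functional(character(0L), map)), 0L)

  # unmapped proteins fall into 'unassigned' with a message
  expect_message(fc2 <- classify_functional(c("A", "Z"), map), "unassigned")
  expect_identical(fc2$n_changed[fc2$class == "unassigned"], 1L)

  # per-treatment counts are appended and each sums to its set size
  fc3 <- classify_functional(c("A", "B", "C"), map,
                             list(t1 = c("A", "C"), t2 = "B"))
  expect_identical(sum(fc3$n_changed[fc3$treatment == "t1"]), 2L)
  expect_identical(sum(fc3$n_changed[fc3$treatment == "t2"]), 1L)
})

test_that("planted class structure is recovered from generator truth", {
  truth <- generate_truth(n_proteins = 500L, n_pathways = 10L, frac_de = 0.1,
                          seed = 77L)
  mito <- names(truth$classes)
  fc <- classify_functional(mito, truth$classes)
  expect_identical(sum(fc$n_changed), length(mito))
  truth_counts <- table(truth$classes)
  for (cl in names(truth_counts)) {
    expect_identical(fc$n_changed[fc$class == cl],
                     as.integer(truth_counts[[cl]]))
  }
})
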