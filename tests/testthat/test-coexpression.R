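test_that("noise-free opposite slopes are recovered exactly", {
  x <- rep(seq(-2, 2, length.out = 8), 2)
  group <- rep(c("control", "OA"), each = 8)
  y <- ifelse(group == "control", x, -x)
  pm <- fit_pair(x, y, group)
  expect_equal(pm$slope_control, 1)
  expect_equal(pm$slope_case, -1)
  expect_equal(pm$slope_diff, -2)
  expect_equal(pm$slope_case - pm$slope_control, pm$slope_diff)
})

test_that("pair fits match the normal-equations oracle to 1e-10", {
  set.seed(101)
  for (i in 1:25) {
    case <- rep(c(FALSE, TRUE), each = 12)
    x <- rnorm(24)
    y <- 0.5 * x + rnorm(24) + 0.8 * case
    pm <- fit_pair(x, y, ifelse(case, "OA", "control"))
    or <- ols_pair_oracle(x, y, case)
    expect_equal(pm$slope_control, or$slope_control, tolerance = 1e-10)
    expect_equal(pm$slope_case, or$slope_case, tolerance = 1e-10)
    expect_equal(pm$slope_diff, or$slope_diff, tolerance = 1e-10)
    expect_equal(pm$se_control, or$se_control, tolerance = 1e-10)
    expect_equal(pm$se_diff, or$se_diff, tolerance = 1e-10)
    expect_equal(c(pm$diff_ci_low, pm$diff_ci_high), or$diff_ci,
                 tolerance = 1e-10)
  }
})

test_that("pairwise-complete handling matches the oracle on missing data", {
  set.seed(77)
  case <- rep(c(FALSE, TRUE), each = 15)
  x <- rnorm(30); y <- rnorm(30)
  x[c(2, 9)] <- NA; y[c(20, 28)] <- NA
  pm <- fit_pair(x, y, ifelse(case, "OA", "control"))
  or <- ols_pair_oracle(x, y, case)
  expect_equal(pm$n_used, or$n_used)
  expect_equal(pm$slope_diff, or$slope_diff, tolerance = 1e-10)
  expect_equal(pm$se_case, or$se_case, tolerance = 1e-10)
})

test_that("all_pairs enumerates both directions in deterministic order", {
  set.seed(5)
  mat <- matrix(rnorm(48), 16, 3, dimnames = list(NULL, c("B", "A", "C")))
  group <- rep(c("control", "OA"), each = 8)
  pairs <- all_pairs(mat, group)
  expect_equal(nrow(pairs), 6)
  expect_equal(pairs$outcome, rep(c("A", "B", "C"), each = 2))
  # rows agree with individual fit_pair calls
  r <- pairs[pairs$outcome == "C" & pairs$predictor == "A", ]
  pm <- fit_pair(mat[, "A"], mat[, "C"], group)
  expect_equal(r$slope_diff, pm$slope_diff, tolerance = 1e-12)
  expect_equal(r$se_control, pm$se_control, tolerance = 1e-12)

  expect_error(all_pairs(mat, rep("control", 16)), "two groups")
  expect_error(all_pairs(mat[, 1, drop = FALSE], group), "2 proteins")
})

test_that("on one effective group the slope equals the correlation both ways", {
  set.seed(31)
  half <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  mat <- standardize(rbind(half, half)) # identical groups
  group <- rep(c("control", "OA"), each = 20)
  pairs <- all_pairs(mat, group)
  r <- stats::cor(mat[, "a"], mat[, "b"])
  expect_equal(pairs$slope_control, rep(r, 2), tolerance = 1e-10)
  expect_equal(pairs$slope_case, rep(r, 2), tolerance = 1e-10)
})

test_that("swapping group labels flips the slope difference", {
  set.seed(13)
  case <- rep(c(FALSE, TRUE), each = 10)
  x <- rnorm(20); y <- rnorm(20) + x * case
  pm1 <- fit_pair(x, y, ifelse(case, "OA", "control"))
  # relabel so the former case group becomes the reference level
  pm2 <- fit_pair(x, y, ifelse(case, "a_ref", "b_other"))
  expect_equal(pm2$slope_diff, -pm1$slope_diff, tolerance = 1e-12)
  expect_equal(pm2$se_diff, pm1$se_diff, tolerance = 1e-12)
  expect_equal(pm2$slope_control, pm1$slope_case, tolerance = 1e-12)
})

test_that("rank-deficient pairs are flagged unestimable, not errors", {
  x <- c(rep(1, 10), rnorm(10)) # constant within controls
  y <- rnorm(20)
  group <- rep(c("control", "OA"), each = 10)
  pm <- fit_pair(x, y, group)
  expect_false(pm$estimable)
  expect_true(is.na(pm$slope_control))
})

test_that("every pair is classified exactly once", {
  set.seed(61)
  mat <- matrix(rnorm(20 * 6), 20, 6,
                dimnames = list(NULL, sprintf("P%d", 1:6)))
  mat[1:8, 3] <- NA # starve one protein within the control group
  group <- rep(c("control", "OA"), each = 10)
  pairs <- all_pairs(mat, group)
  dd <- npxnet:::dedup_unordered(pairs)
  qualifying <- sum(dd$estimable & abs(dd$slope_diff) >= 1 &
                      (dd$diff_ci_low > 0 | dd$diff_ci_high < 0), na.rm = TRUE)
  non_qualifying <- sum(dd$estimable) - qualifying
  unestimable <- sum(!dd$estimable)
  expect_equal(qualifying + non_qualifying + unestimable, choose(6, 2))
})

test_that("enrichment-input selection applies magnitude and CI rules", {
  pairs <- dplyr::bind_rows(
    make_pair_row("ACAN", "SELP", slope_control = -1.02, slope_case = 0.01),
    make_pair_row("P1", "P2", slope_control = 0, slope_case = 0.8),
    make_pair_row("P3", "P4", slope_control = 0, slope_case = 1.4,
                  se_diff = 1.0),
    make_pair_row("P5", "P6", slope_control = 0.2, slope_case = 1.9)
  )
  sel <- select_enrichment_proteins(pairs)
  expect_setequal(sel$control, c("ACAN", "SELP"))
  expect_setequal(sel$case, c("P5", "P6"))
  expect_false(any(c("P1", "P2", "P3", "P4") %in%
                     c(sel$control, sel$case)))
})

test_that("network edges require both the difference and a strong group slope", {
  pairs <- dplyr::bind_rows(
    make_pair_row("TMSB10", "SIRPB1", slope_control = -1.61, slope_case = 0.02),
    make_pair_row("A", "B", slope_control = -0.5, slope_case = 0.9),
    make_pair_row("C", "D", slope_control = 0, slope_case = 0),
    make_pair_row("E", "F", slope_control = 1.3, slope_case = -1.2)
  )
  edges <- select_network_edges(pairs)
  key <- paste(edges$protein_a, edges$protein_b, edges$group, edges$sign)
  expect_true("SIRPB1 TMSB10 control negative" %in% key)
  expect_false(any(grepl("^A B", key))) # diff qualifies but neither slope >= 1
  expect_false(any(grepl("^C D", key)))
  expect_true("E F control positive" %in% key)
  expect_true("E F OA negative" %in% key)
})

test_that("planted differential edges are recovered at study scale", {
  set.seed(99)
  results <- t(sapply(1:20, function(i) {
    sim <- simulate_planted_pairs()
    pairs <- all_pairs(sim$mat, sim$group)
    edges <- select_network_edges(pairs)
    found <- edge_keys(edges)
    c(recovered = sum(sim$planted %in% found),
      false_pos = length(setdiff(found, sim$planted)))
  }))
  expect_gte(median(results[, "recovered"]), 6)
  expect_lte(median(results[, "false_pos"]), 2)
})

test_that("the full panel of ordered pairs fits within the time budget", {
  set.seed(3)
  mat <- matrix(rnorm(24 * 274), 24, 274,
                dimnames = list(NULL, sprintf("P%03d", 1:274)))
  group <- rep(c("control", "OA"), c(13, 11))
  elapsed <- system.time(pairs <- all_pairs(mat, group))["elapsed"]
  expect_equal(nrow(pairs), 274 * 273)
  expect_lt(elapsed, 60)
})
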