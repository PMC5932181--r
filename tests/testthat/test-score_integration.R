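test_that("z-scoring uses the sample sd and is affine-invariant", {
  pr <- make_predictions(c("rs1", "rs2", "rs3"), "hsa-miR-1", "G1",
                         raws = c(1, 2, 3), effects = "disrupt")
  h <- zscore_harmonize(pr)
  expect_equal(h$z_score, c(-1, 0, 1))
  expect_equal(order(h$rsid), 1:3)  # order preserved

  shifted <- pr; shifted$raw_score <- pr$raw_score + 10
  scaled <- pr; scaled$raw_score <- pr$raw_score * 5
  expect_equal(zscore_harmonize(shifted)$z_score, h$z_score)
  expect_equal(zscore_harmonize(scaled)$z_score, h$z_score)
})

test_that("z-scoring standardizes within each tool independently", {
  set.seed(42)
  pr <- do.call(rbind, lapply(mirsnp_tools(), function(tl)
    make_predictions(sprintf("rs%d", 1:50), "hsa-miR-1", "G1",
                     raws = rnorm(50, mean = match(tl, mirsnp_tools()) * 10,
                                  sd = match(tl, mirsnp_tools())),
                     effects = "disrupt", tool = tl)))
  h <- zscore_harmonize(pr)
  for (tl in mirsnp_tools()) {
    z <- h$z_score[h$tool == tl]
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
  }
})

test_that("degenerate tools are refused by name", {
  pr <- make_predictions("rs1", "hsa-miR-1", "G1", 1, "disrupt",
                         tool = "mirsnpscore")
  expect_error(zscore_harmonize(pr), "mirsnpscore.*fewer than 2")
  pr2 <- make_predictions(c("rs1", "rs2"), "hsa-miR-1", "G1", c(3, 3),
                          "disrupt", tool = "mirnasnp2")
  expect_error(zscore_harmonize(pr2), "mirnasnp2.*zero")
})

test_that("a sign-flipped tool reverses its evidence ordering", {
  pr <- make_predictions(c("rs1", "rs2", "rs3"), "hsa-miR-1", "G1",
                         raws = c(1, 2, 3), effects = "disrupt")
  flipped <- zscore_harmonize(pr, mirsnp_config(score_sign_flip = "polymirts"))
  expect_equal(flipped$z_score, c(1, 0, -1))
})

test_that("the unit-interval map is the standard normal CDF", {
  expect_equal(to_unit_interval(0), 0.5)
  a <- c(0.3, 1.7, 2.2)
  expect_equal(to_unit_interval(a) + to_unit_interval(-a), rep(1, 3))
  expect_equal(to_unit_interval(1.644854), 0.95, tolerance = 1e-4)
  z <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(to_unit_interval(z)) > 0))
  expect_error(to_unit_interval(Inf), "finite")
})

test_that("the combined score follows the complement-product rule", {
  expect_equal(combine_nbc(c(0.5, 0.5)), 0.75)
  expect_equal(combine_nbc(c(0, 0, 0)), 0)
  expect_equal(combine_nbc(c(1, 0.37)), 1)
  expect_equal(combine_nbc(c(0.9, 0.5, 0.2)), 0.96)
  expect_equal(combine_nbc(0.42), 0.42)  # single tool passes through
  expect_error(combine_nbc(numeric(0)), "no unit scores")
  expect_error(combine_nbc(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("combiner invariants hold on random score sets", {
  set.seed(7)
  for (i in 1:200) {
    s <- runif(sample(1:3, 1))
    S <- combine_nbc(s)
    expect_equal(S, combine_nbc(rev(s)))           # symmetry
    expect_gte(S, max(s) - 1e-15)                  # dominates each tool
    expect_lte(S, min(1, sum(s)) + 1e-15)          # union bound
    expect_equal(combine_nbc(c(s, 0)), S)          # zero is neutral
    bump <- pmin(s + runif(length(s), 0, 1 - max(s)), 1)
    expect_gte(combine_nbc(bump), S - 1e-15)       # monotone
  }
})

test_that("consensus effect requires unanimity", {
  expect_equal(consensus_effect("disrupt"), "disrupt")
  expect_equal(consensus_effect(rep("create", 3)), "create")
  expect_equal(consensus_effect(c("create", "disrupt")), "ambiguous")
  expect_error(consensus_effect(character(0)), "no effects")
  expect_error(consensus_effect("enhance"), "create/disrupt")
})

test_that("candidate calling applies the strict NBC threshold", {
  # two tools whose unit scores are pinned by rank within tool
  set.seed(5)
  n <- 40
  pr <- rbind(
    make_predictions(sprintf("rs%d", 1:n), sprintf("hsa-miR-%d", 1:n),
                     sprintf("G%d", 1:n), rnorm(n), "disrupt",
                     tool = "polymirts"),
    make_predictions(sprintf("rs%d", 1:n), sprintf("hsa-miR-%d", 1:n),
                     sprintf("G%d", 1:n), rnorm(n), "disrupt",
                     tool = "mirnasnp2"))
  h <- zscore_harmonize(pr)
  cand <- call_candidates(h, mirsnp_config())

  # independent re-filter of the same list
  expected <- character()
  for (rs in unique(h$rsid)) {
    s <- h$unit_score[h$rsid == rs]
    if (oracle_combine(s) > 0.7) expected <- c(expected, rs)
  }
  expect_setequal(cand$rsid, expected)
  expect_true(all(cand$nbc_score > 0.7))

  # a triple landing exactly on the threshold is excluded
  h2 <- h[h$rsid == "rs1", ]
  h2$unit_score <- c(0.7, 0)
  expect_equal(nrow(call_candidates(h2, mirsnp_config())), 0L)
  h2$unit_score <- c(0.7 + 1e-9, 0)
  expect_equal(nrow(call_candidates(h2, mirsnp_config())), 1L)
})

test_that("candidates retain per-tool unit scores and consensus effects", {
  pr <- rbind(
    make_predictions(c("rs1", "rs2"), c("hsa-miR-1", "hsa-miR-2"),
                     c("G1", "G2"), c(5, -5), c("create", "disrupt"),
                     tool = "polymirts"),
    make_predictions(c("rs1", "rs2"), c("hsa-miR-1", "hsa-miR-2"),
                     c("G1", "G2"), c(4, -4), c("disrupt", "disrupt"),
                     tool = "mirsnpscore"))
  cand <- call_candidates(zscore_harmonize(pr), mirsnp_config())
  expect_equal(cand$rsid, "rs1")
  expect_equal(cand$effect, "ambiguous")  # tools disagree on rs1
  expect_false(is.na(cand$s_polymirts))
  expect_false(is.na(cand$s_mirsnpscore))
  expect_true(is.na(cand$s_mirnasnp2))
  expect_equal(cand$nbc_score,
               oracle_combine(c(cand$s_polymirts, cand$s_mirsnpscore)))
  expect_equal(nrow(call_candidates(zscore_harmonize(pr)[0, ],
                                    mirsnp_config())), 0L)
})
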