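test_that("Student's t-test matches the hand-derived example", {
  # pooled variance 1, se = sqrt(2/3), t = -3 / sqrt(2/3) = -sqrt(13.5)
  r <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$df, 4)
  expect_equal(r$t, -sqrt(13.5), tolerance = 1e-12)
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$p, 0.0213, tolerance = 1e-2)
  # two-sided p via the incomplete-beta identity
  expect_equal(r$p, pbeta(4 / (4 + 13.5), 2, 0.5), tolerance = 1e-12)
})

test_that("Student's t-test agrees with stats::t.test across random samples", {
  set.seed(77)
  for (i in 1:50) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1), mean = runif(1, -1, 1))
    mine <- student_t_test(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    mw <- student_t_test(a, b, welch = TRUE)
    rw <- stats::t.test(a, b)
    expect_equal(mw$p, rw$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate-variance inputs follow the defined contract", {
  same <- student_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$degenerate)
  apart <- student_t_test(c(2, 2, 2), c(1, 1, 1))
  expect_equal(apart$p, 0)
  expect_true(apart$degenerate)
  expect_error(student_t_test(1, c(1, 2)), "at least 2")
})

test_that("triplicate filter requires a complete replicate set in every group", {
  full <- rep(1, 9)
  holed <- full; holed[5] <- NA  # one vehicle replicate missing
  quant <- manual_quant(make_L(list(P_full = full, P_holed = holed)))
  tested <- triplicate_filter(quant, manifest_3x3())
  expect_equal(tested, "P_full")
})

test_that("triplicate filter equals a direct mask-count oracle on simulated dropout", {
  sim <- small_sim(seed = 31)
  q <- suppressMessages(quantify_proteins(sim$evidence, sim$db))
  tested <- triplicate_filter(q$quant, sim$manifest)
  oracle <- rownames(q$quant$L)[rowSums(is.na(q$quant$L)) == 0]
  expect_setequal(tested, oracle)
})

test_that("the cascade classifies by treatment-only significance", {
  set.seed(9)
  eps <- function() rnorm(3, 0, 0.01)
  L <- make_L(list(
    dr   = c(1 + eps(), 1 + eps(), 1.5 + eps()),   # treatment shifted only
    both = c(1 + eps(), 1.5 + eps(), 1.5 + eps()), # vehicle shifted too
    null = c(1 + eps(), 1 + eps(), 1 + eps()),
    hole = c(1 + eps(), c(NA, 1, 1), 1.5 + eps())
  ))
  diff <- classify_differential(manual_quant(L), manifest_3x3())
  cls <- setNames(diff$class, diff$protein)
  expect_equal(unname(cls["dr"]), "differentially_regulated")
  expect_equal(unname(cls["both"]), "tested")
  expect_equal(unname(cls["null"]), "tested")
  expect_equal(unname(cls["hole"]), "not_tested")
  expect_true(all(is.na(diff$p_treatment[diff$class == "not_tested"])))
  expect_equal(diff$fc_treatment[diff$protein == "dr"],
               mean(L["dr", 7:9]) / mean(L["dr", 1:3]))
})

test_that("strict criteria act on fold change and vehicle band with stated strictness", {
  set.seed(10)
  eps <- function() rnorm(3, 0, 0.005)
  L <- make_L(list(
    up      = c(1 + eps(), 1 + eps(), 2.5 + eps()),
    down    = c(1 + eps(), 1 + eps(), 0.3 + eps()),
    # vehicle off band but too noisy for its own contrast to be significant
    off_band = c(1 + eps(), c(0.9, 1.3, 1.7), 2.5 + eps()),
    small_fc = c(1 + eps(), 1.0 + eps(), 1.5 + eps())
  ))
  cfg <- selection_config()
  diff <- apply_strict_criteria(classify_differential(manual_quant(L),
                                                      manifest_3x3(), cfg), cfg)
  cls <- setNames(diff$class, diff$protein)
  expect_equal(unname(cls["up"]), "significant_up")
  expect_equal(unname(cls["down"]), "significant_down")
  expect_equal(unname(cls["off_band"]), "differentially_regulated")  # fc_vehicle 1.3
  expect_equal(unname(cls["small_fc"]), "differentially_regulated") # fc 1.5 < 2
})

test_that("fold-change bound is strict and the vehicle band is closed", {
  # zero within-group variance makes the contrasts deterministic:
  # treatment exactly 2x (not MORE than two-fold), vehicle exactly at band edges
  L <- make_L(list(
    at_two    = c(1, 1, 1, 1, 1, 1, 2, 2, 2),
    band_low  = c(1, 1, 1, 0.8, 0.8, 0.8, 3, 3, 3),
    band_high = c(1, 1, 1, 1.2, 1.2, 1.2, 3, 3, 3),
    past_two  = c(1, 1, 1, 1, 1, 1, 2.001, 2.001, 2.001)
  ))
  cfg <- selection_config()
  diff <- apply_strict_criteria(classify_differential(manual_quant(L),
                                                      manifest_3x3(), cfg), cfg)
  cls <- setNames(diff$class, diff$protein)
  # fc exactly 2 fails the strict "> 2"
  expect_equal(unname(cls["at_two"]), "differentially_regulated")
  expect_equal(unname(cls["past_two"]), "significant_up")
  # band edges are inclusive, but a vehicle sitting exactly at the edge with
  # zero variance is itself a (degenerate) significant vehicle change
  expect_equal(unname(cls["band_low"]), "tested")
  expect_equal(unname(cls["band_high"]), "tested")
  # with a vehicle inside the band the call goes through
  L2 <- make_L(list(edge = c(1, 1, 1, 1, 1, 1, 3, 3, 3)))
  d2 <- apply_strict_criteria(classify_differential(manual_quant(L2),
                                                    manifest_3x3(), cfg), cfg)
  expect_equal(d2$class, "significant_up")

  # band inclusivity in isolation: a differentially regulated protein with
  # fc_vehicle exactly 0.8 or 1.2 passes criterion (b)
  d3 <- tibble::tibble(protein = c("a", "b", "c"),
                       fc_treatment = c(3, 3, 3),
                       fc_vehicle = c(0.8, 1.2, 1.2000001),
                       class = "differentially_regulated")
  d3 <- apply_strict_criteria(d3, cfg)
  expect_equal(d3$class, c("significant_up", "significant_up",
                           "differentially_regulated"))
})

test_that("cascade classes nest and counts are monotone along the cascade", {
  sim <- small_sim(seed = 41)
  res <- suppressMessages(run_pipeline(sim$evidence, sim$db, sim$manifest))
  d <- res$differential
  sig <- d$class %in% c("significant_up", "significant_down")
  dr <- sig | d$class == "differentially_regulated"
  tested <- dr | d$class == "tested"
  expect_true(all(sig <= dr), info = "significant within differential")
  expect_true(all(dr <= tested))
  cnt <- res$counts
  expect_true(cnt["detected"] >= cnt["tested"])
  expect_true(cnt["tested"] >= cnt["differentially_regulated"])
  expect_true(cnt["differentially_regulated"] >= cnt["significant"])
})

test_that("tightening the fold threshold or vehicle band never adds a call", {
  sim <- small_sim(seed = 51, cv_biological = 0.3)
  q <- suppressMessages(quantify_proteins(sim$evidence, sim$db))
  base_cfg <- selection_config()
  diff0 <- classify_differential(q$quant, sim$manifest, base_cfg)
  sig_set <- function(cfg) {
    d <- apply_strict_criteria(diff0, cfg)
    d$protein[d$class %in% c("significant_up", "significant_down")]
  }
  s0 <- sig_set(base_cfg)
  for (fc in c(2.5, 3, 5)) {
    expect_true(all(sig_set(selection_config(fc_threshold = fc)) %in% s0))
  }
  for (half in c(0.15, 0.1, 0.02)) {
    cfg <- selection_config(vehicle_band = c(1 - half, 1 + half))
    expect_true(all(sig_set(cfg) %in% s0))
  }
})

test_that("results are invariant under relabeling runs within a group", {
  sim <- small_sim(seed = 61)
  res0 <- suppressMessages(run_pipeline(sim$evidence, sim$db, sim$manifest))
  man2 <- sim$manifest
  i <- which(man2$group == "treatment")
  man2$replicate[i] <- rev(man2$replicate[i])
  res1 <- suppressMessages(run_pipeline(sim$evidence, sim$db, man2))
  expect_equal(res1$differential$class, res0$differential$class)
  expect_equal(res1$differential$p_treatment, res0$differential$p_treatment)
  expect_equal(res1$counts, res0$counts)
})

test_that("reported levels are normalized to the untreated group", {
  L <- make_L(list(p = c(2, 2, 2, 2.2, 2.2, 2.2, 4, 4, 4)))
  diff <- classify_differential(manual_quant(L), manifest_3x3())
  lv <- normalize_to_untreated(diff)
  get <- function(g, col) lv[[col]][lv$group == g]
  expect_equal(get("untreated", "level"), 1.0)
  expect_equal(get("treatment", "level"), 2.0)
  expect_equal(get("vehicle", "level"), 1.1)
  # SDs rescale by the same factor as the means
  set.seed(3)
  L2 <- make_L(list(p = c(rnorm(3, 2, 0.2), rnorm(3, 2, 0.2), rnorm(3, 4, 0.4))))
  d2 <- classify_differential(manual_quant(L2), manifest_3x3())
  lv2 <- normalize_to_untreated(d2)
  expect_equal(lv2$sd[lv2$group == "treatment"],
               d2$sd_treatment / d2$mean_untreated)
})
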