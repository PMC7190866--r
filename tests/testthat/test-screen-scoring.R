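test_that("i_score matches its defining formula", {
  expect_equal(i_score(1000, c(900, 1000, 1100)), 0)
  expect_equal(i_score(0, c(900, 1000, 1100)), 100)
  expect_equal(i_score(400, c(1000, 1000, 1000)), 60)
  expect_equal(i_score(1200, 1000), -20)  # stimulation retained, unclipped
  # even-length DMSO set: median is the mean of the central two
  expect_equal(i_score(500, c(900, 1100)), 50)
})

test_that("i_score rejects degenerate DMSO sets", {
  expect_error(i_score(100, numeric(0)), "empty")
  expect_error(i_score(100, c(0, 0)), "positive")
  expect_error(i_score(100, c(-5, -10)), "positive")
})

test_that("i_score is affine in signal and plate-rescale invariant", {
  set.seed(202)
  for (i in 1:20) {
    dmso <- runif(8, 500, 2000)
    med <- median(dmso)
    a <- runif(1, 0, 2)
    expect_equal(i_score(a * med, dmso), (1 - a) * 100)
    # strictly decreasing in signal
    s <- sort(runif(5, 0, 3000))
    expect_true(all(diff(i_score(s, dmso)) < 0))
    # scaling signal and controls together changes nothing
    k <- runif(1, 0.1, 10)
    expect_equal(i_score(k * s, k * dmso), i_score(s, dmso))
  }
})

test_that("replicate aggregation reports mean and sd", {
  scored <- data.frame(compound = "c1", cell_line = "l1", dose_um = 1,
                       i_score = c(58, 60, 62))
  agg <- aggregate_scores(scored)
  expect_equal(agg$i_score, 60)
  expect_equal(agg$sd, 2)
  expect_equal(agg$n_replicates, 3L)

  single <- aggregate_scores(scored[2, ])
  expect_equal(single$i_score, 60)
  expect_equal(single$sd, 0)
})

test_that("averaging per-well scores equals scoring averaged signals when noiseless", {
  cfg <- noiseless_config(n_replicates = 3)
  truth <- one_compound_truth(ed50 = 1, hill = 1.5, emax = 0.8,
                              lines = c("lineA", "lineB"))
  screen <- generate_single_dose_screen(cfg, list(truth),
                                        doses = c(0.3, 1, 3))
  scored <- score_screen(screen)
  agg <- aggregate_scores(scored)

  # independent route: average raw signals first, then apply the formula
  treated <- screen[screen$compound != DMSO_SENTINEL, ]
  key <- paste(treated$cell_line, treated$dose_um)
  mean_sig <- tapply(treated$luminescence, key, mean)
  expected <- (1 - mean_sig / 10000) * 100
  got <- setNames(agg$i_score, paste(agg$cell_line, agg$dose_um))
  expect_equal(unname(got[names(expected)]), as.numeric(expected))
  expect_equal(unname(agg$sd), rep(0, nrow(agg)))
})

test_that("efficacy filter uses a strict threshold", {
  prof <- rbind(a = c(55, 10, 10), b = c(50, 50, 50), c = c(40, 45, 30))
  colnames(prof) <- c("p53_null", "p53_wt", "p53_R158G")
  eff <- efficacy_filter(prof)
  expect_equal(unname(eff), c(TRUE, FALSE, FALSE))
})

test_that("selectivity classes follow the one-line rule", {
  expect_equal(selectivity_class(c(p53_R158G = 60, p53_wt = 20,
                                   p53_null = 30)), "R158G_selective")
  expect_equal(selectivity_class(c(p53_R158G = 20, p53_wt = 60,
                                   p53_null = 30)), "WT_selective")
  expect_equal(selectivity_class(c(p53_R158G = 20, p53_wt = 30,
                                   p53_null = 60)), "NULL_selective")
  expect_equal(selectivity_class(c(p53_R158G = 60, p53_wt = 60,
                                   p53_null = 60)), "pan_active")
  expect_equal(selectivity_class(c(p53_R158G = 60, p53_wt = 55,
                                   p53_null = 20)),
               "other_selective_pattern")
  # exactly at threshold fails both strict comparisons
  expect_equal(selectivity_class(c(p53_R158G = 60, p53_wt = 50,
                                   p53_null = 20)),
               "other_selective_pattern")
  expect_equal(selectivity_class(c(p53_R158G = 30, p53_wt = 10,
                                   p53_null = 20)), "inactive")
})

test_that("hit classes partition the planted synthetic screen", {
  truths <- demo_screen_truths(n_compounds = 40, n_r158g = 6, n_wt = 3,
                               n_null = 3, n_pan = 5, n_dual = 3)
  cfg <- sim_config(seed = 17, noise_cv = 0.05, n_replicates = 3)
  screen <- generate_single_dose_screen(cfg, truths, doses = c(0.1, 1))
  profile <- inhibition_profile(aggregate_scores(score_screen(screen)))
  hits <- hit_calls(profile)

  planted <- attr(truths, "classes")
  for (cls in c("R158G_selective", "WT_selective", "NULL_selective",
                "pan_active")) {
    expect_setequal(hits$compound[hits$selectivity_class == cls],
                    names(planted)[planted == cls])
  }
  # dual-active compounds land in other_selective_pattern
  expect_setequal(hits$compound[hits$selectivity_class ==
                                  "other_selective_pattern"],
                  names(planted)[planted == "dual_active"])
  # classes are mutually exclusive and exhaustive
  expect_equal(sort(table(hits$selectivity_class)),
               sort(table(c(ifelse(planted == "dual_active",
                                   "other_selective_pattern", planted)))))
})

test_that("profile aggregation takes the max over screened doses", {
  scored <- data.frame(
    compound = rep("c1", 4), cell_line = rep(c("l1", "l2"), each = 2),
    dose_um = rep(c(0.1, 1), 2), i_score = c(20, 70, 10, 30))
  prof <- inhibition_profile(aggregate_scores(scored))
  expect_equal(prof["c1", "l1"], 70)
  expect_equal(prof["c1", "l2"], 30)
  prof_low <- inhibition_profile(aggregate_scores(scored),
                                 aggregation = 0.1)
  expect_equal(prof_low["c1", "l1"], 20)
})

test_that("complete-linkage clustering matches hand and brute-force oracles", {
  # two identical rows merge first at height 0
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  tree <- cluster_profiles(m)
  expect_equal(min(tree$height), 0)

  # hand-computed: {(0,0),(0,3)} merge first at height 3
  m2 <- rbind(a = c(0, 0), b = c(0, 3), c = c(10, 10))
  tree2 <- cluster_profiles(m2)
  expect_equal(tree2$height[1], 3)
  expect_setequal(-tree2$merge[1, ], c(1, 2))

  # merge heights equal the O(n^3) oracle on random matrices
  set.seed(31)
  for (i in 1:6) {
    n <- sample(3:8, 1)
    mat <- matrix(rnorm(n * 3), n, dimnames = list(paste0("c", 1:n), NULL))
    tree_i <- cluster_profiles(mat)
    expect_equal(sort(tree_i$height),
                 brute_complete_linkage_heights(mat))
    # permuting rows leaves the merge heights unchanged
    perm <- sample(n)
    tree_p <- cluster_profiles(mat[perm, , drop = FALSE])
    expect_equal(sort(tree_p$height), sort(tree_i$height))
  }
})

test_that("clustering validates its input", {
  expect_error(cluster_profiles(matrix(1, 1, 3)), "at least 2")
  bad <- matrix(c(1, NA, 2, 3), 2)
  expect_error(cluster_profiles(bad), "missing")
})
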