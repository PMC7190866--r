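doses8 <- 10^seq(-2, 2, length.out = 8)

curve_4pl <- function(d, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (d / ec50)^hill)
}

test_that("noiseless 4PL parameters are recovered to numerical precision", {
  v <- curve_4pl(doses8, 0, 100, 1, 1)
  fit <- fit_4pl(doses8, v)
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 - 1) / 1, 1e-6)
  expect_lt(abs(fit$hill - 1), 1e-6)
  expect_lt(abs(fit$bottom - 0), 1e-4)
  expect_lt(abs(fit$top - 100), 1e-4)
})

test_that("optimizer agrees with the grid-search oracle on seeded noiseless curves", {
  set.seed(41)
  for (i in 1:20) {
    true <- list(bottom = runif(1, 0, 30), top = runif(1, 70, 110),
                 ec50 = 10^runif(1, -1.5, 1.5), hill = runif(1, 0.5, 3))
    v <- curve_4pl(doses8, true$bottom, true$top, true$ec50, true$hill)
    fit <- fit_4pl(doses8, v)
    oracle <- grid_4pl(doses8, v)
    expect_true(fit$converged)
    expect_lt(abs(fit$ec50 - oracle$ec50) / oracle$ec50, 0.01)
    expect_lt(abs(fit$ec50 - true$ec50) / true$ec50, 1e-6)
  }
})

test_that("constant responses are flagged degenerate, not fitted", {
  fit <- fit_4pl(doses8, rep(100, 8))
  expect_false(fit$converged)
  expect_true(fit$degenerate)
})

test_that("fit input validation", {
  expect_error(fit_4pl(c(1, 2, 3), c(90, 50, 10)), "4 distinct")
  expect_error(fit_4pl(c(1, 2, 4, 8), c(90, NA, 30, 10)), "finite")
  expect_error(fit_4pl(c(-1, 2, 4, 8), c(90, 60, 30, 10)), "> 0")
})

test_that("ec50 under noise is recovered within 0.15 log10 units (median)", {
  errs <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    sdlog <- sqrt(log(1 + 0.05^2))
    v_rep <- replicate(3, curve_4pl(doses8, 0, 100, 1, 1) *
                            exp(rnorm(8, 0, sdlog)))
    fit <- fit_4pl(rep(doses8, 3), as.vector(v_rep))
    abs(log10(fit$ec50 / 1))
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("fit is dose-scale equivariant", {
  set.seed(57)
  v <- curve_4pl(doses8, 5, 95, 0.7, 1.4)
  f1 <- fit_4pl(doses8, v)
  for (k in c(0.1, 3, 40)) {
    f2 <- fit_4pl(doses8 * k, v)
    expect_equal(f2$ec50, f1$ec50 * k, tolerance = 1e-6)
    expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
  }
})

test_that("absolute IC50 solves the 50% viability crossing", {
  sym <- structure(list(bottom = 0, top = 100, hill = 1, ec50 = 2,
                        rss = 0, converged = TRUE, degenerate = FALSE,
                        n_points = 8), class = "dose_response_fit")
  expect_equal(ic50_absolute(sym), 2)

  shifted <- sym
  shifted$bottom <- 40
  expect_equal(ic50_absolute(shifted), 10)  # 40 + 60/(1 + d/2) = 50

  high <- sym
  high$bottom <- 60
  expect_warning(res <- ic50_absolute(high), "does not cross")
  expect_true(is.na(res))
})

test_that("constrained fits honor fixed bottom/top", {
  v <- curve_4pl(doses8, 0, 100, 1, 1)
  fit <- fit_4pl(doses8, v, constrain = list(bottom = 0, top = 100))
  expect_true(fit$converged)
  expect_equal(fit$bottom, 0)
  expect_equal(fit$top, 100)
  expect_lt(abs(fit$ec50 - 1), 1e-6)
  # IC50 equals ec50 exactly for a (0, 100) curve
  expect_equal(ic50_absolute(fit), fit$ec50)
})

test_that("potency fold-change flags at 10-fold inclusive", {
  mk <- function(ec50) structure(
    list(bottom = 0, top = 100, hill = 1, ec50 = ec50, rss = 0,
         converged = TRUE, degenerate = FALSE, n_points = 8),
    class = "dose_response_fit")
  exactly10 <- potency_fold_change(mk(0.1), mk(1))
  expect_equal(exactly10$fold, 10)
  expect_true(exactly10$selective)
  same <- potency_fold_change(mk(1), mk(1))
  expect_equal(same$fold, 1)
  expect_false(same$selective)
  unconv <- mk(1)
  unconv$converged <- FALSE
  expect_error(potency_fold_change(unconv, mk(1)), "converged")
})

test_that("a planted strongly selective compound is flagged under noise", {
  truth <- compound_truth("SEL", list(
    p53_R158G = list(ed50 = 0.05, hill = 1, emax = 0.95),
    p53_wt = list(ed50 = 2.5, hill = 1, emax = 0.95)))
  screen <- generate_single_dose_screen(
    sim_config(seed = 23, noise_cv = 0.05, n_replicates = 3),
    list(truth), doses = 10^seq(-3, 1.5, length.out = 8))
  agg <- aggregate_scores(score_screen(screen))
  fits <- lapply(split(agg, agg$cell_line), function(s) {
    fit_4pl(s$dose_um, 100 - s$i_score)
  })
  fc <- potency_fold_change(fits$p53_R158G, fits$p53_wt)
  expect_true(fc$selective)
  expect_gt(fc$fold, 10)
})

test_that("IC50 shift ratios behave as sensitization measures", {
  mk <- function(ec50) structure(
    list(bottom = 0, top = 100, hill = 1, ec50 = ec50, rss = 0,
         converged = TRUE, degenerate = FALSE, n_points = 8),
    class = "dose_response_fit")
  expect_equal(ic50_shift(mk(2), mk(2)), 1)
  expect_equal(ic50_shift(mk(2), mk(1)), 2)  # modulator halves the IC50
  never <- mk(2)
  never$bottom <- 60
  expect_error(suppressWarnings(ic50_shift(never, mk(1))), "undefined")
})

test_that("planted synergy shows as IC50 shift only in the interacting line", {
  combo_truth <- function(ed50) one_compound_truth(ed50 = ed50, hill = 1,
                                                   emax = 0.95,
                                                   lines = c("R158G", "wt"))
  mod <- combo_truth(5); mod$compound_id <- "MOD"
  cyto <- combo_truth(3); cyto$compound_id <- "CYTO"
  m <- generate_dose_matrix(
    sim_config(seed = 67, noise_cv = 0.05, n_replicates = 3),
    mod, cyto, interaction_truth(c(R158G = 0.25, wt = 0)),
    doses_a = 0.1, doses_b = 10^seq(-1.5, 1.5, length.out = 7))
  shift_for <- function(line) {
    sub <- m[m$cell_line == line, ]
    fit_at <- function(da) {
      s <- sub[sub$dose_a_um == da & sub$dose_b_um > 0, ]
      v <- tapply(s$viability_pct, s$dose_b_um, mean)
      fit_4pl(as.numeric(names(v)), as.numeric(v))
    }
    ic50_shift(fit_at(0), fit_at(0.1))
  }
  expect_gt(shift_for("R158G"), 1.5)
  expect_lt(abs(shift_for("wt") - 1), 0.25)
})
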