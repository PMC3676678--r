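test_that("branching times of a hand-readable newick are correct", {
  bt <- branching_times("((A:1,B:1):1,C:2);")
  expect_equal(bt$ages, c(2, 1))
  expect_equal(bt$n_tips, 3L)
})

test_that("a tree with n tips yields exactly n - 1 ages, matching a traversal oracle", {
  for (s in 1:5) {
    tr <- simulate_yule_shift_tree(1, n_tips = 25, seed = 70 + s)
    bt <- branching_times(tr)
    expect_length(bt$ages, 24L)
    expect_equal(bt$ages, node_ages_oracle(tr), tolerance = 1e-9)
  }
})

test_that("non-ultrametric trees are rejected", {
  expect_error(branching_times("((A:1,B:2):1,C:2);"), "ultrametric")
})

test_that("the pure-birth MLE equals the closed form and the numeric optimum", {
  tr <- simulate_yule_shift_tree(0.6, n_tips = 80, seed = 81)
  bt <- branching_times(tr)
  st <- museomics:::bt_stats(bt)
  fit <- fit_bdl(bt, "pureBirth")
  expect_equal(fit$params[["r"]], st$E / st$S, tolerance = 1e-12)
  num <- stats::optimize(function(r)
    -museomics:::loglik_pure_birth(st, r), c(1e-6, 50), tol = 1e-10)
  expect_equal(fit$params[["r"]], num$minimum, tolerance = 1e-6)
})

test_that("the birth-death likelihood agrees with an independent implementation", {
  tr <- simulate_yule_shift_tree(0.5, n_tips = 60, seed = 82)
  bt <- branching_times(tr)
  fit <- fit_bdl(bt, "birthDeath")
  oracle <- ape::birthdeath(tr)
  expect_equal(fit$logL, -oracle$dev / 2, tolerance = 1e-4)
  expect_equal(unname(fit$params["a"]), unname(oracle$para[1]),
               tolerance = 1e-2)
  expect_equal(unname(fit$params["r"]), unname(oracle$para[2]),
               tolerance = 1e-2)
})

test_that("DDX at x = 0 reduces to pure birth", {
  tr <- simulate_yule_shift_tree(1, n_tips = 50, seed = 83)
  st <- museomics:::bt_stats(branching_times(tr))
  r <- st$E / st$S
  ll_pb <- museomics:::loglik_pure_birth(st, r)
  ll_ddx0 <- museomics:::loglik_rate_fn(st, function(k) r * k^0)
  expect_lt(abs(ll_pb - ll_ddx0), 1e-8)
})

test_that("model nestings hold at the optimum", {
  for (s in 1:3) {
    tr <- simulate_yule_shift_tree(0.8, n_tips = 60, seed = 90 + s)
    bt <- branching_times(tr)
    pb <- fit_bdl(bt, "pureBirth")$logL
    y2 <- fit_bdl(bt, "yule2rate")$logL
    y3 <- fit_bdl(bt, "yule3rate")$logL
    bd <- fit_bdl(bt, "birthDeath")$logL
    ddx <- fit_bdl(bt, "DDX")$logL
    expect_gte(y2, pb - 1e-9)
    expect_gte(y3, y2 - 1e-9)
    expect_gte(bd, pb - 1e-6)
    expect_gte(ddx, pb - 1e-6)
  }
})

test_that("reported maxima are local optima under rate perturbation", {
  tr <- simulate_yule_shift_tree(0.7, n_tips = 60, seed = 95)
  bt <- branching_times(tr)
  st <- museomics:::bt_stats(bt)
  pb <- fit_bdl(bt, "pureBirth")
  for (f in c(0.9, 1.1))
    expect_lt(museomics:::loglik_pure_birth(st, pb$params[["r"]] * f),
              pb$logL)
  ddx <- fit_bdl(bt, "DDX")
  for (f in c(0.9, 1.1))
    expect_lte(museomics:::loglik_rate_fn(st, function(k)
      ddx$params[["r0"]] * f * k^(-ddx$params[["x"]])), ddx$logL + 1e-9)
})

test_that("AIC is reconstructed from the stored log-likelihood and dimension", {
  tr <- simulate_yule_shift_tree(1, n_tips = 40, seed = 96)
  bt <- branching_times(tr)
  for (m in museomics::BDL_MODELS) {
    fit <- fit_bdl(bt, m)
    expect_equal(fit$AIC, 2 * fit$n_params - 2 * fit$logL)
  }
})

test_that("the waiting-time likelihood matches direct density evaluation on a 5-tip tree", {
  ## hand-built ultrametric 5-tip tree with ages 4, 3, 2, 1
  bt <- structure(list(ages = c(4, 3, 2, 1), n_tips = 5L),
                  class = "branching_times")
  st <- museomics:::bt_stats(bt)
  r <- 0.37
  ## direct evaluation: product over intervals of k r exp(-k r w), times the
  ## censored terminal survival exp(-n r w_last)
  direct <- log(2 * r) + (-2 * r * (4 - 3)) +
    log(3 * r) + (-3 * r * (3 - 2)) +
    log(4 * r) + (-4 * r * (2 - 1)) +
    (-5 * r * 1)
  expect_equal(museomics:::loglik_pure_birth(st, r), direct,
               tolerance = 1e-8)
})

test_that("yule2rate recovers a threefold rate shift", {
  set.seed(101)
  ratio <- vapply(1:30, function(i) {
    tr <- simulate_yule_shift_tree(c(1, 3), shift_times = 3,
                                   n_tips = 150, seed = 1100 + i)
    fit <- fit_bdl(branching_times(tr), "yule2rate")
    fit$params[["r2"]] / fit$params[["r1"]]
  }, numeric(1))
  expect_gte(mean(ratio >= 2 & ratio <= 4.5), 0.8)
})

test_that("model selection computes the rate-constant vs rate-variable AIC gap", {
  tr <- simulate_yule_shift_tree(1, n_tips = 60, seed = 102)
  sel <- model_select(branching_times(tr))
  aic <- sel$table$AIC
  names(aic) <- sel$table$model
  expect_equal(sel$delta_AIC_RC,
               min(aic[c("pureBirth", "birthDeath")]) -
                 min(aic[c("DDL", "DDX", "yule2rate", "yule3rate")]))
  expect_equal(sel$best_model, sel$table$model[which.min(aic)])
})

test_that("strong two-shift simulations prefer yule3rate", {
  wins <- vapply(1:20, function(i) {
    tr <- simulate_yule_shift_tree(c(0.4, 2, 0.4), shift_times = c(2.5, 4),
                                   n_tips = 150, seed = 1200 + i)
    model_select(branching_times(tr))$best_model == "yule3rate"
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("a zero observed shift statistic is never significant", {
  tr <- simulate_yule_shift_tree(1, n_tips = 30, seed = 103)
  bt <- branching_times(tr)
  ss <- shift_significance(bt, n_boot = 120, seed = 104)
  if (ss$observed <= 0) expect_gte(ss$p_value, 0.5)
  expect_true(ss$p_value >= 0 && ss$p_value <= 1)
  expect_false(ss$low_boot_warning)
  ss2 <- shift_significance(bt, n_boot = 50, seed = 105)
  expect_true(ss2$low_boot_warning)
})

test_that("strongly shifted trees reach small bootstrap p-values", {
  tr <- simulate_yule_shift_tree(c(0.3, 2.4), shift_times = 3.5,
                                 n_tips = 120, seed = 106)
  ss <- shift_significance(branching_times(tr), n_boot = 150, seed = 107)
  expect_lt(ss$p_value, 0.05)
})
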