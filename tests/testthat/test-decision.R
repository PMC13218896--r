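test_that("control calibration reproduces the utility anchors", {
  u <- utility_params()
  expect_equal(utility(79, u), 50)
  expect_equal(utility(-48, u), -50)
  expect_equal(utility(0, u), 0)
})

test_that("high agency amplifies gains more than losses", {
  u <- utility_params()
  hi <- agency_context(0.85)
  expect_equal(utility(79, u, hi), 69)
  expect_equal(utility(-48, u, hi), -53)
  # asymmetry holds for every positive outcome and every level above control
  ctrl <- agency_context(0.35)
  for (A in c(0.5, 0.65, 0.85, 1)) {
    ctx <- agency_context(A)
    for (x in c(1, 5, 20, 48, 79, 200)) {
      dg <- utility(x, u, ctx) - utility(x, u, ctrl)
      dl <- -(utility(-x, u, ctx) - utility(-x, u, ctrl))
      expect_gt(dg, 0)
      expect_gte(dl, 0)
      expect_lt(dl, dg)
    }
  }
  # below control the curves do not shrink
  expect_equal(utility(79, u, agency_context(0.1)), 50)
})

test_that("the coin-toss gamble flips from indifference to acceptance with agency", {
  g <- gamble(c(79, -48), c(0.5, 0.5))
  expect_equal(expected_utility(g, ctx = agency_context(0.35)), 0,
               tolerance = 1e-9)
  expect_equal(expected_utility(g, ctx = agency_context(0.85)), 8,
               tolerance = 1e-9)
  expect_equal(accept_gamble(g, ctx = agency_context(0.35)), "indifferent")
  expect_equal(accept_gamble(g, ctx = agency_context(0.85)), "accept")
  # reduce the win to 70: rejected under control
  g70 <- gamble(c(70, -48), c(0.5, 0.5))
  expect_lt(expected_utility(g70, ctx = agency_context(0.35)), 0)
  expect_equal(accept_gamble(g70, ctx = agency_context(0.35)), "reject")
  # sure thing equals its utility
  sure <- gamble(30, 1)
  expect_equal(expected_utility(sure), utility(30))
})

test_that("probability weighting has fixed endpoints and the inverse-S shape", {
  w <- prob_weight_params(0.6, mode = "one_parameter_weighting")
  expect_equal(probability_weight(0, w), 0)
  expect_equal(probability_weight(1, w), 1)
  expect_gt(probability_weight(0.01, w), 0.01)
  expect_lt(probability_weight(0.99, w), 0.99)
  p <- seq(0, 1, 0.01)
  expect_true(all(diff(probability_weight(p, w)) > 0))
  # gamma = 1 is the identity
  w1 <- prob_weight_params(1, mode = "one_parameter_weighting")
  expect_equal(probability_weight(p, w1), p)
  expect_equal(probability_weight(p, prob_weight_params()), p)  # identity mode
  expect_error(probability_weight(1.2, w), "\\[0, 1\\]")
  # DA modulation shifts the effective distortion
  wda <- prob_weight_params(0.6, da_modulation = 0.2,
                            mode = "one_parameter_weighting")
  hi_da <- agency_context(0.85, tonic_da = 1.8)
  expect_gt(probability_weight(0.01, wda, agency_context(0.35, tonic_da = 1)),
            probability_weight(0.01, wda, hi_da))
})

test_that("weighted utility reduces to standard expected utility under identity", {
  set.seed(4)
  u <- utility_params()
  for (i in 1:20) {
    vals <- round(runif(3, -100, 100), 1)
    pr <- diff(sort(c(0, runif(2), 1)))
    g <- gamble(vals, pr)
    manual <- sum(pr * utility(vals, u))
    expect_equal(expected_utility(g, u), manual, tolerance = 1e-12)
  }
})

test_that("hyperbolic discounting obeys its closed form and limits", {
  expect_identical(discount_factor(0, 1), 1)
  expect_equal(discount_factor(1, 1), 0.5)
  expect_equal(discount_factor(30, 0.1), 0.25)
  t <- seq(0, 200, 1)
  D <- discount_factor(t, 0.05)
  expect_true(all(diff(D) < 0))
  expect_true(all(D <= 1))
  expect_lt(discount_factor(1e9, 0.05), 1e-6)
  expect_error(discount_factor(-1, 1), "non-negative")
})

test_that("discounting is U-shaped in tonic DA", {
  dp <- discount_params()
  expect_equal(alpha_from_da(dp$da_optimum, dp), dp$alpha_min)
  below <- seq(0, dp$da_optimum, length.out = 10)
  expect_true(all(diff(alpha_from_da(below, dp)) < 0))
  above <- seq(dp$da_optimum, 3, length.out = 10)
  expect_true(all(diff(alpha_from_da(above, dp)) > 0))
  expect_error(alpha_from_da(-1, dp), "non-negative")
})

test_that("delayed choice switches at the analytic indifference alpha", {
  u <- utility_params()
  ctx <- agency_context(0.35)
  sooner <- c(50, 0)
  later <- c(80, 10)
  us <- utility(sooner[1], u, ctx)
  ul <- utility(later[1], u, ctx)
  a_star <- indifference_alpha(us, ul, sooner[2], later[2])
  ch_lo <- choose_delayed(sooner, later,
                          dparams = discount_params(alpha = a_star * 0.9),
                          ctx = ctx)
  ch_hi <- choose_delayed(sooner, later,
                          dparams = discount_params(alpha = a_star * 1.1),
                          ctx = ctx)
  expect_equal(as.character(ch_lo), "later")
  expect_equal(as.character(ch_hi), "sooner")
  # ties go to the impulsive (sooner) option
  ch_tie <- choose_delayed(sooner, later,
                           dparams = discount_params(alpha = a_star),
                           ctx = ctx)
  expect_equal(as.character(ch_tie), "sooner")
  expect_error(choose_delayed(c(50, 5), c(80, 5)), "longer delay")
})

test_that("a common front-end delay can reverse preference (hyperbolic signature)", {
  u <- utility_params()
  ctx <- agency_context(0.35)
  dp <- discount_params(alpha = 0.2)
  soon <- c(50, 0); late <- c(80, 10)
  expect_equal(as.character(choose_delayed(soon, late, u, dp, ctx)),
               "sooner")
  shift <- 20
  expect_equal(as.character(choose_delayed(soon + c(0, shift),
                                           late + c(0, shift), u, dp, ctx)),
               "later")
})

test_that("circuit-coupled contexts shift delayed choice toward patience", {
  # tonic DA below the optimum: raising agency raises DA, lowers alpha,
  # and increases later-larger choices over a standard pair battery
  dp <- discount_params()
  battery <- list(list(c(30, 0), c(45, 15)), list(c(50, 0), c(80, 20)),
                  list(c(20, 0), c(26, 10)), list(c(60, 0), c(75, 25)),
                  list(c(10, 0), c(18, 30)))
  frac_later <- function(da) {
    ctx <- agency_context(if (da > 1) 0.85 else 0.35, tonic_da = da)
    mean(vapply(battery, function(pr)
      choose_delayed(pr[[1]], pr[[2]], dparams = dp, ctx = ctx) == "later",
      TRUE))
  }
  expect_gt(frac_later(1.4), frac_later(0.9))
})

test_that("gamble construction is validated", {
  expect_error(gamble(c(1, 2), c(0.6, 0.5)), "sum to 1")
  expect_error(gamble(c(1, 2), c(1.2, -0.2)), "\\[0, 1\\]")
  expect_error(gamble(c(1, 2), c(0.5, 0.5), delays = c(-1, 0)),
               "non-negative")
  expect_error(agency_context(0.85, gain_multiplier = 1,
                              loss_multiplier = 1.2), "at least")
})
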