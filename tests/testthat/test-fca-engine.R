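fx <- simulated_nine_centers()
P <- fx$centers$size
S <- fx$facilities$size
WB <- fx$weights$binary
WS <- fx$weights$stepwise

test_that("step 1 aggregates demand as population times weight", {
  expect_equal(unname(fca_step1_demand(P, WB)$facility_demand),
               c(1500, 4250, 4000))
  expect_equal(unname(fca_step1_demand(P, WS)$facility_demand),
               c(631.5, 1834, 1850))
  expect_equal(unname(fca_step1_demand(P, WB * 0)$facility_demand),
               c(0, 0, 0))
  expect_error(fca_step1_demand(c(1, 2), WB), "rows")
})

test_that("level of service divides supply by demand, flagging zero demand", {
  los <- fca_step1_los(S, fca_step1_demand(P, WB))
  expect_equal(round(unname(los$los) * 1000, 3), c(0.667, 0.706, 0.5))
  los2 <- fca_step1_los(c(1, 3, 2), c(747.815, 1891.852, 1860.333))
  expect_equal(round(los2$los * 1000, 3), c(1.337, 1.586, 1.075))
  expect_equal(fca_step1_los(c(10, 10), c(150, 150))$los,
               c(0.067, 0.067), tolerance = 1e-2)
  expect_warning(z <- fca_step1_los(c(1, 1), c(100, 0)),
                 "zero demand")
  expect_equal(z$los[2], 0, ignore_attr = TRUE)
  expect_equal(z$undefined, 2L)
})

test_that("step 2 allocates service by weight and sums rows", {
  los <- fca_step1_los(S, fca_step1_demand(P, WB))
  acc <- fca_step2_accessibility(los, WB)
  a <- unname(acc$accessibility) * 1000
  expect_equal(signif(a[4], 3), 1.87)
  expect_equal(signif(a[5], 3), 1.21)
  expect_equal(rowSums(acc$allocation), acc$accessibility)

  los_s <- fca_step1_los(S, fca_step1_demand(P, WS))
  a_s <- fca_step2_accessibility(los_s, WS)$accessibility * 1000
  expect_equal(signif(unname(a_s)[4], 3), 2.19)

  # column-standardized allocation of the adjusted LOS (balanced step 2)
  Lstar <- c(1.412, 1.532, 1.091) / 1000
  a_b <- fca_step2_accessibility(Lstar, column_standardize(WB))
  expect_equal(round(unname(a_b$accessibility)[c(1, 3)] * 1000, 3),
               c(0.353, 0.700), tolerance = 2e-3)
})

test_that("selection weights are row-normalized shares", {
  G <- fca_selection_weights(rbind(c(0.600, 0.242, 0), c(0, 0.5, 0)))
  expect_equal(G[1, ], c(0.71259, 0.28741, 0), tolerance = 1e-5)
  expect_equal(G[2, ], c(0, 1, 0))
  G2 <- fca_selection_weights(WS)
  expect_equal(unname(rowSums(G2)), rep(1, 9), tolerance = 1e-12)
  # consistent with the 3SFCA demand cell: 250 * 0.71259 * 0.600
  expect_equal(250 * G2[2, 1] * WS[2, 1], 106.89, tolerance = 1e-3)
})

test_that("3SFCA demand and LOS match the worked table", {
  r <- fca_run_weights(P, S, WS, method = "3sfca")
  expect_equal(round(unname(r$demand$facility_demand), 3),
               c(319.228, 834.191, 1007.744))
  expect_equal(round(unname(r$los$los) * 1000, 3), c(3.133, 3.596, 1.985))
})

test_that("M2SFCA keeps step-1 demand and squares the step-2 weights", {
  r <- fca_run_weights(P, S, WS, method = "m2sfca")
  expect_equal(unname(r$demand$facility_demand), c(631.5, 1834, 1850))
  a <- unname(r$accessibility) * 1000
  expect_equal(signif(a[1], 3), 0.0927)
  expect_equal(signif(a[5], 3), 1.55)
  # squared weights never help: dominated by the unadjusted run
  un <- fca_run_weights(P, S, WS, method = "e2sfca")
  expect_true(all(r$accessibility <= un$accessibility + 1e-15))
})

test_that("balanced method reproduces the adjusted tables", {
  rb <- fca_run_weights(P, S, WB, method = "balanced")
  expect_equal(unname(rb$demand$facility_demand),
               c(708.333, 1958.333, 1833.333), tolerance = 1e-6)
  expect_equal(round(unname(rb$los$los) * 1000, 3), c(1.412, 1.532, 1.091))
  expect_equal(round(unname(rb$accessibility) * 1000, 3),
               c(0.353, 0.544, 0.7, 0.7, rep(0.347, 5)), tolerance = 1e-3)

  rs <- fca_run_weights(P, S, WS, method = "balanced")
  expect_equal(round(unname(rs$demand$facility_demand), 3),
               c(747.815, 1891.852, 1860.333))
  expect_equal(round(unname(rs$los$los) * 1000, 3), c(1.337, 1.586, 1.075))
  expect_equal(round(unname(rs$accessibility) * 1000, 3),
               c(0.192, 0.59, 0.569, 0.853, 0.651, 0.348, 0.208, 0.377,
                 0.208), tolerance = 1e-3)
})

test_that("unadjusted mass identity: population-weighted accessibility equals supply", {
  for (W in list(WB, WS)) {
    r <- fca_run_weights(P, S, W, method = "2sfca")
    expect_equal(sum(P * r$accessibility), sum(S), tolerance = 1e-10)
  }
})

test_that("balanced runs conserve population and level of service", {
  for (W in list(WB, WS)) {
    r <- fca_run_weights(P, S, W, method = "balanced")
    expect_equal(sum(r$demand$facility_demand), sum(P), tolerance = 1e-10)
    expect_equal(sum(r$accessibility), sum(r$los$los), tolerance = 1e-12)
  }
})

test_that("balanced binary equals the equal-split brute-force oracle", {
  set.seed(20190627)
  for (rep in 1:25) {
    n <- 6; m <- 4
    B <- random_covered_binary(n, m)
    Pp <- round(runif(n, 50, 2000))
    Ss <- sample(1:5, m, replace = TRUE)
    r <- fca_run_weights(Pp, Ss, B, method = "balanced")
    oracle <- equal_split_oracle(Pp, Ss, B)
    expect_equal(unname(r$demand$facility_demand), oracle$demand)
    expect_equal(unname(r$los$los), oracle$los)
    expect_equal(unname(r$accessibility), oracle$accessibility)
  }
})

test_that("permuting centers or facilities permutes all outputs", {
  pi_c <- sample(9); pi_f <- sample(3)
  r <- fca_run_weights(P, S, WS, method = "balanced")
  rp <- fca_run_weights(P[pi_c], S[pi_f], WS[pi_c, pi_f],
                        method = "balanced")
  expect_equal(unname(rp$accessibility), unname(r$accessibility[pi_c]))
  expect_equal(unname(rp$demand$facility_demand),
               unname(r$demand$facility_demand[pi_f]))
  expect_equal(unname(rp$los$los), unname(r$los$los[pi_f]))
})

test_that("2sfca and e2sfca tags run the same engine", {
  a <- fca_run_weights(P, S, WS, method = "2sfca")
  b <- fca_run_weights(P, S, WS, method = "e2sfca")
  expect_equal(a$accessibility, b$accessibility)
})

test_that("a scenario with costs runs end to end through impedance", {
  sc <- random_scenario(8, 3, seed = 99)
  r <- suppressWarnings(fca_run(sc, "gaussian:20", method = "balanced"))
  covered <- rowSums(impedance_weights(parse_impedance("gaussian:20"),
                                       sc$costs)) > 0
  expect_equal(sum(r$demand$facility_demand),
               sum(sc$centers$size[covered]), tolerance = 1e-10)
  expect_error(fca_run_weights(P, S, WS, method = "huff"), "arg")
})
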