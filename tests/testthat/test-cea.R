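test_that("ICER reproduces the published worked example and dominance labels", {
  # pooled NHS/PSS estimates: 740.11 / 0.0501644 = 14753.7 -> GBP 14,754
  ic <- icer(740.11, 0.0501644)
  expect_equal(ic$label, "value")
  expect_equal(round(ic$ratio), 14754)
  expect_equal(ic$quadrant, "NE")

  # societal: cost-saving and more effective -> dominant
  expect_equal(icer(-568.50, 0.0501644)$label, "dominant")
  expect_equal(icer(-568.50, 0.0501644)$quadrant, "SE")
  expect_equal(icer(500, -0.01)$label, "dominated")
  expect_equal(icer(0, 0.05)$ratio, 0)
  expect_equal(icer(100, 0)$label, "undefined")
  sw <- icer(-100, -0.01)
  expect_true(sw$sw_flag)
  expect_equal(sw$ratio, 10000)
  expect_error(icer(NaN, 0.1), "finite")
})

test_that("INMB matches the published worked example and identities", {
  # 30000 * 0.0501644 - 740.11 = 764.822 -> GBP 765
  expect_equal(round(inmb(740.11, 0.0501644, 30000)), 765)
  expect_equal(inmb(740.11, 0.0501644, 0), -740.11)
  # at lambda = ICER the net benefit is zero
  expect_equal(inmb(740.11, 0.0501644, 740.11 / 0.0501644), 0,
               tolerance = 1e-9)
  # affine in lambda
  l <- c(0, 10000, 20000, 30000)
  v <- inmb(740.11, 0.0501644, l)
  expect_equal(diff(v), rep(10000 * 0.0501644, 3))
  # INMB > 0 iff lambda > ICER when dE > 0
  expect_true(all((v > 0) == (l > 740.11 / 0.0501644)))
  expect_error(inmb(1, 1, -5), "nonnegative")
})

test_that("CEAC is the NMB-sign frequency, ties conservative", {
  dominant <- data.frame(delta_cost = -runif(50, 1, 100),
                         delta_effect = runif(50, 0.01, 0.1))
  cc <- ceac(dominant, c(0, 10000, 30000))
  expect_equal(cc$probability, c(1, 1, 1))

  two <- data.frame(delta_cost = c(-1, 1), delta_effect = c(0.1, 0.1))
  expect_equal(ceac(two, c(0))$probability, 0.5)

  # lambda = 0: probability of being cost-saving
  set.seed(8)
  cloud <- data.frame(delta_cost = rnorm(400, 200, 500),
                      delta_effect = rnorm(400, 0.03, 0.02))
  expect_equal(ceac(cloud, 0)$probability, mean(cloud$delta_cost < 0))

  # enumeration oracle on a random small cloud
  grid <- c(0, 5000, 20000, 50000)
  cc2 <- ceac(cloud, grid)
  oracle <- sapply(grid, function(l)
    sum(l * cloud$delta_effect - cloud$delta_cost > 0) / nrow(cloud))
  expect_equal(cc2$probability, oracle)

  # an NMB of exactly zero counts as not cost-effective
  tie <- data.frame(delta_cost = c(1, 1), delta_effect = c(1e-4, 2e-4))
  expect_equal(ceac(tie, 10000)$probability, 0.5)

  # limiting behaviour: huge lambda -> fraction with positive effect
  expect_equal(ceac(cloud, 1e9)$probability,
               mean(cloud$delta_effect > 0), tolerance = 1e-3)

  expect_error(ceac(cloud[0, ], 0), "empty")
  expect_error(ceac(cloud, c(5, 1)), "increasing")
})

test_that("stacked-cloud CEAC equals the mean of per-imputation CEACs", {
  set.seed(12)
  cloud <- data.frame(imputation = rep(1:4, each = 100),
                      replicate = rep(1:100, 4),
                      delta_cost = rnorm(400, 300, 600),
                      delta_effect = rnorm(400, 0.04, 0.03))
  grid <- seq(0, 40000, 10000)
  stacked <- ceac(cloud, grid)$probability
  per_imp <- sapply(split(cloud, cloud$imputation),
                    function(d) ceac(d, grid)$probability)
  expect_equal(stacked, rowMeans(per_imp))
})

test_that("plane export counts quadrants exactly", {
  dom <- data.frame(delta_cost = -runif(30), delta_effect = runif(30))
  pl <- plane_export(dom, 20000)
  expect_equal(unname(pl$quadrant_shares["SE"]), 1)
  expect_equal(sum(pl$quadrant_shares), 1)

  four <- data.frame(delta_cost = c(1, 1, -1, -1),
                     delta_effect = c(1, -1, 1, -1))
  expect_equal(unname(plane_export(four)$quadrant_shares[c("NE", "NW", "SE", "SW")]),
               rep(0.25, 4))

  set.seed(3)
  cl <- data.frame(delta_cost = rnorm(500), delta_effect = rnorm(500))
  pl2 <- plane_export(cl, 30000)
  brute <- c(NE = sum(cl$delta_cost >= 0 & cl$delta_effect >= 0),
             SE = sum(cl$delta_cost < 0 & cl$delta_effect >= 0),
             NW = sum(cl$delta_cost >= 0 & cl$delta_effect < 0),
             SW = sum(cl$delta_cost < 0 & cl$delta_effect < 0)) / 500
  expect_equal(pl2$quadrant_shares[names(brute)], brute)
  expect_equal(sum(pl2$quadrant_shares), 1)

  # boundary points land north/east by convention, shares still sum to 1
  bnd <- data.frame(delta_cost = c(0, 0, 1, -1),
                    delta_effect = c(1, -1, 0, 0))
  shares <- plane_export(bnd)$quadrant_shares
  expect_equal(sum(shares), 1)
  expect_equal(unname(shares["NE"]), 0.5)   # (0,1) and (1,0)

  # NMB-line probability consistent with the CEAC at the same threshold
  expect_equal(pl2$prob_below_lambda_line, ceac(cl, 30000)$probability)
  expect_error(plane_export(cl[0, ]), "empty")

  cp <- tempfile(fileext = ".csv")
  write_ceac(ceac(cl, c(0, 1000)), cp)
  expect_equal(nrow(read.csv(cp)), 2L)
})
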