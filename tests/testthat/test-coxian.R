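test_that("a single-state model reduces to the exponential distribution", {
  m <- coxian(100)
  expect_equal(coxian_survival(m, 100), exp(-1), tolerance = 1e-12)
  expect_equal(coxian_survival(m, 0), 1)
  expect_equal(coxian_density(m, 0), 1 / 100)
  expect_equal(coxian_density(m, 50), exp(-0.5) / 100, tolerance = 1e-12)
  expect_equal(coxian_quantile(m, 0.5), 100 * log(2), tolerance = 1e-5)
  expect_equal(mean(m), 100)
  # memorylessness: conditional survival ignores elapsed time
  expect_equal(conditional_survival(m, 500, 30), coxian_survival(m, 30),
               tolerance = 1e-10)
})

test_that("constructor rejects invalid models", {
  expect_error(coxian(c(100, 50), 0.3), "increasing")
  expect_error(coxian(c(-5, 50), 0.3), "positive")
  expect_error(coxian(c(10, 50), 1.3), "\\[0, 1\\]")
  expect_error(coxian(c(10, 50), c(0.1, 0.2)), "length")
  expect_error(coxian_survival(coxian(10), -1), ">= 0")
  expect_error(coxian_quantile(coxian(10), 1.5), "between 0 and 1")
})

test_that("closed-form survival and density match the matrix-exponential oracle", {
  set.seed(11)
  for (k in c(1, 2, 3, 4)) {
    m <- random_coxian(k)
    tgrid <- c(0, exp(seq(log(0.5), log(20 * max(m$state_means)),
                          length.out = 25)))
    expect_lt(max(abs(coxian_survival(m, tgrid) - oracle_survival(m, tgrid))),
              1e-8)
    fd <- oracle_density(m, tgrid)
    expect_lt(max(abs(coxian_density(m, tgrid) - fd) / (1 + fd)), 1e-8)
  }
})

test_that("density is the negative derivative of survival and integrates to one", {
  set.seed(12)
  for (rep in 1:3) {
    m <- random_coxian(3)
    tgrid <- seq(1, 5 * max(m$state_means), length.out = 20)
    h <- 1e-4
    fd <- (coxian_survival(m, tgrid) - coxian_survival(m, tgrid + h)) / h
    expect_equal(coxian_density(m, tgrid), fd, tolerance = 1e-5)
    total <- stats::integrate(function(t) coxian_density(m, t), 0, Inf,
                              rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("survival is a proper non-increasing survivor function", {
  set.seed(13)
  for (rep in 1:5) {
    m <- random_coxian(sample(1:4, 1))
    tgrid <- c(0, exp(seq(log(0.1), log(50 * max(m$state_means)),
                          length.out = 60)))
    S <- coxian_survival(m, tgrid)
    expect_equal(S[1], 1)
    expect_true(all(diff(S) <= 1e-12))
    expect_true(all(S >= 0 & S <= 1))
    expect_lt(S[length(S)], 1e-6)
  }
})

test_that("quantile inverts the survival function", {
  set.seed(14)
  for (rep in 1:4) {
    m <- random_coxian(3)
    for (p in c(0.9, 0.5, 0.2, 0.05)) {
      t <- coxian_quantile(m, p)
      expect_equal(coxian_survival(m, t), p, tolerance = 1e-6)
    }
  }
})

test_that("mean length of stay equals the continuation-weighted closed form and the integral of survival", {
  # London placement parameters: 25 + 0.646*157 + 0.646*0.595*2053
  m <- london_placement()
  expect_equal(mean(m), 25 + 0.646 * 157 + 0.646 * 0.595 * 2053,
               tolerance = 1e-12)
  set.seed(15)
  for (rep in 1:3) {
    mm <- random_coxian(3)
    byquad <- stats::integrate(function(t) coxian_survival(mm, t), 0, Inf,
                               rel.tol = 1e-8)$value
    expect_equal(mean(mm), byquad, tolerance = 1e-4)
  }
})

test_that("near-equal state rates use the matrix-exponential fallback correctly", {
  m <- coxian(c(100, 100 * (1 + 1e-9)), 0.3)
  # equal-rate limit: mixture of Exp(lambda) and Erlang(2, lambda)
  lam <- 1 / 100
  tgrid <- c(1, 50, 150, 600)
  ref <- 0.3 * exp(-lam * tgrid) + 0.7 * (1 + lam * tgrid) * exp(-lam * tgrid)
  expect_equal(coxian_survival(m, tgrid), ref, tolerance = 1e-6)
  # well-separated rates: both paths agree tightly
  m2 <- coxian(c(30, 300), 0.4)
  expect_lt(max(abs(coxian_survival(m2, tgrid) - oracle_survival(m2, tgrid))),
            1e-10)
})

test_that("reach probabilities multiply continuation chances", {
  expect_equal(reach_probabilities(c(0.313, 0.476)),
               c(1, 0.687, 0.687 * 0.524), tolerance = 1e-12)
  expect_equal(reach_probabilities(c(0.603, 0.678)),
               c(1, 0.397, 0.397 * 0.322), tolerance = 1e-12)
  expect_equal(reach_probabilities(c(1, 0.5)), c(1, 0, 0))
  m <- london_placement()
  expect_true(all(diff(reach_probabilities(m)) <= 0))
  expect_equal(reach_probabilities(m)[1], 1)
})

test_that("all-discharge model degenerates to the first-state exponential", {
  m <- coxian(c(25, 157, 2053), c(1, 1))
  e <- coxian(25)
  tgrid <- c(0, 5, 25, 100, 400)
  expect_equal(coxian_survival(m, tgrid), coxian_survival(e, tgrid),
               tolerance = 1e-12)
  expect_equal(coxian_density(m, tgrid), coxian_density(e, tgrid),
               tolerance = 1e-12)
  expect_equal(mean(m), 25)
  expect_equal(coxian_quantile(m, 0.3), coxian_quantile(e, 0.3),
               tolerance = 1e-6)
})

test_that("conditional survival equals the ratio of survivals", {
  set.seed(16)
  m <- random_coxian(3)
  for (a in c(0, 10, 500)) {
    for (x in c(0, 30, 365)) {
      expect_equal(conditional_survival(m, a, x),
                   oracle_survival(m, a + x) / oracle_survival(m, a),
                   tolerance = 1e-8)
    }
  }
  expect_equal(conditional_survival(m, 0, 90), coxian_survival(m, 90))
  expect_error(conditional_survival(london_placement(), 3e6, 30),
               "numerically zero")
})

test_that("simulation is reproducible and matches the analytic distribution", {
  m <- london_placement()
  expect_identical(simulate(m, 100, seed = 5), simulate(m, 100, seed = 5))
  set.seed(17)
  x <- simulate(m, 1e4)
  ks <- suppressWarnings(
    stats::ks.test(x, function(q) 1 - coxian_survival(m, q)))
  expect_gt(ks$p.value, 0.01)
  # survivor fraction past the fitted median
  set.seed(18)
  y <- simulate(m, 1e5)
  frac <- mean(y > 148)
  expect_lt(abs(frac - coxian_survival(m, 148)), 3 * sqrt(0.25 / 1e5))
  expect_lt(abs(frac - 0.5), 0.01)
  # CLT check on a single exponential state
  set.seed(19)
  z <- simulate(coxian(100), 1e5)
  expect_lt(abs(mean(z) - 100), 3 * 100 / sqrt(1e5))
})

test_that("JSON serialization round-trips losslessly", {
  m <- coxian(c(17.25, 111.5, 2083.125), c(0.354321, 0.405678),
              label = "Placement/PF")
  path <- tempfile(fileext = ".json")
  coxian_to_json(m, path)
  m2 <- coxian_from_json(path)
  expect_identical(m2$state_means, m$state_means)
  expect_identical(m2$discharge_probs, m$discharge_probs)
  expect_identical(m2$label, m$label)
  # k = 1 model with no discharge_probs survives the trip too
  m3 <- coxian_from_json(coxian_to_json(coxian(42)))
  expect_identical(m3$state_means, 42)
  expect_equal(m3$k, 1L)
})

test_that("state table mirrors the state-and-arrow diagram", {
  tab <- state_table(london_placement())
  expect_equal(tab$state, c("short-stay", "medium-stay", "long-stay"))
  expect_equal(tab$mean_days, c(25, 157, 2053))
  expect_equal(tab$discharge_prob, c(0.354, 0.405, 1))
  expect_equal(tab$continue_prob, c(0.646, 0.595, 0))
  expect_equal(tab$reach_prob, c(1, 0.646, 0.646 * 0.595))
})
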