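test_that("growth formulas match direct arithmetic", {
  r <- growth_records("CF5", n_start = 100, n_dead = 0,
                      start_weight = 610, end_weight = 11550,
                      feed_consumed = 25000, days = 35)
  expect_equal(lwgpl(r), 109.4)

  r2 <- growth_records("CF5", 100, 2, 610, 11550, 25000, 35)
  expect_equal(lwgpl(r2), (11550 - 610) / 98, tolerance = 1e-12)

  # no gain, feed = gain, survival examples
  flatr <- growth_records("x", 100, 0, 500, 500, 1, 35)
  expect_equal(lwgpl(flatr), 0)
  even <- growth_records("x", 10, 0, 100, 200, 100, 35)
  expect_equal(fcr(even), 1)
  expect_equal(eci(even), 100)
  expect_equal(survival_rate(growth_records("x", 100, 0, 1, 2, 1, 1)), 100)
  expect_equal(survival_rate(growth_records("x", 100, 1, 1, 2, 1, 1)), 99)

  # FCR 4.1 corresponds to ECI 24.39%
  hp <- growth_records("HPF8", 100, 1, 610, 1610, 4100, 35)
  expect_equal(fcr(hp), 4.1, tolerance = 1e-9)
  expect_equal(eci(hp), 100 / 4.1, tolerance = 1e-9)
  expect_equal(round(eci(hp), 2), 24.39)

  expect_error(lwgpl(growth_records("x", 5, 5, 1, 2, 1, 1)), "surviving")
  expect_error(fcr(flatr), "gained")
})

test_that("specific growth rate uses log mean body weights per day", {
  # 6.1 mg -> 115.5 mg per larva over 35 days
  r <- growth_records("FSF5", 100, 0, 610, 11550, 25000, 35)
  expect_equal(sgr(r), 100 * (log(115.5) - log(6.1)) / 35,
               tolerance = 1e-12)
  expect_equal(round(sgr(r), 2), 8.40)

  # no growth -> 0; doubling over ln(2)*100 days -> 1 %/day
  expect_equal(sgr(growth_records("x", 10, 0, 50, 50, 1, 20)), 0)
  expect_equal(sgr(growth_records("x", 10, 0, 50, 100, 1, log(2) * 100)), 1,
               tolerance = 1e-12)

  # scale invariance: mg vs g changes nothing
  rg <- growth_records("FSF5", 100, 0, 0.610, 11.550, 25, 35)
  expect_equal(sgr(rg), sgr(r), tolerance = 1e-12)
  # lwgpl scales linearly with the weight unit
  expect_equal(lwgpl(rg) * 1000, lwgpl(r), tolerance = 1e-9)

  expect_error(sgr(growth_records("x", 10, 0, 0, 5, 1, 10)), "> 0")
})

test_that("ECI equals 100/FCR for 1000 seeded records", {
  set.seed(8)
  n <- 1000
  start <- runif(n, 400, 800)
  gain <- runif(n, 1000, 12000)
  rec <- growth_records(sprintf("g%04d", 1:n),
                        n_start = sample(50:150, n, replace = TRUE),
                        n_dead = sample(0:5, n, replace = TRUE),
                        start_weight = start,
                        end_weight = start + gain,
                        feed_consumed = runif(n, 5000, 50000),
                        days = 35)
  expect_lt(max(abs(fcr(rec) * eci(rec) - 100)), 1e-9)
  m <- growth_metrics(rec)
  expect_equal(m$lwgpl, gain / (rec$n_start - rec$n_dead), tolerance = 1e-12)
  expect_equal(m$sgr,
               100 * log((rec$end_weight / (rec$n_start - rec$n_dead)) /
                           (rec$start_weight / rec$n_start)) / 35,
               tolerance = 1e-12)
  expect_true(all(m$survival >= 0 & m$survival <= 100))
})

test_that("nutrient mixing is fraction-weighted and invertible", {
  form <- data.frame(name = c("substrate", "bran"), fraction = c(1, 0),
                     fat = c(27, 4.7), protein = c(8, 15))
  expect_equal(mix_nutrients(form), c(fat = 27, protein = 8))

  form$fraction <- c(0.5, 0.5)
  form$fat <- c(10, 20)
  expect_equal(mix_nutrients(form)[["fat"]], 15)

  # 46.2% substrate (fat 27.0) + 53.8% wheat bran (fat 4.7) -> 15.0% diet
  mix <- mix_nutrients(data.frame(name = c("cf", "wb"),
                                  fraction = c(0.462, 0.538),
                                  fat = c(27.0, 4.7)))
  expect_equal(round(mix[["fat"]], 1), 15.0)

  expect_error(mix_nutrients(data.frame(name = "a", fraction = 0.9,
                                        fat = 1)), "sum to 1")
})

test_that("inclusion solving inverts the mixing model", {
  expect_equal(solve_inclusion(4.7, 27, 4.7), 0)

  # component fat contents recovered from the 10% and 15% coconut diets
  comp <- solve_component_values(c(0.238, 10.0), c(0.462, 15.0))
  expect_equal(comp[["substrate"]], 27.01, tolerance = 0.01)
  expect_equal(comp[["base"]], 4.69, tolerance = 0.01)
  # ... predict the 20% diet inclusion printed as 68.6%
  expect_equal(100 * solve_inclusion(20, comp[["substrate"]],
                                     comp[["base"]]),
               68.6, tolerance = 0.05)

  # flaxseed series: FSF10/FSF15 rows predict the printed FSF20 54.1%
  fcomp <- solve_component_values(c(0.187, 10.0), c(0.364, 15.0))
  expect_equal(100 * solve_inclusion(20, fcomp[["substrate"]],
                                     fcomp[["base"]]),
               54.1, tolerance = 0.05)

  # pure components are returned as-is
  expect_equal(solve_component_values(c(0, 4.7), c(1, 27)),
               c(substrate = 27, base = 4.7))

  # mix_nutrients and solve_inclusion are mutual inverses
  set.seed(9)
  for (i in 1:20) {
    s <- runif(1, 10, 40); b <- runif(1, 1, 9); p <- runif(1)
    target <- mix_nutrients(data.frame(name = c("s", "b"),
                                       fraction = c(p, 1 - p),
                                       fat = c(s, b)))[["fat"]]
    expect_lt(abs(solve_inclusion(target, s, b) - p), 1e-9)
  }

  expect_error(solve_inclusion(30, 27, 4.7), "outside")
  expect_error(solve_component_values(c(0.3, 10), c(0.3, 12)), "singular")
  expect_error(solve_inclusion(5, 8, 8), "undetermined")
})
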