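get_cost <- function(df, p, col) df[[col]][df$protocol == p]

test_that("first-survey totals reproduce the published wage extremes", {
  prof <- fixture_profiles()
  at <- function(p, h) {
    get_cost(total_cost(prof, r = 0.2, h = h, m = 1), p, "total_cost")
  }
  expect_equal(at("LI", 0), 4700)
  expect_equal(at("LI", 55), 17845)
  expect_equal(at("CT-74", 0), 27482)
  expect_equal(at("CT-74", 55), 29737)
})

test_that("first-survey cost is independent of the replacement rate", {
  prof <- fixture_profiles()
  t_low <- total_cost(prof, r = 0, h = 20, m = 1)
  t_high <- total_cost(prof, r = 1, h = 20, m = 1)
  expect_equal(t_low$total_cost, t_high$total_cost)
  # and at h = 0 it is E + V + C + v for every protocol
  t0 <- total_cost(prof, r = 0.5, h = 0, m = 1)
  expect_equal(t0$total_cost,
               prof$equipment + prof$vehicle + prof$consumables +
                 prof$deploy_vehicle)
})

test_that("marginal cost evaluates the published formula exactly", {
  prof <- fixture_profiles()
  expect_equal(
    get_cost(marginal_cost(prof, r = 0, h = 0), "CT-74", "marginal_cost"),
    900 # V + C = 400 + 500
  )
  expect_equal(
    get_cost(marginal_cost(prof, r = 0.045, h = 33), "LI", "marginal_cost"),
    0.045 * 2280 + 2000 + 120 + 33 * 184 # = 8294.6
  )
})

test_that("marginal cost is the increment of total cost at every m", {
  set.seed(21)
  for (rep in 1:20) {
    prof <- tibble::tibble(
      protocol = "CT-74", equipment = runif(1, 0, 5e4),
      vehicle = runif(1, 0, 5e3), consumables = runif(1, 0, 2e3),
      labour_h = runif(1, 0, 300), deploy_labour_h = runif(1, 0, 100),
      deploy_vehicle = runif(1, 0, 1e3)
    )
    r <- runif(1); h <- runif(1, 0, 60); m <- sample(1:20, 1)
    diff <- total_cost(prof, r, h, m + 1)$total_cost -
      total_cost(prof, r, h, m)$total_cost
    expect_equal(diff, marginal_cost(prof, r, h)$marginal_cost)
  }
})

test_that("scenario grids have the published extents", {
  full <- scenario_grid("full")
  expect_equal(nrow(full), 31 * 56)
  expect_equal(range(full$r), c(0, 0.30))
  expect_equal(range(full$h), c(0, 55))
  realistic <- scenario_grid("realistic")
  expect_equal(nrow(realistic), 10 * 45)
  expect_equal(range(realistic$r), c(0, 0.09))
  expect_equal(range(realistic$h), c(11, 55))
  expect_error(scenario_grid("custom", r_values = numeric(0), h_values = 1),
               "non-empty")
  # a zero step size collapses the grid onto repeated values
  expect_error(scenario_grid("custom", r_values = rep(0.05, 3),
                             h_values = 1), "distinct")
})

test_that("grid summaries follow the affine closed forms", {
  prof <- fixture_profiles()
  grid <- scenario_grid("full")
  summ <- scenario_summary(prof, grid)
  for (p in protocol_levels()) {
    row <- prof[prof$protocol == p, ]
    # the marginal-cost formula is affine in (r, h), so the grid mean is the
    # formula at the grid means ...
    expect_equal(get_cost(summ, p, "mean"),
                 mean(grid$r) * row$equipment + row$vehicle +
                   row$consumables + mean(grid$h) * row$labour_h)
    # ... and for an independent rectangular grid the SD decomposes
    var_pop <- function(x) mean((x - mean(x))^2)
    expect_equal(get_cost(summ, p, "sd"),
                 sqrt(row$equipment^2 * var_pop(unique(grid$r)) +
                        row$labour_h^2 * var_pop(unique(grid$h))))
  }
  # published CT-74 headline numbers at the table's rounding
  expect_equal(get_cost(summ, "CT-74", "mean"), 6014, tolerance = 1 / 6014)
  expect_equal(get_cost(summ, "CT-74", "sd"), 2469, tolerance = 1 / 2469)
})

test_that("marginal cost is monotone in replacement rate and wage", {
  prof <- fixture_profiles()
  base <- marginal_cost(prof, r = 0.1, h = 20)$marginal_cost
  expect_true(all(marginal_cost(prof, r = 0.2, h = 20)$marginal_cost >= base))
  expect_true(all(marginal_cost(prof, r = 0.1, h = 40)$marginal_cost >= base))
})

test_that("degenerate grids summarise sensibly", {
  prof <- fixture_profiles()
  single <- scenario_grid("custom", r_values = 0.05, h_values = 30)
  summ <- scenario_summary(prof, single)
  expect_equal(summ$mean,
               marginal_cost(prof, r = 0.05, h = 30)$marginal_cost)
  expect_equal(summ$sd, rep(0, 7))
  empty <- scenario_grid("full")[0, ]
  expect_error(marginal_cost_grid(prof, empty), "empty")
})
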