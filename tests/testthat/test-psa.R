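fake_draws <- function(dc, dq, comparison = "BRF_vs_TAU") {
  structure(
    tibble::tibble(b = seq_along(dc), comparison = comparison,
                   delta_cost = dc, delta_qaly = dq),
    class = c("ce_draws", "tbl_df", "tbl", "data.frame")
  )
}

test_that("net benefit follows its closed form", {
  expect_equal(net_benefit(0, 0.02, 150), -150)
  expect_equal(net_benefit(20000, 0.0159, 319), 20000 * 0.0159 - 319)  # -1
  expect_equal(net_benefit(c(0, 1e5), 0, 0), c(0, 0))
  expect_error(net_benefit(-5, 0.1, 0), "lambda")
  # incremental NB equals the difference of absolute arm net benefits
  lam <- 30000
  expect_equal(net_benefit(lam, 0.31, 4100) - net_benefit(lam, 0.29, 4300),
               net_benefit(lam, 0.31 - 0.29, 4100 - 4300))
})

test_that("CEAC probabilities equal brute-force net-benefit counts", {
  # 4 draws engineered to give INB {+1, +2, -1, -3} at lambda = 2000
  dq <- c(0.0015, 0.002, 0.0005, -0.0005)
  dc <- c(2, 2, 2, 2)
  d <- fake_draws(dc, dq)
  cc <- ceac_from_draws(d, lambdas = c(0, 2000))
  p <- cc$probability[cc$lambda == 2000 & cc$option == "AV-BRF"]
  expect_equal(p, 0.5)
  # at lambda 0 INB = -delta_cost < 0 for every draw
  expect_equal(cc$probability[cc$lambda == 0 & cc$option == "AV-BRF"], 0)
  # probabilities across the compared arms sum to 1 at every lambda
  sums <- tapply(cc$probability, cc$lambda, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
  # exact ties split equally
  tied <- fake_draws(c(0, 5), c(0, 0.001))
  ct <- ceac_from_draws(tied, lambdas = 10000)
  expect_equal(ct$probability[ct$option == "AV-BRF"], 0.5 + 0.25)
  expect_error(ceac_from_draws(fake_draws(numeric(0), numeric(0))), "draws")
})

test_that("CEAC limits match plane fractions at lambda 0 and infinity", {
  set.seed(55)
  d <- fake_draws(rnorm(400, 100, 800), rnorm(400, 0.005, 0.02))
  cc <- ceac_from_draws(d, lambdas = c(0, 1e9))
  expect_equal(cc$probability[cc$lambda == 0 & cc$option == "AV-BRF"],
               mean(d$delta_cost < 0))
  expect_equal(cc$probability[cc$lambda == 1e9 & cc$option == "AV-BRF"],
               mean(d$delta_qaly > 0))
  q <- plane_quadrant_summary(d)
  expect_equal(sum(q$fraction), 1)
  expect_equal(q$fraction[q$quadrant == "SE"] + q$fraction[q$quadrant == "SW"],
               mean(d$delta_cost < 0))
})

test_that("quadrant fractions classify engineered draws and split boundaries", {
  d <- fake_draws(c(-10, -10, 5, 0), c(0.01, 0.01, -0.01, 0.02))
  q <- plane_quadrant_summary(d)
  expect_equal(q$fraction[q$quadrant == "SE"], 0.5 + 0.125)  # boundary half
  expect_equal(q$fraction[q$quadrant == "NW"], 0.25)
  expect_equal(sum(q$fraction), 1)
  d2 <- fake_draws(c(-3, -1), c(0.01, 0.02))
  expect_equal(plane_quadrant_summary(d2)$fraction,
               c(0, 0, 1, 0))  # NE, NW, SE, SW
})

test_that("bootstrap draws: count, determinism and degenerate resampling", {
  ds <- sim_dataset(25, seed = 41, effect_cost = 300, effect_qaly = 0.01)
  d7 <- bootstrap_draws(ds, B = 7, seed = 2)
  expect_identical(max(d7$b), 7L)
  expect_identical(nrow(d7), 14L)  # two comparisons per draw

  d7b <- bootstrap_draws(ds, B = 7, seed = 2)
  expect_tables_identical(d7, d7b)
  expect_tables_identical(attr(d7, "arm_means"), attr(d7b, "arm_means"))
  d7c <- bootstrap_draws(ds, B = 7, seed = 3)
  expect_false(identical(d7$delta_cost, d7c$delta_cost))

  # identical rows within each arm: every resample is the same dataset
  one <- ds[c(1, 26, 51), ]
  deg <- dplyr::bind_rows(purrr::map(1:10, ~one))
  deg$participant_id <- sprintf("D%02d", seq_len(nrow(deg)))
  deg$site <- "site1"
  dd <- suppressWarnings(bootstrap_draws(deg, B = 5, seed = 4))
  expect_equal(stats::sd(dd$delta_cost[dd$comparison == "BRF_vs_TAU"]), 0)

  expect_warning(bootstrap_draws(ds, B = 2, seed = 5,
                                 stratify_by_arm = FALSE),
                 "unstratified")
})

test_that("percentile intervals agree with the analytic CI on complete data", {
  ds <- sim_dataset(170, seed = 47, effect_cost = 500, effect_qaly = 0.015)
  inc <- fit_sur_incrementals(ds)
  draws <- bootstrap_draws(ds, B = 600, seed = 8)
  for (cmp in c("BRF_vs_TAU", "EXT_vs_TAU")) {
    b <- draws$delta_cost[draws$comparison == cmp]
    half_boot <- diff(unname(stats::quantile(b, c(0.025, 0.975)))) / 2
    half_analytic <- 1.96 * inc$se_cost[inc$comparison == cmp]
    expect_equal(half_boot, half_analytic, tolerance = 0.10)
  }
})

test_that("three-way ranking CEAC sums to 1 and matches pairwise logic in
           two-option subsets", {
  ds <- sim_dataset(40, seed = 53, effect_cost = -200, effect_qaly = 0.01)
  draws <- bootstrap_draws(ds, B = 60, seed = 12)
  cc3 <- ceac_from_draws(draws, lambdas = c(0, 20000, 1e5),
                         mode = "three_way")
  sums <- tapply(cc3$probability, cc3$lambda, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
  expect_true(all(cc3$probability >= 0 & cc3$probability <= 1))
})
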