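test_that("log-normal fits match the CI-arithmetic closed form", {
  fit <- fit_lognormal(0.86, 0.77, 0.96)
  expect_equal(fit$meanlog, -0.1508229, tolerance = 1e-6)
  expect_equal(fit$sdlog, 0.0562620, tolerance = 1e-6)

  # degenerate CI: all draws equal the point
  deg <- fit_lognormal(0.5, 0.5, 0.5)
  expect_equal(deg$sdlog, 0)
  expect_equal(sample_dist(deg, 5), rep(0.5, 5))

  # mean anchoring shifts the location by half the log-variance
  m <- fit_lognormal(0.86, 0.77, 0.96, anchor = "mean")
  expect_equal(m$meanlog, log(0.86) - m$sdlog^2 / 2)

  expect_error(fit_lognormal(0.86, -0.1, 0.96), "0 < low")
  expect_error(fit_lognormal(0.5, 0.6, 0.7), "0 < low")
})

test_that("beta fits are method-of-moments on possibly shifted supports", {
  fit <- fit_beta(0.824, 0.800, 0.848)
  expect_equal(fit$shape1, 796.146, tolerance = 1e-3)
  expect_equal(fit$shape2, 170.051, tolerance = 1e-3)
  expect_equal(fit$shape1 / (fit$shape1 + fit$shape2), 0.824)

  # an overdispersed CI is infeasible
  expect_error(fit_beta(0.5, -3, 4), "infeasible")

  # disutility on its reflected support keeps the configured mean
  pen <- fit_beta(-0.0003, -0.002, 0, support = c(-0.002, 0))
  set.seed(1)
  x <- sample_dist(pen, 2e5)
  expect_true(all(x >= -0.002 & x <= 0))
  expect_equal(mean(x), -0.0003, tolerance = 2e-2)
})

test_that("the PSA parameter table covers costs, utilities and effects", {
  cfg <- base_config()
  tab <- psa_parameters(cfg, "hr_clinical")
  expect_true("states.CV_DEATH.annual_cost" %in% tab$name)
  expect_true("states.POST_IS.utility" %in% tab$name)
  expect_true("strategies.alirocumab.utility_penalty" %in% tab$name)
  expect_true("effects.alirocumab.hr_clinical.cv_death.point" %in% tab$name)
  # event rates are never sampled
  expect_false(any(grepl("base_rates|growth", tab$name)))
  # families as declared
  expect_true(all(tab$family[grepl("utility", tab$name)] == "beta"))
  expect_true(all(tab$family[grepl("cost|point", tab$name)] == "lognormal"))
})

test_that("fitted distributions reproduce their point values and ranges", {
  res <- check_distribution_fits(base_config(), n = 2e4, seed = 3)
  expect_gt(nrow(res), 15)
  expect_true(all(res$rel_error < 0.005))
  expect_true(all(res$coverage >= 0.93 & res$coverage <= 1))
})

test_that("one-way sweeps hold everything else at base case", {
  cfg <- base_config()
  # endpoints at the base value give zero span
  null_sweep <- one_way_sweep(cfg, "states.POST_IS.utility", 0.524, 0.524)
  expect_equal(null_sweep$span, 0)

  # metadata that the model never reads gives zero span
  meta <- one_way_sweep(cfg, "fatal_event_costs.fatal_mi", 0, 1e5)
  expect_equal(meta$span, 0)

  # a real utility parameter moves the ICER
  u <- one_way_sweep(cfg, "states.EVENT_FREE.utility", 0.800, 0.848)
  expect_gt(u$span, 0)
  expect_error(one_way_sweep(cfg, "states.FOO.utility", 0, 1), "unknown")
})

test_that("the tornado ranks the event-free and post-IS utilities on top", {
  tw <- tornado(base_config())
  top3 <- tw$parameter[1:3]
  expect_true("states.EVENT_FREE.utility" %in% top3)
  expect_true("states.POST_IS.utility" %in% top3)
  expect_equal(tw$span, sort(tw$span, decreasing = TRUE))
  # base-case ICER lies within the endpoint ICERs for the top driver
  cfg <- base_config()
  base_icer <- cea_compare(run_strategy(cfg, "statin"),
                           run_strategy(cfg, "alirocumab"))$icer
  expect_gte(base_icer, min(tw$icer_low[1], tw$icer_high[1]))
  expect_lte(base_icer, max(tw$icer_low[1], tw$icer_high[1]))
})

test_that("the PSA is a pure function of config, seed and draw count", {
  cfg <- base_config()
  a <- run_psa(cfg, n_draws = 25, seed = 42)
  b <- run_psa(cfg, n_draws = 25, seed = 42)
  expect_identical(a$params, b$params)
  expect_identical(a$costs, b$costs)
  expect_identical(a$qalys, b$qalys)
  c <- run_psa(cfg, n_draws = 25, seed = 43)
  expect_false(identical(a$costs, c$costs))
})

test_that("the PSA scatters around the deterministic base case", {
  cfg <- base_config()
  psa <- run_psa(cfg, n_draws = 400, seed = 5)
  det <- cea_compare(run_strategy(cfg, "statin"),
                     run_strategy(cfg, "alirocumab"))
  dc <- psa$costs[, "alirocumab"] - psa$costs[, "statin"]
  dq <- psa$qalys[, "alirocumab"] - psa$qalys[, "statin"]
  # ICER at mean incremental outcomes within 10% of the deterministic run
  expect_lt(abs(mean(dc) / mean(dq) - det$icer) / det$icer, 0.10)
})

test_that("acceptability curves behave at threshold extremes", {
  cfg <- base_config()
  psa <- run_psa(cfg, n_draws = 200, seed = 9)
  dc <- psa$costs[, "alirocumab"] - psa$costs[, "statin"]
  dq <- psa$qalys[, "alirocumab"] - psa$qalys[, "statin"]

  # wtp = 0: the cheaper strategy wins every draw
  cc <- ceac(psa, wtp_grid = 0, type = "multi")
  expect_equal(cc$probability[cc$strategy == "statin"], mean(dc > 0))

  # far beyond any ICER, positive-gain draws favour the add-on
  hi <- ceac(psa, wtp_grid = 1e9, type = "pairwise")
  expect_equal(hi$probability, mean(dq > 0))

  # multi-strategy probabilities partition the draws
  multi <- ceac(psa, wtp_grid = c(0, 2e5, 1e6), type = "multi")
  sums <- tapply(multi$probability, multi$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, 3))

  # pairwise acceptability is non-decreasing in wtp on positive-gain draws
  keep <- dq > 0
  psa_pos <- psa
  psa_pos$costs <- psa$costs[keep, , drop = FALSE]
  psa_pos$qalys <- psa$qalys[keep, , drop = FALSE]
  curve <- ceac(psa_pos, wtp_grid = seq(0, 5e6, by = 5e5),
                type = "pairwise")
  expect_true(all(diff(curve$probability) >= 0))

  expect_error(ceac(psa, wtp_grid = numeric(0)), "empty")
})
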