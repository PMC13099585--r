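kn_test <- c(-1.7, -0.4, 0.3, 1.8)

# planted surface whose pure-temperature curve is a(T - vertex)^2 at e = 0
quad_fit <- function(vertex, a = 1e-3) {
  planted_fit(c(-2 * a * vertex, a, rep(0, 11)), kn_test)
}

test_that("climate bias adjustment removes trend offsets", {
  set.seed(1)
  ob <- data.table(county_id = rep(c("a", "b"), each = 10),
                   year = rep(2005:2014, 2))
  ob[, mean_temp := 10 + 0.02 * (year - 2005) + rnorm(.N, 0, 0.1)]
  daily <- data.table(county_id = rep(c("a", "b"), each = 30),
                      date = rep(as.IDate("2015-01-01") + 0:29, 2),
                      temp = rnorm(60, 12, 3))
  # identical series: zero adjustment
  a0 <- bias_adjust_climate(ob, ob, daily)
  expect_lt(max(abs(attr(a0, "bias_adjustment")$adjustment)), 1e-10)
  expect_equal(a0$temp, daily$temp)
  # constant offset recovered exactly
  pr <- copy(ob)[, mean_temp := mean_temp + 1.5]
  a1 <- bias_adjust_climate(ob, pr, daily)
  expect_equal(attr(a1, "bias_adjustment")$adjustment, rep(1.5, 2),
               tolerance = 1e-9)
  expect_equal(a1$temp, daily$temp - 1.5)
  # known quadratic trends: adjustment equals the analytic difference
  yrs <- 2005:2014
  ob2 <- data.table(county_id = "a", year = yrs,
                    mean_temp = 10 + 0.1 * (yrs - 2005) +
                      0.01 * (yrs - 2005)^2)
  pr2 <- data.table(county_id = "a", year = yrs,
                    mean_temp = 11 + 0.2 * (yrs - 2005) +
                      0.02 * (yrs - 2005)^2)
  anchor <- 2015
  a2 <- bias_adjust_climate(ob2, pr2, daily[county_id == "a"],
                            anchor_year = anchor)
  t0 <- anchor - 2005
  analytic <- (11 + 0.2 * t0 + 0.02 * t0^2) - (10 + 0.1 * t0 + 0.01 * t0^2)
  expect_equal(attr(a2, "bias_adjustment")$adjustment, analytic,
               tolerance = 1e-9)
  expect_error(bias_adjust_climate(ob[year < 2007], pr, daily))
})

test_that("MMT search recovers planted vertices and applies the cap rule", {
  expect_equal(find_mmt(quad_fit(27.8)), 27.8, tolerance = 0.05)
  expect_equal(find_mmt(quad_fit(22.35)), 22.35, tolerance = 0.05)
  # tie/flat edge: vertex outside the range binds at the range edge
  expect_equal(find_mmt(quad_fit(5)), 10, tolerance = 1e-6)

  # heterogeneous fit with monotone decreasing surface: cap at 29.5
  hetf <- list(beta_bar = c(-1, rep(0, 12)),
               gamma = list(mu_T = rep(0, 13)), dims = "mu_T",
               bands = list(mu_T = c(0, 30)), knots = kn_test,
               xcols = c(paste0("x", 1:13), paste0("x", 1:13, "_mu_T")),
               coef_all = setNames(rep(0, 26),
                                   c(paste0("x", 1:13),
                                     paste0("x", 1:13, "_mu_T"))))
  class(hetf) <- c("het_panel_fit", "panel_fit")
  ch <- data.table(county_id = "a", mu_T = 15)
  expect_equal(find_mmt(hetf, ch), 29.5)
})

test_that("excess mortality is zero at the optimum and linear in coefficients", {
  rf <- make_response_function(quad_fit(25))
  expect_equal(excess_mortality_rate(rf, "a", rf$mmt, 0), 0,
               tolerance = 1e-10)
  expect_true(all(excess_mortality_rate(rf, "a", c(10, 20, 30, 35), 0) >= 0))

  set.seed(2)
  b1 <- rnorm(13, sd = 1e-3); b2 <- rnorm(13, sd = 1e-3)
  f1 <- planted_fit(b1, kn_test); f2 <- planted_fit(b2, kn_test)
  f12 <- planted_fit(b1 + b2, kn_test)
  tt <- runif(5, 10, 35); ee <- runif(5, -2, 2)
  # with a common MMT reference the rate is linear in beta
  mm <- 20
  r1 <- predict_surface(f1, tt, ee) - predict_surface(f1, mm, 0)
  r2 <- predict_surface(f2, tt, ee) - predict_surface(f2, mm, 0)
  r12 <- predict_surface(f12, tt, ee) - predict_surface(f12, mm, 0)
  expect_equal(r12, r1 + r2, tolerance = 1e-12)

  # two-evaluation oracle of predict_surface
  rf1 <- make_response_function(f1)
  oracle <- predict_surface(f1, tt, ee) - predict_surface(f1, rf1$mmt, 0)
  expect_equal(excess_mortality_rate(rf1, "a", tt, ee), oracle)
})

test_that("characteristic evolution applies percentage changes with clipping", {
  cur <- data.table(county_id = c("a", "b"),
                    mu_T = c(10, 20), sigma_T = c(2, 3),
                    rmse_c = c(1.0, 1.6))
  bands <- list(mu_T = c(8, 25), sigma_T = c(1.5, 3.5),
                rmse_c = c(0.9, 1.5))
  base <- copy(cur); endc <- copy(cur)
  # end = baseline: unchanged (up to clipping, which binds for rmse b)
  ev0 <- evolve_characteristics(cur, base, endc, bands = bands)
  expect_equal(ev0$mu_T, cur$mu_T)
  expect_equal(ev0$rmse_c, pmin(pmax(cur$rmse_c, 0.9), 1.5))
  # RMSE halves: evolved = max(observed * 0.5, band floor)
  endc2 <- copy(cur)[, rmse_c := rmse_c * 0.5]
  ev1 <- evolve_characteristics(cur, base, endc2, bands = bands)
  expect_equal(ev1$rmse_c, pmax(cur$rmse_c * 0.5, 0.9))
  # property: always inside the band
  set.seed(3)
  endc3 <- copy(cur)[, `:=`(mu_T = mu_T * runif(2, 0.5, 2),
                            sigma_T = sigma_T * runif(2, 0.5, 2),
                            rmse_c = rmse_c * runif(2, 0.1, 3))]
  ev2 <- evolve_characteristics(cur, base, endc3, bands = bands)
  for (d in names(bands))
    expect_true(all(ev2[[d]] >= bands[[d]][1] & ev2[[d]] <= bands[[d]][2]))
  # zero baseline cannot define a percentage change
  base0 <- copy(base)[1, mu_T := 0]
  expect_error(evolve_characteristics(cur, base0, endc3, bands = bands))
})

test_that("annual deaths follow the population-scaled daily rates", {
  # beta = 0: all totals zero
  rf0 <- make_response_function(planted_fit(rep(0, 13), kn_test))
  panel <- data.table(county_id = "a",
                      date = as.IDate("2095-01-01") + 0:364,
                      temp = 25, error = 0)
  pop <- c(a = 1e5)
  p0 <- annual_excess_mortality(panel, rf0, pop)
  expect_equal(p0$annual$deaths, 0)
  expect_equal(p0$six_year_mean_hot, 0)

  # single county arithmetic: surface T - MMT with MMT = 10 gives a rate
  # of 0.1/day at T = 10.1; pop 100k over 365 days -> 36.5 deaths
  lin <- planted_fit(c(1, rep(0, 12)), kn_test)     # f(T, e) = T
  rf1 <- make_response_function(lin)
  expect_equal(rf1$mmt, 10, tolerance = 1e-6)
  panel2 <- copy(panel)[, temp := 10.1]
  p1 <- annual_excess_mortality(panel2, rf1, pop)
  expect_equal(p1$annual$deaths, 0.1 * 365, tolerance = 1e-6)
  # all days at/below the hot threshold: hot-day total is zero
  expect_equal(p1$annual$deaths_hot, 0)
  # hot days counted strictly above threshold
  panel3 <- copy(panel)[, temp := c(rep(20, 165), rep(20.5, 200))]
  p3 <- annual_excess_mortality(panel3, rf1, pop)
  expect_equal(p3$annual$deaths_hot, 10.5 * 200, tolerance = 1e-6)

  expect_error(annual_excess_mortality(panel, rf1, c(b = 1)))
})

test_that("lives saved vanish at identity and scale with population", {
  fx <- fixture_panel()
  truth <- fx$truth
  planted <- planted_fit(truth$beta_true, truth$knots, vcov_scale = 1e-6)
  rf <- make_response_function(planted)
  panel <- fx$records[year(date) == 2006,
                      .(county_id, date, temp, error = error_demeaned)]
  pop <- setNames(fx$counties$population_base, fx$counties$county_id)
  proj <- annual_excess_mortality(panel, rf, pop)
  ls0 <- lives_saved(proj, proj, planted, n_draws = 50, seed = 5)
  expect_equal(ls0$lives_saved, c(0, 0))
  expect_true(all(ls0$lo95 <= 0 & ls0$hi95 >= 0))

  # halving all errors on a convex-in-error surface saves lives
  panel_better <- copy(panel)[, error := error / 2]
  proj_b <- annual_excess_mortality(panel_better, rf, pop)
  ls1 <- lives_saved(proj_b, proj, planted, n_draws = 50, seed = 5)
  expect_gt(ls1[metric == "all_days"]$lives_saved, 0)

  # doubling the population doubles deaths and lives saved
  proj2 <- annual_excess_mortality(panel, rf, pop * 2)
  expect_equal(proj2$annual$deaths, 2 * proj$annual$deaths)
  proj2_b <- annual_excess_mortality(panel_better, rf, pop * 2)
  ls2 <- lives_saved(proj2_b, proj2, planted, n_draws = 50, seed = 5)
  expect_equal(ls2$lives_saved, 2 * ls1$lives_saved)

  expect_error(lives_saved(proj, annual_excess_mortality(
    panel[year(date) != 2006 | month(date) != 1], rf, pop)))
})

test_that("hot-day error mortality weights 1-degree bins by day counts", {
  fx <- fixture_panel()
  rf <- make_response_function(planted_fit(fx$truth$beta_true,
                                           fx$truth$knots))
  em <- hot_day_error_mortality(rf, fx$records)
  expect_true(all(names(em) %in% fx$counties$county_id))
  # independent recomputation for one county
  cid <- names(em)[1]
  rec <- fx$records[county_id == cid & temp > 20]
  ny <- uniqueN(year(fx$records[county_id == cid]$date))
  dd <- predict_surface(rf$fit, rec$temp, rec$error_demeaned) -
    predict_surface(rf$fit, rec$temp, 0)
  bins <- floor(rec$temp)
  bm <- tapply(dd, bins, mean); bn <- tapply(dd, bins, length)
  expect_equal(unname(em[cid]),
               sum(bm * (bn / ny)) / sum(bn / ny), tolerance = 1e-12)
})
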