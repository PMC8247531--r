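make_dx <- function(vals, ny = 1, nx = 1) {
  x <- exposure_surface(array(vals, c(ny, nx, length(vals) / (ny * nx))),
                        array(0, c(ny, nx, length(vals) / (ny * nx))))
  # zero baseline leaves the (2-day averaged) values untouched when the
  # series is constant in time
  isolate_fire_baseline(x, background_baseline(matrix(0, ny, nx)))
}

test_that("the risk coefficient transforms rate ratios correctly", {
  expect_equal(beta_from_rr(1), 0)
  expect_error(beta_from_rr(-0.5), "> 0")
  # percent increase at the CRF increment recovers 100 * (RR - 1)
  for (rr in c(1.008, 1.028, 1.048, 1.0207)) {
    b <- beta_from_rr(rr)
    expect_equal(100 * (exp(b * 10) - 1), 100 * (rr - 1), tolerance = 1e-12)
  }
  # crf_spec carries its own increment
  crf <- crf_spec("respiratory", "WF", 1.028, 1.014, 1.041, increment = 20)
  expect_equal(beta_from_rr(crf), log(1.028) / 20)
})

test_that("county rates become daily per-person rates on the grid", {
  cm <- matrix(1L, 2, 2)
  r <- data.frame(county_id = 1, outcome = "respiratory",
                  annual_rate_per_100k = 365)
  expect_equal(regrid_rates(r, cm, "respiratory"),
               matrix(1e-5, 2, 2))
  # three-county map matches the scalar lookup oracle bit-exactly
  set.seed(3)
  cm3 <- matrix(sample(1:3, 20, replace = TRUE), 4, 5)
  r3 <- data.frame(county_id = rep(1:3, 2),
                   outcome = rep(c("respiratory", "asthma"), each = 3),
                   annual_rate_per_100k = runif(6, 500, 5000))
  expect_identical(regrid_rates(r3, cm3, "asthma"),
                   oracle_regrid_rates(r3, cm3, "asthma"))
  expect_error(regrid_rates(r3[r3$county_id != 2, ], cm3, "respiratory"),
               "county id\\(s\\): 2")
})

test_that("tract population splits equally and conserves totals exactly", {
  tr <- data.frame(tract_id = 1, x = c(1, 1, 2, 2), y = c(1, 2, 1, 2),
                   population = 100)
  expect_equal(regrid_population(tr, c(2, 2)), matrix(25, 2, 2))
  # two disjoint tracts match hand allocation
  tr2 <- rbind(tr, data.frame(tract_id = 2, x = 3, y = 1, population = 7))
  pop <- regrid_population(tr2, c(2, 3))
  expect_equal(pop[1, 3], 7)
  expect_equal(sum(pop), 107)
  # exact conservation even when the split is not representable exactly
  tr3 <- data.frame(tract_id = 1, x = 1:3, y = 1, population = 100)
  expect_identical(sum(regrid_population(tr3, c(1, 3))), 100)
  # random fixture conservation
  set.seed(8)
  trr <- do.call(rbind, lapply(1:20, function(i) {
    n <- sample(1:4, 1)
    data.frame(tract_id = i, x = sample(1:6, n), y = sample(1:6, n),
               population = round(runif(1, 10, 9999)))
  }))
  expect_identical(sum(regrid_population(trr, c(6, 6))),
                   sum(vapply(split(trr$population, trr$tract_id),
                              function(p) p[1], numeric(1))))
  expect_error(regrid_population(data.frame(tract_id = 1, x = 9, y = 1,
                                            population = 5), c(2, 2)),
               "outside the grid")
})

test_that("the health impact function evaluates Eq.-style worked cases", {
  # no exposure or null CRF -> no impact
  dx0 <- make_dx(rep(0, 3))
  rp <- uniform_rp(1, 1, rate_annual = 3650, pop_cell = 1e5)
  null_crf <- crf_spec("respiratory", "WF", 1, 1, 1)
  expect_true(all(excess_admissions(dx0, null_crf, rp)$dy == 0))
  crf <- wf_crf()
  expect_equal(excess_admissions(dx0, crf, rp)$total, 0)
  # single cell: YNF = 1e-5/day, RR = 1.028, dx = 10, Pop = 1e5
  dx10 <- make_dx(10)
  rp1 <- rate_pop_grid(matrix(1e-5, 1, 1), matrix(1e5, 1, 1),
                       matrix(1L, 1, 1), "respiratory")
  expect_equal(excess_admissions(dx10, crf, rp1)$total,
               1e-5 * 0.028 * 1e5, tolerance = 1e-12)
})

test_that("impacts are linear in population and rates, monotone in exposure", {
  set.seed(41)
  dx <- make_dx(runif(9 * 4, 0, 30), ny = 3, nx = 3)
  cm <- matrix(rep(1:3, each = 3), 3, 3)
  ynf <- matrix(c(1e-5, 4e-5, 8e-5)[cm], 3, 3)  # county-constant rates
  pop <- matrix(runif(9, 0, 5000), 3, 3)
  crf <- wf_crf()
  base <- excess_admissions(dx, crf,
                            rate_pop_grid(ynf, pop, cm, "respiratory"))
  dbl_pop <- excess_admissions(dx, crf,
                               rate_pop_grid(ynf, 2 * pop, cm, "respiratory"))
  expect_equal(dbl_pop$total, 2 * base$total, tolerance = 1e-12)
  dbl_ynf <- excess_admissions(dx, crf,
                               rate_pop_grid(2 * ynf, pop, cm, "respiratory"))
  expect_equal(dbl_ynf$total, 2 * base$total, tolerance = 1e-12)
  # monotone in exposure
  dx2 <- make_dx(runif(9 * 4, 0, 30) + 40, ny = 3, nx = 3)
  hi <- excess_admissions(dx2, crf,
                          rate_pop_grid(ynf, pop, cm, "respiratory"))
  expect_gt(hi$total, base$total)
  # small-exposure limit agrees with the linearised impact within 1%
  dxs <- make_dx(rep(0.1, 9), ny = 3, nx = 3)
  beta <- beta_from_rr(crf)
  lin <- sum(ynf * beta * 0.1 * pop)
  small <- excess_admissions(dxs, crf,
                             rate_pop_grid(ynf, pop, cm, "respiratory"))
  expect_equal(small$daily[1], lin, tolerance = 0.01)
  # county totals partition the regional total
  expect_equal(sum(base$county_totals), base$total, tolerance = 1e-9)
})

test_that("the gridded impact matches the scalar-loop oracle bit-exactly", {
  set.seed(55)
  dx <- make_dx(runif(10 * 10 * 5, 0, 40), ny = 10, nx = 10)
  ynf <- matrix(1e-5, 10, 10)
  pop <- matrix(runif(100, 0, 3000), 10, 10)
  crf <- wf_crf()
  got <- excess_admissions(dx, crf,
                           rate_pop_grid(ynf, pop, matrix(1L, 10, 10),
                                         "respiratory"))
  want <- oracle_impact(dx$dx, ynf, pop, beta_from_rr(crf))
  expect_identical(got$dy, want$dy)
  expect_equal(got$daily, want$daily, tolerance = 1e-15)
  expect_equal(got$total, want$total, tolerance = 1e-15)
})

test_that("impact assessment requires 2-day-averaged exposure and aligned grids", {
  dx <- make_dx(c(5, 5))
  crf <- wf_crf()
  rp_bad <- uniform_rp(2, 2)
  expect_error(excess_admissions(dx, crf, rp_bad), "misaligned")
  dx_raw <- dx
  dx_raw$two_day_averaged <- FALSE
  expect_error(excess_admissions(dx_raw, crf, uniform_rp(1, 1)),
               "2-day averaged")
})

test_that("stratified assessments run per subgroup and add up when they should", {
  set.seed(17)
  dx <- make_dx(runif(4 * 3, 0, 25), ny = 2, nx = 2)
  cm <- matrix(1L, 2, 2)
  ynf <- matrix(2e-5, 2, 2)
  pop_a <- matrix(runif(4, 100, 2000), 2, 2)
  pop_b <- matrix(runif(4, 100, 2000), 2, 2)
  crf <- wf_crf()
  crfs <- list(a = crf, b = crf,
               all = crf)
  rps <- list(a = rate_pop_grid(ynf, pop_a, cm, "respiratory", "a"),
              b = rate_pop_grid(ynf, pop_b, cm, "respiratory", "b"),
              all = rate_pop_grid(ynf, pop_a + pop_b, cm, "respiratory"))
  res <- stratified_assessment(dx, crfs, rps)
  # same CRF and rates, population partition -> additivity
  expect_equal(res$a$total + res$b$total, res$all$total, tolerance = 1e-12)
  expect_error(stratified_assessment(dx, crfs["a"], rps["b"]),
               "subgroup")
  # a protective subgroup CRF (RR < 1) yields a negative point estimate
  crf_lo <- crf_spec("asthma", "WF", 0.999, 0.935, 1.068, subgroup = "5-19")
  neg <- excess_admissions(dx, crf_lo,
                           rate_pop_grid(ynf, pop_a, cm, "asthma", "5-19"))
  expect_lt(neg$total, 0)
})
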