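# Cohort engine: background mortality, discounting, half-cycle correction,
# and the partitioned-survival trace.

test_that("other_cause_prob converts annual qx to the cycle scale", {
  lt <- life_table(40:100, c(rep(0.01, 60), 1))
  expect_equal(other_cause_prob(lt, 45), 1 - 0.99^(21 / 365.25))
  expect_equal(other_cause_prob(lt, 45), 5.777e-4, tolerance = 1e-3)
  lt0 <- life_table(40:100, c(rep(0, 60), 1))
  expect_equal(other_cause_prob(lt0, 50), 0)
  expect_equal(other_cause_prob(lt, 100), 1)   # qx = 1 row
  expect_equal(other_cause_prob(lt, 150), 1)   # clamped above the table
  expect_equal(other_cause_prob(NULL, 45), 0)
  expect_error(other_cause_prob(lt, 20), "below")
})

test_that("life_table validates its invariants", {
  expect_error(life_table(c(40, 42), c(0.1, 1)), "contiguous")
  expect_error(life_table(40:41, c(0.5, 0.9)), "maximum age")
  expect_error(life_table(40:41, c(-0.1, 1)), "\\[0, 1\\]")
})

test_that("combine_mortality composes independent risks", {
  expect_equal(combine_mortality(0, 0), 0)
  expect_equal(combine_mortality(0.01, 0.001), 0.010990)
  p <- c(0, 0.3, 0.77, 1)
  expect_equal(combine_mortality(p, 0), p)
  expect_equal(combine_mortality(0.2, 0.4), combine_mortality(0.4, 0.2))
  expect_true(all(combine_mortality(p, 0.1) >= pmax(p, 0.1) - 1e-15))
  expect_error(combine_mortality(1.2, 0), "\\[0, 1\\]")
})

test_that("discount_factor matches the annual-rate closed form", {
  expect_equal(discount_factor(0, 0.05), 1.0)
  expect_equal(discount_factor(0:50, 0), rep(1.0, 51))
  one_year <- 365.25 / 21
  expect_equal(discount_factor(one_year, 0.03), 1 / 1.03)
  expect_equal(discount_factor(one_year, 0.03), 0.97087, tolerance = 1e-5)
  expect_error(discount_factor(-1, 0.03), ">= 0")
  expect_error(discount_factor(1, -0.01), ">= 0")
})

test_that("half_cycle_person_time is the trapezoid sum", {
  expect_equal(half_cycle_person_time(c(1, 0.5, 0.25)), 1.125)
  expect_equal(half_cycle_person_time(rep(0.4, 11)), 0.4 * 10)
  # trapezoid error is O(dt^2) against the continuous integral
  r <- 0.05; T <- 100
  coarse <- half_cycle_person_time(exp(-r * (0:T)))
  exact <- (1 - exp(-r * T)) / r
  expect_equal(coarse, exact, tolerance = 1e-3)
  expect_error(half_cycle_person_time(1), "at least two")
})

test_that("run_cohort reproduces exponential closed forms", {
  pfs <- parametric_survival("exponential", rate = 0.2)
  os <- parametric_survival("exponential", rate = 0.1)
  st <- engine_settings(horizon = 200, discount_rate = 0.03)
  tr <- run_cohort(pfs, os, table = NULL, settings = st)
  t <- tr$cycle
  expect_equal(tr$pd, exp(-0.1 * t) - exp(-0.2 * t), tolerance = 1e-10)
  expect_equal(tr$pfs_no_ae + tr$pfs_ae, exp(-0.2 * t), tolerance = 1e-10)
  expect_equal(tr$death, 1 - exp(-0.1 * t), tolerance = 1e-10)
})

test_that("identical PFS and OS curves give zero progressed occupancy", {
  m <- ll_bsc_os()
  tr <- run_cohort(m, m, table = NULL, settings = engine_settings(horizon = 300))
  expect_true(all(tr$pd == 0))
})

test_that("trace conservation and absorbing death on the published models", {
  lt <- synthetic_life_table()
  tr <- run_cohort(ll_cbsc_pfs(), ll_cbsc_os(), lt, engine_settings())
  rows <- tr$pfs_no_ae + tr$pfs_ae + tr$pd + tr$death
  expect_true(all(abs(rows - 1) <= 1e-9))
  expect_true(all(diff(tr$death) >= -1e-12))
  expect_true(all(as.matrix(tr[, c("pfs_no_ae", "pfs_ae", "pd", "death")]) >=
                    -1e-12))
  # the extrapolated control-arm curves cross around cycle 266; the clamp
  # zeroes progressed-disease occupancy there and reports the cycles
  tr2 <- suppressMessages(
    run_cohort(ll_bsc_pfs(), ll_bsc_os(), lt, engine_settings()))
  expect_true(all(tr2$pd >= 0))
  cross <- attr(tr2, "crossing_cycles")
  expect_gt(length(cross), 0)
  expect_true(all(tr2$pd[tr2$cycle %in% cross] == 0))
})

test_that("ae_split partitions the progression-free compartment", {
  tr <- run_cohort(ll_bsc_pfs(), ll_bsc_os(), NULL,
                   engine_settings(horizon = 100), ae_split = 0.3)
  expect_equal(tr$pfs_ae / (tr$pfs_ae + tr$pfs_no_ae),
               rep(0.3, nrow(tr)), tolerance = 1e-12)
  expect_error(run_cohort(ll_bsc_pfs(), ll_bsc_os(), NULL,
                          engine_settings(), ae_split = 1.5), "\\[0, 1\\]")
})

test_that("no life table reproduces pure disease survival", {
  st <- engine_settings(horizon = 150)
  tr <- run_cohort(ll_bsc_pfs(), ll_bsc_os(), NULL, st)
  expect_equal(1 - tr$death, survival_at(ll_bsc_os(), tr$cycle),
               tolerance = 1e-12)
  # adding background mortality can only reduce survival
  tr_bg <- run_cohort(ll_bsc_pfs(), ll_bsc_os(), synthetic_life_table(), st)
  n <- min(nrow(tr), nrow(tr_bg))
  expect_true(all(tr_bg$death[1:n] >= tr$death[1:n] - 1e-12))
})

test_that("discounted person-time matches the geometric closed form", {
  q <- exp(-0.1)
  d <- discount_factor(1, 0.03)
  os <- parametric_survival("exponential", rate = 0.1)
  st <- engine_settings(horizon = 400, discount_rate = 0.03,
                        half_cycle_correction = FALSE)
  tr <- run_cohort(os, os, NULL, st)
  alive_time <- accrue(tr, c(pfs_no_ae = 1, pfs_ae = 1, pd = 1, death = 0),
                       st)
  T <- max(tr$cycle)
  closed <- q * d * (1 - (q * d)^T) / (1 - q * d)
  expect_equal(alive_time, closed, tolerance = 1e-8)
  # half-cycle correction shifts both sides by (x0 - xT dT)/2
  st_h <- engine_settings(horizon = 400, discount_rate = 0.03,
                          half_cycle_correction = TRUE)
  tr_h <- run_cohort(os, os, NULL, st_h)
  alive_h <- accrue(tr_h, c(pfs_no_ae = 1, pfs_ae = 1, pd = 1, death = 0),
                    st_h)
  expect_equal(alive_h, closed + 0.5 - 0.5 * q^T * d^T, tolerance = 1e-8)
})

test_that("discounted person-time is monotone in the discount rate", {
  os <- ll_bsc_os()
  vals <- c(pfs_no_ae = 1, pfs_ae = 1, pd = 1, death = 0)
  pt <- vapply(c(0, 0.02, 0.05, 0.08), function(r) {
    st <- engine_settings(horizon = 300, discount_rate = r)
    accrue(run_cohort(ll_bsc_pfs(), os, NULL, st), vals, st)
  }, numeric(1))
  expect_true(all(diff(pt) < 0))
})

test_that("accrue validates dimensions and handles matrices", {
  st <- engine_settings(horizon = 10, discount_rate = 0)
  tr <- run_cohort(parametric_survival("exponential", rate = 0.1),
                   parametric_survival("exponential", rate = 0.1), NULL, st)
  expect_error(accrue(tr, matrix(1, 3, 4), st), "cycles x 4")
  expect_error(accrue(tr, c(a = 1), st), "named over the four states")
  m <- matrix(1, nrow(tr), 4, dimnames = list(NULL,
              c("pfs_no_ae", "pfs_ae", "pd", "death")))
  expect_equal(accrue(tr, m, st),
               accrue(tr, c(pfs_no_ae = 1, pfs_ae = 1, pd = 1, death = 1),
                      st))
})
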