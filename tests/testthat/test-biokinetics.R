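test_that("single closed compartment integrates to 1/lambda", {
  lam <- 24 * log(2) / 192.608               # /d for an 8.0252 d half-life
  m <- compartment_model("A", data.frame(from = character(0),
                                         to = character(0),
                                         rate = numeric(0)),
                         lam, c(A = 1))
  ca <- cumulated_activities(m)
  expect_equal(unname(ca$entries[["A"]]), 192.608 / log(2) / 24 * 24,
               tolerance = 1e-10)            # = 277.87 h = 1/lambda_p
})

test_that("two-compartment chain matches the closed form and the ODE oracle", {
  m <- chain_model(k = 2, k2 = 1)
  ca <- cumulated_activities(m)
  lam <- m$lambda_phys
  # closed form for B fed by A -> B at rate k (no B outflow other than k2):
  # A~_B = k / ((k + lam) (k2 + lam)) days
  expect_equal(unname(ca$entries[["B"]]),
               24 * 2 / ((2 + lam) * (1 + lam)), tolerance = 1e-10)
  orc <- ode_cumulated_oracle(m)
  expect_equal(unname(ca$compartment_hours), unname(orc), tolerance = 1e-8)
})

test_that("decay-count conservation holds on all-sinks-tracked models", {
  for (F in c(0.05, 0.25, 0.95)) {
    m <- build_iodide_pregnancy_model(F, "I-131")
    ca <- cumulated_activities(m)
    expect_equal(sum(ca$compartment_hours) * m$lambda_phys / 24, 1,
                 tolerance = 1e-8)
  }
  m <- build_iodide_pregnancy_model(0.35, "I-123")
  ca <- cumulated_activities(m)
  expect_equal(sum(ca$compartment_hours) * m$lambda_phys / 24, 1,
               tolerance = 1e-8)
})

test_that("cumulated activities are linear in A0 and vanish as decay dominates", {
  m <- chain_model()
  ca1 <- cumulated_activities(m)
  m2 <- m; m2$A0 <- m$A0                      # scaling A0 scales A~
  # (A0 must sum to 1 in the constructor; check linearity on the solution)
  sol <- solve(diag(m$lambda_phys, 3) - m$K, 2 * m$A0)
  expect_equal(sol, 2 * solve(diag(m$lambda_phys, 3) - m$K, m$A0),
               tolerance = 1e-12)
  # lambda -> infinity: compartments not in A0 get nothing
  mfast <- chain_model(lambda = 1e8)
  cafast <- cumulated_activities(mfast)
  expect_lt(unname(cafast$entries[["B"]]), 1e-6)
  expect_lt(unname(cafast$entries[["C"]]), 1e-12)
})

test_that("iodide model reproduces the uptake-level trends", {
  regions <- c("thyroid", "fetus thyroid", "stomach", "liver",
               "salivary glands", "urinary bladder contents")
  vals <- sapply(uptake_levels(), function(F) {
    ca <- cumulated_activities(build_iodide_pregnancy_model(F, "I-131"))
    ca$entries[c("thyroid", "fetus thyroid", "stomach", "liver")]
  })
  expect_true(all(diff(vals["thyroid", ]) > 0))
  expect_true(all(diff(vals["fetus thyroid", ]) < 0))
  expect_true(all(diff(vals["stomach", ]) < 0))
  expect_true(all(diff(vals["liver", ]) > 0))
})

test_that("thyroid cumulated activity vanishes as F -> 0+", {
  ca <- cumulated_activities(build_iodide_pregnancy_model(1e-6, "I-131"))
  expect_lt(unname(ca$entries[["thyroid"]]), 1e-3)
  expect_error(build_iodide_pregnancy_model(0, "I-131"), "F must be")
  expect_error(build_iodide_pregnancy_model(1.2, "I-131"), "F must be")
})

test_that("voiding bladder model reproduces its analytic and oracle limits", {
  # zero inflow
  expect_equal(bladder_cumulated_activity(function(t) 0 * t, 2,
                                          voiding_schedule(3.5),
                                          horizon = 40), 0, tolerance = 1e-10)
  # constant inflow r, negligible decay, interval T, horizon nT: n r T^2 / 2
  r <- 0.1; Tn <- 4; n <- 6
  got <- bladder_cumulated_activity(function(t) rep(r, length(t)),
                                    lambda_phys = 1e-9,
                                    voiding_schedule(Tn), horizon = n * Tn)
  expect_equal(got, n * r * Tn^2 / 2, tolerance = 1e-4)
  # decaying inflow vs an explicit event-stepping oracle
  lam_d <- 24 * log(2) / 13.2235             # I-123-like decay, per day
  lam_h <- lam_d / 24
  inflow <- function(t) 0.05 * exp(-0.3 * t)
  got <- bladder_cumulated_activity(inflow, lam_d, voiding_schedule(3.5),
                                    horizon = 60)
  dt <- 1e-3; tt <- seq(0, 60 - dt, by = dt)
  b <- 0; acc <- 0; nextv <- 3.5
  for (t in tt) {
    if (t >= nextv - 1e-12) { b <- 0; nextv <- nextv + 3.5 }
    acc <- acc + b * dt
    b <- b + inflow(t) * dt - lam_h * b * dt
  }
  expect_equal(got, acc, tolerance = 0.001)
})

test_that("noisy curves are seeded, unbiased, and noiseless at cv = 0", {
  m <- chain_model()
  tt <- seq(1, 48, length.out = 12)
  noiseless <- solve_compartments(m, tt)
  expect_equal(gen_time_activity(m, tt, cv = 0), noiseless)
  a <- gen_time_activity(m, tt, cv = 0.1, seed = 11)
  b <- gen_time_activity(m, tt, cv = 0.1, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, gen_time_activity(m, tt, cv = 0.1, seed = 12)))
  # mean over replicates approaches the noiseless curve (3 SE)
  reps <- sapply(1:1000, function(s)
    gen_time_activity(m, tt, cv = 0.1, seed = s)[6, "B"])
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - noiseless[6, "B"]), 3 * se)
})

test_that("rate fitting recovers generating constants", {
  m <- chain_model(k = 2, k2 = 1)
  tt <- seq(0.5, 72, length.out = 20)
  # zero noise: recovery to 0.1%
  fit0 <- fit_rates(gen_time_activity(m, tt, cv = 0), m,
                    free = c("A->B", "B->C"))
  expect_lt(abs(fit0$estimates[["A->B"]] - 2) / 2, 1e-3)
  expect_lt(abs(fit0$estimates[["B->C"]] - 1) / 1, 1e-3)
  # wrong structure fits worse than the right one
  m_wrong <- compartment_model(
    c("A", "B", "C"),
    data.frame(from = c("A", "A"), to = c("B", "C"), rate = c(2, 1)),
    m$lambda_phys, c(A = 1),
    region_map = c(A = "A", B = "B", C = "C"), excreta = "C")
  obs <- gen_time_activity(m, tt, cv = 0.02, seed = 5)
  fit_right <- fit_rates(obs, m, free = c("A->B", "B->C"))
  fit_bad <- fit_rates(obs, m_wrong, free = c("A->B", "A->C"))
  expect_gt(fit_bad$residual_norm, fit_right$residual_norm)
})

test_that("fixture activities load with unit conversion and round-trip", {
  ru <- load_fixture_activities("russell", "I-131", 0.25)
  expect_equal(unname(ru$entries[["thyroid"]]), 2.54 * 24)  # 60.96 h
  ic <- load_fixture_activities("icrp53", "Tc-99m")
  expect_equal(unname(ic$entries[["thyroid"]]), 2.23 / 60, tolerance = 1e-12)
  st <- load_fixture_activities("this_study", "I-131", 0.25)
  expect_equal(unname(st$entries[["fetus thyroid"]]), 4.42)
  f <- tempfile(fileext = ".csv")
  write_activities(ru, f)
  ru2 <- read_activities(f)
  expect_equal(ru2$entries, ru$entries)
  expect_identical(ru2$provenance, ru$provenance)
  expect_error(load_fixture_activities("russell", "I-131", 0.33),
               "no fixture")
})
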