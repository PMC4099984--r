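test_that("scheme structure matches the decay modes", {
  tc <- load_scheme("Tc-99m")
  expect_identical(nrow(tc$betas), 0L)          # isomeric transition
  i131 <- load_scheme("I-131")
  expect_gte(nrow(i131$betas), 1L)
  expect_gte(sum(i131$lines$particle == "photon"), 1L)
  expect_error(load_scheme("Cs-137"), "unknown nuclide")
})

test_that("fixture checksums are unchanged", {
  expect_identical(scheme_checksum("I-131"),
                   "5827805055c0a6b83a73f9859877924d")
  expect_identical(scheme_checksum("I-123"),
                   "49e1c7687224b56cf6a24980736d136e")
  expect_identical(scheme_checksum("Tc-99m"),
                   "231b2f50c45f3f79eea0f821dd612ee9")
})

test_that("yield cutoff removes sub-threshold lines and logs them", {
  tc <- load_scheme("Tc-99m")                   # has a 0.023% gamma
  expect_true(any(tc$lines$yield <= 0.001))
  cut <- apply_yield_cutoff(tc, 0.001)
  expect_true(cut$cutoff_applied)
  expect_true(all(cut$lines$yield > 0.001))
  expect_gt(attr(cut, "removed_yield"), 0)
  # threshold 0 is the identity
  expect_identical(apply_yield_cutoff(tc, 0)$lines, tc$lines)
  # an explicit 0.05% line is removed at the 0.1% rule
  sch <- tc
  sch$lines <- rbind(sch$lines,
                     data.frame(particle = "photon", origin = "gamma",
                                energy = 0.2, yield = 5e-4, tag = "gX"))
  expect_false(0.2 %in% apply_yield_cutoff(sch, 0.001)$lines$energy)
})

test_that("beta spectra normalize, match quadrature, and feel the Coulomb pull", {
  br <- list(E_max = 0.6063, yield = 0.896, Z_daughter = 54,
             sign = "beta-minus")
  sp <- beta_spectrum(br)
  expect_equal(sum(sp$weight), br$yield, tolerance = 1e-9)
  expect_true(all(sp$energy > 0 & sp$energy < br$E_max))
  # Z = 0: pure phase space; mean against an independent quadrature
  br0 <- list(E_max = 0.5, yield = 1, Z_daughter = 0, sign = "beta-minus")
  me <- 0.51099895
  num <- integrate(function(E) {
    W <- 1 + E / me; p <- sqrt(W^2 - 1)
    E * p * W * (0.5 - E)^2
  }, 0, 0.5, rel.tol = 1e-10)$value
  den <- integrate(function(E) {
    W <- 1 + E / me; p <- sqrt(W^2 - 1)
    p * W * (0.5 - E)^2
  }, 0, 0.5, rel.tol = 1e-10)$value
  expect_equal(beta_mean_energy(br0), num / den, tolerance = 1e-3)
  # beta-minus attraction shifts the mean below the Z = 0 mean
  brz <- list(E_max = 0.5, yield = 1, Z_daughter = 54, sign = "beta-minus")
  expect_lt(beta_mean_energy(brz), beta_mean_energy(br0))
  expect_error(beta_spectrum(list(E_max = -1, yield = 1, Z_daughter = 0,
                                  sign = "beta-minus")), "E_max")
})

test_that("sampling reproduces the spectrum mean", {
  br <- list(E_max = 0.6063, yield = 0.896, Z_daughter = 54,
             sign = "beta-minus")
  x <- sample_beta(br, 1e5, seed = 3)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - beta_mean_energy(br)), 3 * se)
})

test_that("electron-line collapse applies both policies and conserves yield", {
  sch <- load_scheme("I-131")
  col <- collapse_electron_lines(sch)
  el0 <- sch$lines[sch$lines$particle == "electron", ]
  el1 <- col$lines[col$lines$particle == "electron", ]
  # one line per tag
  expect_identical(anyDuplicated(el1$tag), 0L)
  # yield conserved per group
  for (tg in unique(el0$tag))
    expect_equal(sum(el1$yield[el1$tag == tg]),
                 sum(el0$yield[el0$tag == tg]), tolerance = 1e-12)
  # Auger groups at the weighted average energy
  kaug <- el0[el0$tag == "K-auger", ]
  expect_equal(el1$energy[el1$tag == "K-auger"],
               sum(kaug$energy * kaug$yield) / sum(kaug$yield))
  # conversion subshells at the subshell maximum
  expect_equal(el1$energy[el1$tag == "L364"],
               max(el0$energy[el0$tag == "L364"]))
  # idempotent
  col2 <- collapse_electron_lines(col)
  expect_equal(col2$lines[order(col2$lines$tag), c("energy", "yield")],
               col$lines[order(col$lines$tag), c("energy", "yield")])
  # single-group scheme: trivial restatement
  one <- sch
  one$lines <- data.frame(particle = "electron", origin = "auger",
                          energy = 0.003, yield = 0.1, tag = "G")
  c1 <- collapse_electron_lines(one)
  expect_equal(c1$lines$energy, 0.003)
  expect_equal(c1$lines$yield, 0.1)
})

test_that("mean emitted energy is stable under sub-0.1% cutoffs", {
  sch <- load_scheme("I-131")
  e_full <- mean_energy_per_decay(sch)
  for (th in c(1e-4, 5e-4, 1e-3)) {
    cut <- apply_yield_cutoff(sch, th)
    removed <- attr(cut, "removed_yield")
    # the change is bounded by removed yield x the maximum line energy
    expect_lt(abs(mean_energy_per_decay(cut) - e_full),
              removed * max(sch$lines$energy, sch$betas$E_max) + 1e-12)
  }
  expect_true(is.finite(e_full))
})
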