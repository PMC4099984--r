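xs <- xs_table()

# tiny scheme: one photon line, handy for arithmetic checks
.mini_scheme <- function(lines, betas = NULL) {
  structure(list(
    nuclide = "test", half_life = 10,
    lines = lines,
    betas = betas %||% data.frame(E_max = numeric(0), yield = numeric(0),
                                  Z_daughter = integer(0),
                                  sign = character(0)),
    cutoff_applied = TRUE), class = "decay_scheme")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

.fake_tally <- function(source, targets, dpp, particle = "photon",
                        energy = 0.1, rel = 0) {
  structure(list(values = data.frame(
    source = source, target = targets, particle = particle, energy = energy,
    specific_energy = dpp, rel_err = rel, histories = 1000L,
    stringsAsFactors = FALSE)), class = "tally_result")
}

test_that("S-value assembly is the yield-weighted sum", {
  sch <- .mini_scheme(data.frame(particle = "photon", origin = "gamma",
                                 energy = 0.1, yield = 0.5, tag = "g"))
  sv <- assemble_svalues(list(list(tally = .fake_tally("s", "t", 2.0),
                                   yield = 0.5)), sch)
  expect_equal(sv$S, 1.0)                        # 0.5 x 2 MeV/g
  # empty scheme: S-values are zero (no contributions)
  sch0 <- .mini_scheme(data.frame(particle = character(0),
                                  origin = character(0),
                                  energy = numeric(0), yield = numeric(0),
                                  tag = character(0)))
  sv0 <- assemble_svalues(list(), sch0)
  expect_identical(nrow(sv0), 0L)
  # two lines: hand-weighted sum, components kept
  sch2 <- .mini_scheme(data.frame(particle = c("photon", "electron"),
                                  origin = c("gamma", "conversion"),
                                  energy = c(0.1, 0.05),
                                  yield = c(0.8, 0.2), tag = c("g", "ce")))
  sv2 <- assemble_svalues(list(
    list(tally = .fake_tally("s", "t", 1.5, "photon", 0.1), yield = 0.8),
    list(tally = .fake_tally("s", "t", 4.0, "electron", 0.05), yield = 0.2)),
    sch2)
  expect_equal(sv2$S, 0.8 * 1.5 + 0.2 * 4.0)
  expect_equal(sv2$S_photon, 1.2)
  expect_equal(sv2$S_electron, 0.8)
  # missing coverage errors with the gap listed
  expect_error(assemble_svalues(list(
    list(tally = .fake_tally("s", "t", 1.5, "photon", 0.1), yield = 0.8)),
    sch2), "missing tally coverage")
})

test_that("organ doses carry the exact unit constant and are linear", {
  sch <- .mini_scheme(data.frame(particle = "photon", origin = "gamma",
                                 energy = 0.1, yield = 1, tag = "g"))
  sv <- assemble_svalues(list(list(tally = .fake_tally("thyroid", "t", 1.0),
                                   yield = 1)), sch)
  act <- cumulated_activity_set(c(thyroid = 1), nuclide = "test")
  d <- organ_doses(sv, act)
  expect_equal(d$dose, 576.7836, tolerance = 1e-6)   # 3600e9 x 1.602e-10 mGy
  expect_equal(d$dose, dose_unit_constant(), tolerance = 1e-12)
  # zero activity -> zero dose; doubling doubles
  expect_equal(organ_doses(sv, cumulated_activity_set(c(thyroid = 0)))$dose, 0)
  expect_equal(organ_doses(sv, cumulated_activity_set(c(thyroid = 2)))$dose,
               2 * d$dose)
  # region mismatch errors
  expect_error(organ_doses(sv, cumulated_activity_set(c(spleen = 1))),
               "no S-values")
  # excreta entries are skipped, not an error
  expect_equal(
    organ_doses(sv, cumulated_activity_set(c(thyroid = 1, urine = 99)))$dose,
    d$dose)
})

test_that("dose-table fixture reproduces the printed uptake relations", {
  t5 <- load_dose_table()
  ft <- t5[t5$target == "fetus, thyroid" & t5$provenance == "this_study", ]
  ratio <- ft$dose_mGy_per_MBq[ft$uptake == 0.05] /
    ft$dose_mGy_per_MBq[ft$uptake == 0.95]
  expect_identical(round(ratio), 15)               # factor-15 decrease
  th <- t5[t5$target == "thyroid" & t5$provenance == "this_study", ]
  th <- th[order(th$uptake), ]
  expect_true(all(diff(th$dose_mGy_per_MBq) > 0))  # maternal thyroid rises
})

test_that("uptake sweep at one level equals a direct dose call", {
  sch <- .mini_scheme(data.frame(particle = "photon", origin = "gamma",
                                 energy = 0.1, yield = 1, tag = "g"))
  # S-values for every source region the computed activities produce
  regs <- c("thyroid", "salivary glands", "stomach", "small intestine",
            "liver", "kidneys", "remaining tissues", "fetus thyroid",
            "fetus remainder", "urinary bladder contents")
  tl <- lapply(regs, function(r)
    list(tally = .fake_tally(r, "t", 1.0), yield = 1))
  sv <- assemble_svalues(tl, sch)
  sw <- uptake_sweep("I-131", sv, levels = 0.25)
  act <- pipeline_activities("I-131", 0.25)
  expect_equal(sw[["0.25"]]$dose, organ_doses(sv, act)$dose,
               tolerance = 1e-12)
})

test_that("provenance comparison reports columns and base-explicit differences", {
  sch <- .mini_scheme(data.frame(particle = "photon", origin = "gamma",
                                 energy = 0.1, yield = 1, tag = "g"))
  regs <- c("thyroid", "stomach", "small intestine", "liver",
            "urinary bladder contents", "remaining tissues", "kidneys",
            "fetus")
  tl <- lapply(regs, function(r)
    list(tally = .fake_tally(r, "t", 1.0), yield = 1))
  sv <- assemble_svalues(tl, sch)
  ru <- load_fixture_activities("russell", "I-131", 0.25)
  ic <- load_fixture_activities("icrp53", "I-131", 0.25)
  ic$entries <- ic$entries[names(ic$entries) != "kidneys"]
  ic2 <- ru; ic2$provenance <- "copy"
  cmp0 <- compare_activity_sets(list(a = ru, b = ic2), sv, base = "a")
  expect_true(all(abs(cmp0$pct_diff_b_vs_a) < 1e-12))
  cmp <- compare_activity_sets(list(russell = ru, icrp53 = ic), sv,
                               base = "russell")
  expect_true(all(c("russell", "icrp53") %in% names(cmp)))
  expect_false(anyNA(cmp$russell))
  expect_false(anyNA(cmp$icrp53))
  expect_identical(attr(cmp, "base"), "russell")
})

test_that("a local fetal-thyroid source out-doses a uniform fetal source", {
  sc <- build_reference_scene("reference_9mo")
  lat <- voxelize_scene(sc, spacing = 4,
                        labels = sc$fetus_labels)
  cfg <- transport_config(n_histories = 2e4, seed = 21)
  tloc <- transport_photons(lat, xs, 122L, 0.364, cfg)
  tuni <- transport_photons(lat, xs, sc$fetus_labels, 0.364, cfg)
  dloc <- tloc$values$specific_energy[tloc$values$target == "fetus thyroid"]
  duni <- tuni$values$specific_energy[tuni$values$target == "fetus thyroid"]
  expect_gt(dloc, duni)
  # electrons make the contrast extreme (self-absorption)
  eloc <- transport_electrons(lat, xs, 122L, 0.3, cfg)
  euni <- transport_electrons(lat, xs, sc$fetus_labels, 0.3, cfg)
  dle <- eloc$values$specific_energy[eloc$values$target == "fetus thyroid"]
  due <- euni$values$specific_energy[euni$values$target == "fetus thyroid"]
  expect_gt(dle, 10 * due)
})

test_that("fetal summary is the mass-weighted mean and an energy audit", {
  expect_equal(fetal_summary(c(a = 2, b = 2, c = 2),
                             c(a = 1, b = 5, c = 9)), 2)
  expect_equal(fetal_summary(c(a = 4, b = 0), c(a = 1, b = 3)), 1)
  expect_error(fetal_summary(c(a = 1), c(b = 1)), "missing fetal masses")
  # audit identity: weighted mean of region doses == total energy/total mass
  sc <- build_reference_scene("minimal_test")
  lat <- voxelize_scene(sc, spacing = 4)
  t <- transport_photons(lat, xs, "core", 0.14,
                         transport_config(n_histories = 1e4, seed = 2))
  grp <- fetodose:::.region_groups(lat)
  v <- t$values
  doses <- setNames(v$specific_energy, v$target)
  masses <- grp$mass[names(doses)]
  lhs <- fetal_summary(doses, masses)
  rhs <- sum(doses * masses) / sum(masses)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("pure-electron component is dominated by the source organ", {
  sc <- build_reference_scene("minimal_test")
  lat <- voxelize_scene(sc, spacing = 4)
  t <- transport_electrons(lat, xs, "core", 0.3,
                           transport_config(n_histories = 1000, seed = 1))
  v <- t$values
  self <- v$specific_energy[v$target == "core"]
  expect_true(all(v$specific_energy[v$target != "core"] < self))
})

test_that("dose maps render to PNG", {
  skip_if_not_installed("png")
  lat <- uniform_lattice(c(8, 8, 8), 5, "water")
  mesh <- mesh_tally_from_energy(lat, runif(prod(lat$dims)))
  dm <- mesh_dose_map(mesh)
  f <- tempfile(fileext = ".png")
  render_dose_map(dm, f, axis = 1)
  expect_true(file.exists(f) && file.size(f) > 0)
})
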