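test_that("grid-aligned box voxelizes to the exact analytic count", {
  sc <- box_scene(half = c(5, 5, 5))           # 10x10x10 mm box
  lat <- voxelize_scene(sc, spacing = 1, labels = 1L,
                        origin = c(-7, -7, -7))
  expect_identical(unname(label_index(lat)[["1"]]), 1000L)
})

test_that("sphere voxel volume approaches the analytic volume", {
  sc <- sphere_scene(r = 10)
  lat <- voxelize_scene(sc, spacing = 1, labels = 1L)
  v <- label_index(lat)[["1"]] * prod(lat$spacing)
  expect_lt(abs(v - 4188.79) / 4188.79, 0.02)
})

test_that("sphere volume error shrinks as spacing halves and is <0.5% at 1mm", {
  sc <- sphere_scene(r = 20)
  vol <- 4 / 3 * pi * 20^3
  err <- vapply(c(4, 2, 1), function(sp) {
    lat <- voxelize_scene(sc, spacing = sp, labels = 1L)
    abs(label_index(lat)[["1"]] * prod(lat$spacing) - vol) / vol
  }, numeric(1))
  expect_lt(err[3], 0.005)
  expect_lt(err[3], err[1] + 1e-12)     # finer beats coarsest (within noise)
})

test_that("nested contents win over their wall in the overlap", {
  sc <- build_reference_scene("minimal_test")
  lat <- voxelize_scene(sc, spacing = 2)
  # label 3 (contents) is nested inside label 2: the contents ellipsoid
  # centre voxel must carry label 3
  idx <- round((c(0, 0, -30) - lat$origin) / lat$spacing) + 1L
  expect_identical(lat$labels[idx[1], idx[2], idx[3]], 3L)
  expect_gt(sum(lat$labels == 2L), 0)
})

test_that("wall layering peels the analytic layer counts and conserves voxels", {
  lat <- block_lattice(10)
  before <- sum(lat$labels == 1L)
  lat2 <- add_wall_layers(lat, 1L, 1L, 99L, wall_material = "water")
  expect_identical(sum(lat2$labels == 99L), 1000L - 512L)   # 10^3 - 8^3
  expect_identical(sum(lat2$labels == 1L), 512L)
  expect_identical(sum(lat2$labels %in% c(1L, 99L)), before)
  # n_layers = 0 is the identity
  expect_identical(add_wall_layers(lat, 1L, 0L, 99L)$labels, lat$labels)
  # peeling a 4^3 block twice empties it
  small <- block_lattice(4)
  expect_error(add_wall_layers(small, 1L, 2L, 99L), "empties")
})

test_that("adjust_mass removes the exact voxel count and respects its bound", {
  lat <- block_lattice(10, material = "water")   # 1000 voxels, 1 g
  lat2 <- adjust_mass(lat, 1L, 0.995)
  expect_identical(sum(lat2$labels == 1L), 995L)
  voxmass <- voxel_volume_cm3(lat2) * 1.0
  expect_lte(abs(organ_mass(lat2, 1L) - 0.995), voxmass)
  # growth works too and is idempotent once within tolerance
  lat3 <- adjust_mass(lat, 1L, 1.012)
  expect_identical(sum(lat3$labels == 1L), 1012L)
  lat4 <- adjust_mass(lat3, 1L, 1.012)
  expect_identical(lat4$labels, lat3$labels)
})

test_that("adjust_mass only touches the organ surface or 6-adjacent voxels", {
  lat <- block_lattice(10)
  org <- lat$labels == 1L
  surf <- fetodose:::.surface6(org)
  adj <- fetodose:::.adjacent6(org)
  lat2 <- adjust_mass(lat, 1L, 0.97)
  changed <- lat2$labels != lat$labels
  expect_true(all(changed[!(surf | adj)] == FALSE))
  lat3 <- adjust_mass(lat, 1L, 1.03)
  changed <- lat3$labels != lat$labels
  expect_true(all(changed[!(surf | adj)] == FALSE))
})

test_that("total lattice mass equals the sum of per-label masses", {
  sc <- build_reference_scene("minimal_test")
  lat <- voxelize_scene(sc, spacing = 2)
  cnt <- label_index(lat)
  lt <- lat$label_table
  per <- sum(vapply(lt$label, function(l)
    if (as.character(l) %in% names(cnt)) organ_mass(lat, l) else 0,
    numeric(1)))
  expect_equal(lattice_total_mass(lat), per, tolerance = 1e-12)
})

test_that("mass_report computes the printed percent-difference convention", {
  expect_equal(mass_percent_diff(165.84, 230.01), -27.90)
  expect_equal(mass_percent_diff(156.61, 280.01), -44.07)
  expect_equal(mass_percent_diff(100, 100), 0)
  lat <- block_lattice(10, material = "water")
  rep <- mass_report(lat, references = c("1" = 1.0))
  expect_equal(rep$percent_diff[rep$label == 1L], 0)
})

test_that("voxelization errors name the offending organ", {
  sc <- sphere_scene(r = 0.4)              # smaller than any voxel
  expect_error(voxelize_scene(sc, spacing = 4, labels = 1L), "ball")
})

test_that("lattice containers round-trip bit-exactly", {
  sc <- build_reference_scene("minimal_test")
  lat <- voxelize_scene(sc, spacing = 4)
  f <- tempfile(fileext = ".txt.gz")
  write_lattice(lat, f)
  lat2 <- read_lattice(f)
  expect_identical(lat2$labels, lat$labels)
  expect_identical(lat2$dims, lat$dims)
  expect_equal(lat2$spacing, lat$spacing)
  expect_equal(lat2$origin, lat$origin)
  expect_equal(lat2$label_table$density, lat$label_table$density)
  fb <- tempfile(fileext = ".bin")
  write_lattice(lat, fb, format = "binary")
  expect_identical(read_lattice(fb, format = "binary")$labels, lat$labels)
  # truncated file: clear error
  full <- readLines(gzfile(f))
  ftr <- tempfile(fileext = ".txt")
  writeLines(head(full, length(full) - 5L), ftr)
  expect_error(read_lattice(ftr), "truncated|size mismatch")
})
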