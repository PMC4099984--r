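# Organ layout for the synthetic 9-months-pregnant scene.
#
# The anatomy roster and target masses follow the ICRP 89/110 reference values
# for a late-term pregnancy (maternal source organs plus a 20-organ fetus,
# including the 1.3 g fetal thyroid). The *shapes* are deliberate geometric
# stand-ins -- ellipsoids, capsules and shells in a simplified trunk + gravid
# uterus arrangement -- because every downstream algorithm (voxelization, mass
# adjustment, transport) is geometry-agnostic; fidelity is to organ masses,
# materials and topology (wall/contents nesting, fetus inside uterus), not to
# anatomical shape. All placement coordinates live in this one file so the
# layout can be reviewed and edited in a single place. Coordinates are mm;
# +x patient left, +y anterior, +z cranial; origin mid-trunk.
#
# Relative placement of the uteroplacental components (placenta, amniotic
# fluid, umbilical cord) is not constrained by reference data and is an
# arbitrary choice here; the placenta is posterior-superior and is truncated
# where the fetal envelope overrides it (declaration-order precedence), so its
# voxelized mass is below target unless explicitly adjusted.

.ell <- function(center, semi) primitive("ellipsoid", center, semi = semi)
.sph <- function(center, r) primitive("sphere", center, radius = r)
.cap <- function(center, r, len, axis)
  primitive("capsule", center, radius = r, length = len, axis = axis)
.shell <- function(center, ri, ro)
  primitive("spherical_shell", center, r_inner = ri, r_outer = ro)
.eshell <- function(center, semi_outer, semi_inner)
  primitive("ellipsoid_shell", center, semi_outer = semi_outer,
            semi_inner = semi_inner)

.organ <- function(label, name, region, shape, mass, material,
                   parent = NA_integer_, source = FALSE, fetal = FALSE) {
  list(label = as.integer(label), name = name, region = region, shape = shape,
       target_mass = mass, material = material, parent = as.integer(parent),
       source_flag = source, fetal = fetal, wall = NULL)
}

# Full reference layout; order is the painting order used to resolve
# same-depth overlaps (later declarations win).
.reference_layout <- function() {
  B <- c(0, 50, -27)        # fetal body centre
  U <- c(0, 45, -15)        # uterus centre
  skin_t <- 1.84            # fetal skin shell thickness, mm
  so <- c(80, 70, 140)      # fetal skin outer semi-axes
  si <- so - skin_t
  list(
    # --- maternal organs -------------------------------------------------
    .organ(1, "thyroid", "thyroid",
           .ell(c(0, 55, 290), c(18, 10, 21.5)), 17.00, "soft_tissue",
           source = TRUE),
    .organ(2, "salivary gland, left", "salivary glands",
           .cap(c(45, 40, 310), 14, 35, "z"), 35.00, "soft_tissue",
           source = TRUE),
    .organ(3, "salivary gland, right", "salivary glands",
           .cap(c(-45, 40, 310), 14, 35, "z"), 35.00, "soft_tissue",
           source = TRUE),
    .organ(8, "liver", "liver",
           .ell(c(-60, 15, 185), c(95, 65, 50)), 1400.00, "soft_tissue",
           source = TRUE),
    .organ(4, "stomach wall", "stomach wall",
           .ell(c(65, 15, 170), c(45, 35, 55)), 140.00, "soft_tissue",
           source = TRUE),
    .organ(5, "stomach contents", "stomach contents",
           .ell(c(65, 15, 170), c(38.6, 29, 47)), 230.01, "gi_contents",
           parent = 4, source = TRUE),
    .organ(11, "spleen", "spleen",
           .ell(c(95, -45, 150), c(38, 25, 31)), 130.00, "soft_tissue"),
    .organ(12, "pancreas", "pancreas",
           .cap(c(10, -70, 190), 16, 110, "x"), 120.00, "soft_tissue"),
    .organ(9, "kidney, left", "kidneys",
           .ell(c(95, -55, 60), c(32, 20, 53)), 149.48, "soft_tissue",
           source = TRUE),
    .organ(10, "kidney, right", "kidneys",
           .ell(c(-95, -55, 60), c(31, 19, 50)), 125.53, "soft_tissue",
           source = TRUE),
    .organ(6, "small intestine wall", "small intestine wall",
           .ell(c(0, -70, 120), c(75, 55, 48)), 600.00, "soft_tissue",
           source = TRUE),
    .organ(7, "small intestine contents", "small intestine contents",
           .ell(c(0, -70, 120), c(52, 38, 33)), 280.01, "gi_contents",
           parent = 6, source = TRUE),
    .organ(13, "ovary, left", "ovaries",
           .ell(c(55, 0, -175), c(11, 9, 12.7)), 5.50, "soft_tissue"),
    .organ(14, "ovary, right", "ovaries",
           .ell(c(-55, 0, -175), c(11, 9, 12.7)), 5.50, "soft_tissue"),
    # --- uterus and contents --------------------------------------------
    .organ(100, "uterus", "uterus",
           .ell(U, c(105, 95, 158)), 823.33, "soft_tissue"),
    .organ(102, "amniotic fluid", "amniotic fluid",
           .ell(c(0, 88, -80), c(36, 30, 40)), 207.17, "amniotic_fluid",
           parent = 100),
    .organ(101, "placenta", "placenta",
           .ell(c(0, 7, 13), c(78, 34, 66)), 1070.39, "placenta",
           parent = 100, source = TRUE),
    .organ(103, "umbilical cord", "umbilical cord",
           .cap(c(0, 127, -40), 7, 40, "z"), 25.60, "blood",
           parent = 100),
    .organ(110, "fetus, skin", "fetus skin",
           .eshell(B, so, si), 229.08, "skin", parent = 100, fetal = TRUE),
    .organ(111, "fetus, soft tissue", "fetus soft tissue",
           .ell(B, si), 2299.96, "fetal_soft", parent = 100,
           source = TRUE, fetal = TRUE),
    # --- fetal organs (children of 111, painting order = carving order) --
    .organ(112, "fetus, brain", "fetus brain",
           .ell(B + c(0, 0, -80), c(45, 42, 45)), 370.00, "brain",
           parent = 111, fetal = TRUE),
    .organ(113, "fetus, skull", "fetus skeleton",
           .shell(B + c(0, 0, -80), 47, 50), 108.00, "fetal_skeleton",
           parent = 111, fetal = TRUE),
    .organ(120, "fetus, eye, left", "fetus eyes",
           .sph(B + c(16, 26, -90), 7.81), 2.065, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(121, "fetus, eye, right", "fetus eyes",
           .sph(B + c(-16, 26, -90), 7.81), 2.065, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(122, "fetus, thyroid", "fetus thyroid",
           .ell(B + c(0, 0, -23), c(8, 4.6, 8)), 1.30, "fetal_soft",
           parent = 111, source = TRUE, fetal = TRUE),
    .organ(123, "fetus, lung, left", "fetus lungs",
           .ell(B + c(29, 0, 10), c(16, 17, 25)), 30.00, "fetal_lung",
           parent = 111, fetal = TRUE),
    .organ(124, "fetus, lung, right", "fetus lungs",
           .ell(B + c(-29, 0, 10), c(16, 17, 25)), 30.00, "fetal_lung",
           parent = 111, fetal = TRUE),
    .organ(126, "fetus, heart", "fetus heart",
           .cap(B + c(0, 0, 10), 12, 20, "z"), 20.00, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(125, "fetus, thymus", "fetus thymus",
           .ell(B + c(0, 18, -5), c(13, 9.5, 24)), 13.00, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(127, "fetus, liver", "fetus liver",
           .ell(B + c(-20, 0, 55), c(38, 28, 28)), 130.00, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(130, "fetus, gall bladder wall", "fetus gall bladder wall",
           .ell(B + c(-2, 8, 67), c(8.5, 7, 8.5)), 0.72, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(131, "fetus, gall bladder contents", "fetus gall bladder contents",
           .ell(B + c(-2, 8, 67), c(6, 4.5, 6.2)), 0.72, "gi_contents",
           parent = 130, fetal = TRUE),
    .organ(128, "fetus, stomach wall", "fetus stomach wall",
           .ell(B + c(32, 0, 57), c(17, 14, 14)), 10.15, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(129, "fetus, stomach contents", "fetus stomach contents",
           .ell(B + c(32, 0, 57), c(12, 8.6, 8.6)), 3.86, "gi_contents",
           parent = 128, fetal = TRUE),
    .organ(142, "fetus, spleen", "fetus spleen",
           .ell(B + c(40, -15, 40), c(12, 10, 19)), 9.50, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(143, "fetus, pancreas", "fetus pancreas",
           .cap(B + c(25, -8, 70), 6.5, 25, "x"), 5.00, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(138, "fetus, kidney, left", "fetus kidneys",
           .ell(B + c(30, -22, 80), c(13, 11, 20)), 12.50, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(139, "fetus, kidney, right", "fetus kidneys",
           .ell(B + c(-30, -22, 80), c(13, 11, 20)), 12.50, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(140, "fetus, adrenal, left", "fetus adrenals",
           .ell(B + c(34, -30, 58), c(9, 8, 9.5)), 3.00, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(141, "fetus, adrenal, right", "fetus adrenals",
           .ell(B + c(-34, -30, 58), c(9, 8, 9.5)), 3.00, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(132, "fetus, SI wall", "fetus SI wall",
           .ell(B + c(0, 4, 80), c(26, 18, 13.5)), 13.63, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(133, "fetus, SI contents", "fetus SI contents",
           .ell(B + c(0, 4, 80), c(16, 13, 12.6)), 11.39, "gi_contents",
           parent = 132, fetal = TRUE),
    .organ(134, "fetus, LI wall", "fetus LI wall",
           .ell(B + c(-32, 5, 103), c(15, 13, 14)), 6.03, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(135, "fetus, LI contents", "fetus LI contents",
           .ell(B + c(-32, 5, 103), c(11.5, 9.5, 12.1)), 5.95, "gi_contents",
           parent = 134, fetal = TRUE),
    .organ(136, "fetus, bladder wall", "fetus bladder wall",
           .ell(B + c(0, 6, 112), c(22, 19, 22)), 9.44, "fetal_soft",
           parent = 111, fetal = TRUE),
    .organ(137, "fetus, bladder contents", "fetus bladder contents",
           .ell(B + c(0, 6, 112), c(19.5, 16.5, 19.5)), 27.22, "urine",
           parent = 136, fetal = TRUE),
    .organ(114, "fetus, spine", "fetus skeleton",
           .cap(B + c(0, -22, 25), 9, 95, "z"), 33.00, "fetal_skeleton",
           parent = 111, fetal = TRUE),
    .organ(115, "fetus, spinal cord", "fetus spinal cord",
           .cap(B + c(0, -22, 25), 4.2, 95, "z"), 5.43, "fetal_soft",
           parent = 114, fetal = TRUE),
    .organ(116, "fetus, arm bones, left", "fetus skeleton",
           .cap(B + c(55, 0, -15), 7.5, 60, "z"), 15.8275, "fetal_skeleton",
           parent = 111, fetal = TRUE),
    .organ(117, "fetus, arm bones, right", "fetus skeleton",
           .cap(B + c(-55, 0, -15), 7.5, 60, "z"), 15.8275, "fetal_skeleton",
           parent = 111, fetal = TRUE),
    .organ(118, "fetus, leg bones, left", "fetus skeleton",
           .cap(B + c(0, 18, 70), 7, 70, "x"), 15.8275, "fetal_skeleton",
           parent = 111, fetal = TRUE),
    .organ(119, "fetus, leg bones, right", "fetus skeleton",
           .cap(B + c(0, 18, 84), 7, 70, "x"), 15.8275, "fetal_skeleton",
           parent = 111, fetal = TRUE),
    # --- maternal bladder (below the uterus, painted last) ---------------
    .organ(15, "urinary bladder wall", "urinary bladder wall",
           .sph(c(0, 70, -205), 40), 40.00, "soft_tissue"),
    .organ(16, "urinary bladder contents", "urinary bladder contents",
           .sph(c(0, 70, -205), 35.8), 200.00, "urine",
           parent = 15, source = TRUE)
  )
}

.minimal_layout <- function() {
  core <- .organ(1, "core", "core", .sph(c(0, 0, 25), 20), 35.0,
                 "soft_tissue", source = TRUE)
  wall <- .organ(2, "shell wall", "shell wall",
                 .ell(c(0, 0, -30), c(25, 20, 15)), 20.0, "soft_tissue")
  cont <- .organ(3, "shell contents", "shell contents",
                 .ell(c(0, 0, -30), c(15, 12, 9)), 7.0, "gi_contents",
                 parent = 2, source = TRUE)
  cube <- .organ(4, "cube", "cube",
                 primitive("box", c(42, 0, 0), half = c(10, 10, 10)),
                 8.4, "soft_tissue")
  # exercise the voxel wall-layering path: one peeled layer becomes label 5
  cube$wall <- list(n_layers = 1L, wall_label = 5L, wall_material = "skin",
                    wall_name = "cube crust", wall_region = "cube crust")
  list(core, wall, cont, cube)
}
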