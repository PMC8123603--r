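test_that("disulfide detection respects the SG-SG cut-off and greedy pairing", {
  two_cys <- function(d) {
    structure_model(rbind(
      data.frame(chain = "A", resno = 1L, resid = "CYS", elety = "SG",
                 elesy = "S", x = 0, y = 0, z = 0),
      data.frame(chain = "A", resno = 2L, resid = "CYS", elety = "SG",
                 elesy = "S", x = d, y = 0, z = 0)))
  }
  expect_equal(nrow(find_disulfides(two_cys(2.04))), 1L)
  expect_equal(nrow(find_disulfides(two_cys(5.0))), 0L)
  # three Cys in a row: the middle one bonds its nearest partner only
  three <- structure_model(data.frame(
    chain = "A", resno = 1:3, resid = "CYS", elety = "SG", elesy = "S",
    x = c(0, 2.0, 4.2), y = 0, z = 0))
  ss <- find_disulfides(three)
  expect_equal(nrow(ss), 1L)
  expect_equal(c(ss$res_a, ss$res_b), c(1L, 2L))
  # Cys without SG warns and is skipped
  no_sg <- structure_model(data.frame(
    chain = "A", resno = 1L, resid = "CYS", elety = "CA", elesy = "C",
    x = 0, y = 0, z = 0))
  expect_warning(find_disulfides(no_sg), "SG")
})

test_that("aromatic interaction types follow their residue definitions", {
  toy <- make_toy_structure(c("pi_pi_pair", "cation_pi_pair",
                              "amino_pi_pair", "his_pi_pair",
                              "sulfur_pi_pair"))
  cat <- find_aromatic_interactions(toy$model)
  expect_equal(sort(cat$type),
               sort(c("pi_pi", "cation_pi", "amino_pi", "his_pi",
                      "sulfur_pi")))
  # negated geometries produce an empty catalog
  neg <- make_toy_structure(paste0("no_", c("pi_pi_pair", "cation_pi_pair",
                                            "amino_pi_pair", "his_pi_pair",
                                            "sulfur_pi_pair")))
  expect_equal(nrow(find_aromatic_interactions(neg$model)), 0L)
  # a His near a Phe is a His-pi partner, never a cation
  his_phe <- make_toy_structure("his_pi_pair")
  cat2 <- find_aromatic_interactions(his_phe$model)
  expect_false("cation_pi" %in% cat2$type)
  # His pairs are not pi-pi (pi-pi is Phe/Tyr/Trp only)
  expect_false("pi_pi" %in% cat2$type)
})

test_that("raising a geometric cut-off never removes catalog entries", {
  toy <- make_toy_structure(rep(c("pi_pi_pair", "sulfur_pi_pair",
                                  "cation_pi_pair"), 2))
  thr <- default_interaction_thresholds()
  base <- find_aromatic_interactions(toy$model, thr)
  for (f in c("pi_pi", "sulfur_pi", "cation_pi")) {
    thr_up <- thr
    thr_up[[f]] <- thr[[f]] + 3
    bigger <- find_aromatic_interactions(toy$model, thr_up)
    key <- function(x) paste(x$type, x$res_a, x$res_b)
    expect_true(all(key(base) %in% key(bigger)))
  }
})

test_that("catalogs, accessibility and site distances are rigid-body invariant", {
  toy <- make_toy_structure(c("disulfide_pair", "pi_pi_pair", "zn_site",
                              "sulfur_pi_pair"))
  rot <- random_rotation(99)
  moved <- transform_structure(toy$model, rot, c(11.3, -40.2, 7.7))
  cat_a <- find_aromatic_interactions(toy$model)
  cat_b <- find_aromatic_interactions(moved)
  expect_equal(cat_a$distance, cat_b$distance, tolerance = 1e-6)
  expect_equal(cat_a[, 1:5], cat_b[, 1:5])
  expect_equal(find_disulfides(toy$model)$distance,
               find_disulfides(moved)$distance, tolerance = 1e-6)
  expect_equal(solvent_accessibility(toy$model, n_sphere_points = 240)$asa,
               solvent_accessibility(moved, n_sphere_points = 240)$asa,
               tolerance = 1e-6)
  expect_equal(
    site_distances(toy$model, 1L, zn_sites = "auto"),
    site_distances(moved, 1L, zn_sites = "auto"),
    tolerance = 1e-6)
})

test_that("solvent accessibility hits the clamped extremes", {
  lone <- make_toy_structure("exposed_residue")
  expect_equal(solvent_accessibility(lone$model)$rel_acc, 1.0)
  caged <- make_toy_structure("buried_cage")
  expect_equal(solvent_accessibility(caged$model)$rel_acc, 0.0)
  expect_error(solvent_accessibility(lone$model, n_sphere_points = 8),
               "12")
  expect_error(solvent_accessibility(lone$model, probe_radius = 0))
})

test_that("sphere-sampled accessibility agrees with a Monte-Carlo oracle", {
  for (seed in 1:3) {
    cloud <- random_atom_cloud(20, box = 8, seed = seed)
    sr <- solvent_accessibility(cloud, n_sphere_points = 960)
    xyz <- as.matrix(cloud$atoms[, c("x", "y", "z")])
    radii <- rep(1.70, 20)
    set.seed(seed + 100)
    mc <- mc_exposed_fraction(xyz, radii, probe = 1.4, n_samples = 2000)
    frac_sr <- sr$asa / (4 * pi * (1.70 + 1.4)^2)
    expect_true(all(abs(frac_sr - mc) < 0.05))
  }
})

test_that("site distances match an all-pairs atom scan", {
  toy <- make_toy_structure(c("disulfide_pair", "zn_site", "glyco_site",
                              "pi_pi_pair"))
  zn <- toy$model$hetero[toy$model$hetero$resid == "ZN", ]
  glyco_res <- toy$model$atoms$resno[toy$model$atoms$resid == "ASN"][1L]
  ss_res <- unique(toy$model$atoms$resno[toy$model$atoms$resid == "CYS"])
  for (query in unique(toy$model$atoms$resno)) {
    got <- site_distances(toy$model, query, zn_sites = "auto",
                          glyco_sites = glyco_res,
                          disulfide_cys = ss_res)
    at <- toy$model$atoms
    q_xyz <- as.matrix(at[at$resno == query, c("x", "y", "z")])
    expect_equal(got[["dist_metal"]],
                 naive_min_dist(q_xyz, as.matrix(zn[, c("x", "y", "z")])),
                 tolerance = 1e-9)
    expect_equal(got[["dist_carbohyd"]],
                 naive_min_dist(q_xyz, as.matrix(
                   at[at$resno == glyco_res, c("x", "y", "z")])),
                 tolerance = 1e-9)
    expect_equal(got[["dist_disulfide"]],
                 naive_min_dist(q_xyz, as.matrix(
                   at[at$resno %in% ss_res, c("x", "y", "z")])),
                 tolerance = 1e-9)
  }
  # a bridged Cys is at distance zero from the disulfide set
  expect_equal(site_distances(toy$model, ss_res[1L], zn_sites = NULL,
                              disulfide_cys = ss_res)[["dist_disulfide"]],
               0)
  # empty site sets report missing, not zero
  d <- site_distances(toy$model, 1L, zn_sites = NULL, glyco_sites = NULL,
                      disulfide_cys = NULL)
  expect_true(all(is.na(d)))
})

test_that("domain lookup uses the inclusive residue ranges", {
  expect_equal(domain_of(83), "saposin")
  expect_equal(domain_of(165), "saposin")
  expect_equal(domain_of(166), "linker")
  expect_equal(domain_of(198), "linker")
  expect_equal(domain_of(199), "catalytic")
  expect_equal(domain_of(612), "none")
  expect_equal(domain_of(c(1, 400)), c("none", "catalytic"))
  expect_error(domain_of(0))
})

test_that("substitution descriptors capture aromaticity and volume change", {
  d <- substitution_descriptor(c("F", "A", "H"), c("A", "V", "Y"))
  expect_equal(d$aromatic_change, c(TRUE, FALSE, FALSE))
  expect_equal(d$delta_volume[1L], 88.6 - 189.9)
  expect_true(substitution_descriptor("K", "E")$charge_change)
  expect_error(substitution_descriptor("A", "A"))
  expect_error(substitution_descriptor("A", "Z"))
})

test_that("structures and catalogs round-trip through files", {
  dir <- withr::local_tempdir()
  toy <- make_toy_structure(c("disulfide_pair", "pi_pi_pair", "zn_site"),
                            path = file.path(dir, "toy.pdb"))
  back <- read_structure(file.path(dir, "toy.pdb"))
  expect_equal(nrow(back$atoms), nrow(toy$model$atoms))
  expect_equal(find_disulfides(back)$distance,
               find_disulfides(toy$model)$distance, tolerance = 1e-3)
  cat_path <- file.path(dir, "catalog.tsv")
  cat0 <- find_aromatic_interactions(toy$model)
  write_interaction_catalog(cat0, cat_path)
  expect_equal(read_interaction_catalog(cat_path)$type, cat0$type)
  thr_path <- file.path(dir, "thr.yaml")
  thr <- default_interaction_thresholds()
  thr$pi_pi <- 6.5
  write_interaction_thresholds(thr, thr_path)
  expect_equal(read_interaction_thresholds(thr_path)$pi_pi, 6.5)
})
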