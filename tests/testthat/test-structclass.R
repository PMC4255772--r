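# Structure parsing, contact detection, ASA and site classification.

test_that("parse_structure reads chains, drops waters, routes hetero groups", {
  path <- fixture_two_chain()
  cx <- parse_structure(path, c(A = "mt", B = "nuclear"))
  expect_s3_class(cx, "complex_structure")
  expect_equal(sort(unique(cx$atoms$chain)), c("A", "B"))
  expect_equal(nrow(cx$residues), 6)

  # HETATM heme routed to hetero, chains unchanged
  atoms <- data.frame(type = c(rep("ATOM", 2), "HETATM"), eleno = 1:3,
                      elety = c("CA", "CA", "FE"),
                      resid = c("ALA", "ALA", "HEM"),
                      chain = c("A", "B", "A"), resno = c(1, 1, 90),
                      x = c(0, 20, 5), y = 0, z = 0)
  p2 <- write_fixture_pdb(atoms)
  cx2 <- parse_structure(p2, c(A = "mt", B = "nuclear"))
  expect_equal(nrow(cx2$residues), 2)
  expect_equal(length(unique(cx2$hetero$group)), 1)
  expect_true(all(cx2$hetero$is_heme))

  expect_error(parse_structure(path, c(A = "mt")), "encoding")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  atoms <- data.frame(type = "ATOM", eleno = 1:3, elety = "CA",
                      resid = "ALA", chain = "A", resno = c(1, 1, 2),
                      x = c(0, 5, 9), y = 0, z = 0)
  p <- write_fixture_pdb(atoms, alt = c("A", "B", " "), occ = c(0.3, 0.7, 1))
  cx <- parse_structure(p, c(A = "mt", B = "nuclear"), chain_filter = "A")
  a1 <- cx$atoms[cx$atoms$resno == 1, ]
  expect_equal(nrow(a1), 1)
  expect_equal(a1$x, 5)  # the occupancy-0.7 conformer
})

test_that("residue_min_distance is the exhaustive minimum and symmetric", {
  expect_equal(residue_min_distance(c(0, 0, 0), c(3, 0, 0)), 3)
  expect_equal(residue_min_distance(rbind(c(1, 2, 3), c(0, 0, 0)),
                                    rbind(c(1, 2, 3))), 0)
  set.seed(11)
  for (rep in 1:5) {
    a <- matrix(rnorm(15, sd = 5), 5)
    b <- matrix(rnorm(15, sd = 5), 5)
    brute <- min(vapply(1:5, function(i)
      min(sqrt(colSums((t(b) - a[i, ])^2))), numeric(1)))
    expect_equal(residue_min_distance(a, b), brute, tolerance = 1e-12)
    expect_equal(residue_min_distance(b, a),
                 residue_min_distance(a, b))
  }
  expect_error(residue_min_distance(matrix(0, 0, 3), c(0, 0, 0)), "atom")
})

test_that("contacts respect the cutoff, exclude hetero, and are symmetric", {
  path <- fixture_two_chain()
  cx <- parse_structure(path, c(A = "mt", B = "nuclear"))
  partners <- build_contact_labels(cx, cutoff = 4)
  expect_equal(partners[["A:3"]], "B")
  expect_equal(partners[["B:1"]], "A")
  others <- setdiff(names(partners), c("A:3", "B:1"))
  expect_true(all(lengths(partners[others]) == 0))
  # below-cutoff threshold: 3 A contact disappears at cutoff 2.9
  p2 <- build_contact_labels(cx, cutoff = 2.9)
  expect_true(all(lengths(p2) == 0))
  # monotonicity: larger cutoff never shrinks partner sets
  p8 <- build_contact_labels(cx, cutoff = 8)
  for (k in names(partners))
    expect_true(all(partners[[k]] %in% p8[[k]]))
})

test_that("ASA matches closed forms for isolated and disjoint atoms", {
  atoms <- data.frame(type = "ATOM", eleno = 1:2, elety = "CA",
                      resid = "ALA", chain = "A", resno = c(1, 2),
                      x = c(0, 50), y = 0, z = 0)
  p <- write_fixture_pdb(atoms)
  cx <- parse_structure(p, c(A = "mt"))
  asa <- compute_residue_asa(cx, sphere_points = 960)
  r <- 1.7 + 1.4  # carbon vdw + probe
  expect_equal(unname(asa[["A:1"]]), 4 * pi * r^2, tolerance = 1e-6)
  expect_equal(unname(sum(asa)), 2 * 4 * pi * r^2, tolerance = 1e-6)
  expect_error(compute_residue_asa(cx, probe_radius = -1), "probe")
})

test_that("ASA of two overlapping atoms matches an exact closed form", {
  # two equal spheres of radius R = r_vdw + probe at distance d: each loses
  # a spherical cap of height h = R - d/2; exposed area = 4 pi R^2 - 2 pi R h
  d <- 3
  atoms <- data.frame(type = "ATOM", eleno = 1:2, elety = "CA",
                      resid = "ALA", chain = "A", resno = c(1, 2),
                      x = c(0, d), y = 0, z = 0)
  p <- write_fixture_pdb(atoms)
  cx <- parse_structure(p, c(A = "mt"))
  asa <- compute_residue_asa(cx, sphere_points = 960)
  R <- 1.7 + 1.4
  h <- R - d / 2
  exact <- 4 * pi * R^2 - 2 * pi * R * h
  expect_equal(unname(asa[["A:1"]]), exact, tolerance = 0.02)
  expect_equal(unname(asa[["A:2"]]), exact, tolerance = 0.02)
})

test_that("classification recovers planted classes and interface flags", {
  toy <- make_toy_complex(seed = 7)
  cx <- toy$structure
  partners <- build_contact_labels(cx)
  asa2 <- compute_residue_asa(cx)
  asa1 <- unlist(lapply(names(cx$encoding), function(ch)
    compute_residue_asa(cx, chains = ch)))
  lab <- classify_sites(cx, asa1, asa2, partners)
  m <- merge(lab, toy$truth, by = "key")
  expect_equal(nrow(m), nrow(lab))
  expect_equal(mean(m$site_class == m$class), 1)
  en <- m$site_class == "EXPOSED_NONCONTACT"
  expect_equal(m$interface.x[en], m$interface.y[en])
  expect_true(all(is.na(m$interface.x[!en])))
  # delta-ASA is never negative and the four classes partition the set
  expect_true(all(lab$delta_asa >= 0))
  expect_true(all(lab$site_class %in% c("MT_NU_CONTACT", "MT_MT_CONTACT",
                                        "EXPOSED_NONCONTACT",
                                        "BURIED_NONCONTACT")))
  # contact classes coincide with nonempty partner sets
  expect_equal(lab$partners != "",
               lab$site_class %in% c("MT_NU_CONTACT", "MT_MT_CONTACT"))
})

test_that("zero contact fraction plants no contacts", {
  toy <- make_toy_complex(contact_fraction = 0, seed = 3)
  partners <- build_contact_labels(toy$structure)
  expect_true(all(lengths(partners) == 0))
  expect_false(any(toy$truth$class %in% c("MT_NU_CONTACT", "MT_MT_CONTACT")))
})

test_that("heme distances equal the brute-force minimum over heme groups", {
  toy <- make_toy_complex(seed = 7)
  cx <- toy$structure
  hd <- heme_min_distances(cx, "A")
  hem <- cx$hetero[cx$hetero$is_heme, ]
  at <- cx$atoms[cx$atoms$chain == "A", ]
  for (k in sample(names(hd), 5)) {
    xyz <- as.matrix(at[at$key == k, c("x", "y", "z")])
    brute <- min(vapply(seq_len(nrow(hem)), function(i)
      min(sqrt(colSums((t(xyz) - as.numeric(hem[i, c("x", "y", "z")]))^2))),
      numeric(1)))
    expect_equal(unname(hd[[k]]), brute, tolerance = 1e-9)
  }
  cx2 <- cx
  cx2$hetero <- cx2$hetero[0, ]
  expect_error(heme_min_distances(cx2, "A"), "heme")
})

test_that("labels round-trip through the TSV writer", {
  toy <- make_toy_complex(seed = 7)
  cx <- toy$structure
  partners <- build_contact_labels(cx)
  asa2 <- compute_residue_asa(cx)
  asa1 <- unlist(lapply(names(cx$encoding), function(ch)
    compute_residue_asa(cx, chains = ch)))
  lab <- classify_sites(cx, asa1, asa2, partners)
  p <- tempfile(fileext = ".tsv")
  write_labels_tsv(lab, p)
  lab2 <- read_labels_tsv(p)
  expect_equal(lab2$site_class, lab$site_class)
  expect_equal(lab2$asa_complex, lab$asa_complex, tolerance = 1e-8)
})
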