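# Geometric interaction classification against constructions and
# brute-force oracles.

test_that("contact cutoffs are inclusive at 6.0 A", {
  mk <- function(d_nm) make_toy_ens(rbind(c(0, 0, 0), c(d_nm, 0, 0)),
                                    c("C", "C"), c(1, 2),
                                    ligand = c(FALSE, TRUE))
  expect_true(residue_contact(mk(0.599), 1, 1, 2))
  expect_false(residue_contact(mk(0.601), 1, 1, 2))
  expect_true(residue_contact(mk(0.600), 1, 1, 2))
  expect_error(residue_contact(mk(0.5), 1, 1, integer(0)), "non-empty")
})

test_that("hydrophobic contacts require the right element pair within 4 A", {
  mk <- function(el_p, el_l, d_nm) {
    make_toy_ens(rbind(c(0, 0, 0), c(d_nm, 0, 0)), c(el_p, el_l), c(1, 2),
                 ligand = c(FALSE, TRUE))
  }
  expect_true(hydrophobic_contact(mk("C", "CL", 0.39), 1, 1))
  expect_false(hydrophobic_contact(mk("C", "CL", 0.41), 1, 1))
  expect_false(hydrophobic_contact(mk("N", "C", 0.30), 1, 1))  # excluded pair
  expect_true(hydrophobic_contact(mk("C", "C", 0.40), 1, 1))
})

test_that("hydrogen bonds respect the 3.5 A / 150 degree rule", {
  mk <- function(angle_deg, d_ha = 0.20) {
    # donor O - H along x; acceptor placed so the D-H-A angle is as given
    a <- angle_deg * pi / 180
    acc <- c(0.096 - d_ha * cos(a), d_ha * sin(a), 0)
    make_toy_ens(rbind(c(0, 0, 0), c(0.096, 0, 0), acc),
                 c("O", "H", "O"), c(1, 1, 2),
                 donor = c(TRUE, FALSE, FALSE),
                 acceptor = c(TRUE, FALSE, TRUE),
                 attached_h = list(`1` = 2L))
  }
  expect_equal(nrow(hydrogen_bonds(mk(180), 1)), 1)
  expect_equal(nrow(hydrogen_bonds(mk(140), 1)), 0)
  expect_equal(nrow(hydrogen_bonds(mk(160), 1)), 1)
  expect_equal(nrow(hydrogen_bonds(mk(180, d_ha = 0.36), 1)), 0)  # too long
  # same-residue donor/acceptor pairs are excluded by construction
  same <- make_toy_ens(rbind(c(0, 0, 0), c(0.096, 0, 0), c(0.3, 0, 0)),
                       c("O", "H", "O"), c(1, 1, 1),
                       donor = c(TRUE, FALSE, FALSE),
                       acceptor = c(TRUE, FALSE, TRUE),
                       attached_h = list(`1` = 2L))
  expect_equal(nrow(hydrogen_bonds(same, 1)), 0)
})

test_that("hydrogen bonds match brute-force enumeration on random frames", {
  set.seed(44)
  for (rep in 1:5) {
    n <- 20
    xyz <- matrix(runif(3 * n, 0, 1.2), n, 3)
    els <- rep(c("O", "H"), n / 2)
    res <- rep(seq_len(n / 2), each = 2)
    donor <- els == "O" & seq_len(n) %% 4 == 1
    acc <- els == "O"
    ah <- as.list(setNames(as.integer(which(donor) + 1), which(donor)))
    ens <- make_toy_ens(xyz, els, res, donor = donor, acceptor = acc,
                        attached_h = ah)
    got <- hydrogen_bonds(ens, 1)
    ref <- oracle_hbonds(ens, 1)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(got)) expect_equal(unname(as.matrix(got)), unname(ref))
  }
})

test_that("ring geometry reproduces constructed configurations", {
  r1 <- hexagon(c(0, 0, 0), normal = c(0, 0, 1))
  r2 <- hexagon(c(0, 0, 0.35), normal = c(0, 0, 1))
  ens <- make_toy_ens(rbind(r1, r2), rep("C", 12), rep(c(1, 2), each = 6),
                      ligand = rep(c(FALSE, TRUE), each = 6),
                      ring_groups = list(a = 1:6, b = 7:12))
  g <- ring_geometry(ens, 1, 1:6, 7:12)
  expect_equal(g$R, 0.35, tolerance = 1e-9)
  expect_lt(g$theta, 1e-6)
  expect_lt(g$phi, 1e-6)
  # perpendicular ring centered along A's normal: theta = 90, phi = 0
  r3 <- hexagon(c(0, 0, 0.5), normal = c(1, 0, 0))
  ens2 <- make_toy_ens(rbind(r1, r3), rep("C", 12), rep(c(1, 2), each = 6),
                       ring_groups = list(a = 1:6, b = 7:12))
  g2 <- ring_geometry(ens2, 1, 1:6, 7:12)
  expect_equal(g2$theta, 90, tolerance = 1e-6)
  expect_lt(g2$phi, 1e-6)
  # collinear "ring" is a degenerate-geometry error
  line <- cbind(seq(0, 0.5, length.out = 6), 0, 0)
  ens3 <- make_toy_ens(rbind(line, r1), rep("C", 12), rep(c(1, 2), each = 6))
  expect_error(ring_geometry(ens3, 1, 1:6, 7:12), "collinear")
})

test_that("ring geometry is invariant under a shared rigid transform", {
  r1 <- hexagon(c(0.1, 0, 0), normal = c(0, 1, 1))
  r2 <- hexagon(c(0.2, 0.4, 0.1), normal = c(1, 0, 0))
  both <- rbind(r1, r2)
  moved <- random_rigid(both, seed = 12)
  e1 <- make_toy_ens(both, rep("C", 12), rep(c(1, 2), each = 6))
  e2 <- make_toy_ens(moved, rep("C", 12), rep(c(1, 2), each = 6))
  g1 <- ring_geometry(e1, 1, 1:6, 7:12)
  g2 <- ring_geometry(e2, 1, 1:6, 7:12)
  expect_equal(g1$R, g2$R, tolerance = 1e-9)
  expect_equal(g1$theta, g2$theta, tolerance = 1e-6)
  expect_equal(g1$phi, g2$phi, tolerance = 1e-6)
})

test_that("stacking classes follow the R/theta/phi windows exclusively", {
  cf <- interaction_cutoffs()
  g <- function(R, theta, phi) list(R = R * 0.1, theta = theta, phi = phi)
  expect_equal(classify_stacking(g(3.5, 0, 0), cf), "parallel")
  expect_equal(classify_stacking(g(5.0, 90, 0), cf), "t_stack")
  expect_equal(classify_stacking(g(10.0, 0, 0), cf), "none")
  # theta boundaries: 59 parallel-eligible, 76 T-eligible, 60-75 dead zone
  expect_equal(classify_stacking(g(5.0, 59, 10), cf), "parallel")
  expect_equal(classify_stacking(g(5.0, 76, 10), cf), "t_stack")
  expect_equal(classify_stacking(g(5.0, 70, 10), cf), "none")
  expect_equal(classify_stacking(g(7.0, 50, 10), cf), "none")  # too far for parallel
})

test_that("profiles average per-frame classification and bound fractions count", {
  fx <- fx_adduct()
  ens <- fx$ens
  prof <- interaction_profile(ens)
  expect_true(all(prof$contact >= 0 & prof$contact <= 1))
  # hydrophobic contacts are a subset of contacts at matched residues
  expect_true(all(prof$hydrophobic <= prof$contact + 1e-12))
  # tethering residue neighbours are always in contact
  expect_equal(prof$contact[prof$residue %in% 13:15], rep(1, 3))
  # single-frame profile has populations in {0, 1}
  p1 <- interaction_profile(ens, frames = 1)
  expect_true(all(p1$contact %in% c(0, 1)))
  # profile equals the brute-force per-frame average for contacts
  a <- ens$topology$atoms
  lig_heavy <- a$id[a$ligand & a$heavy]
  for (r in c(5, 14, 30)) {
    manual <- mean(vapply(seq_len(n_frames(ens)), function(f) {
      xyz <- get_frame(ens, f)
      ids <- a$id[a$res_index == r & a$heavy]
      oracle_min_dist(xyz, ids, lig_heavy) <= 0.6
    }, logical(1)))
    expect_equal(prof$contact[prof$residue == r], manual, tolerance = 1e-12)
  }
  # hand-built bound fraction: 4 of 10 frames bound
  far <- ens
  far$coords <- ens$coords[rep(1, 10), , , drop = FALSE]
  lig_rows <- a$id[a$ligand]
  for (f in 5:10) far$coords[f, lig_rows, 1] <- far$coords[f, lig_rows, 1] + 50
  far$weights <- rep(0.1, 10)
  expect_equal(bound_fraction(far), 0.4)
})

test_that("profile r-squared matches hand-computed Pearson behavior", {
  p1 <- data.frame(contact = c(0.1, 0.4, 0.9, 0.2, 0.5))
  p2 <- data.frame(contact = c(0.2, 0.5, 0.7, 0.1, 0.6))
  expect_equal(profile_r2(p1, p1), 1.0)
  expect_equal(profile_r2(p1, data.frame(contact = 2 * p1$contact)), 1.0)
  expect_equal(profile_r2(p1, p2), cor(p1$contact, p2$contact)^2)
  flat <- data.frame(contact = rep(0.3, 5))
  expect_warning(r <- profile_r2(p1, flat), "zero-variance")
  expect_true(is.nan(r))
})
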