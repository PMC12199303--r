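# Synthetic-ensemble generator: determinism, helicity and compaction
# control, steric soundness, ligand decoration, pseudo-observables.

test_that("identical configs give bitwise-identical ensembles", {
  cfg <- generator_config(n_frames = 4, seed = 11)
  a <- sample_ensemble(cfg)
  b <- sample_ensemble(cfg)
  expect_identical(a$ensemble$coords, b$ensemble$coords)
  expect_identical(a$truth$states, b$truth$states)
})

test_that("mean helicity rises monotonically with uniform propensity", {
  fractions <- vapply(c(0, 0.5, 1), function(p) {
    out <- sample_ensemble(generator_config(n_frames = 200, seed = 13,
                                            helix_propensity = p,
                                            helix_cooperativity = 0))
    mean(helical_fraction(out$ensemble)$fraction)
  }, numeric(1))
  expect_lt(fractions[1], 0.05)
  expect_true(all(diff(fractions) > 0))
  expect_gt(fractions[3], 0.9)
})

test_that("fully helical chains reach the Salpha ceiling", {
  out <- sample_ensemble(generator_config(n_frames = 20, seed = 14,
                                          helix_propensity = 1))
  s <- salpha(out$ensemble)
  expect_true(all(abs(s - 50) / 50 < 0.1))
})

test_that("a stiffer Rg restraint pulls the ensemble closer to target", {
  rg_err <- vapply(c(50, 400), function(k) {
    out <- sample_ensemble(generator_config(n_frames = 15, seed = 15,
                                            rg_target = 1.2,
                                            rg_force_constant = k,
                                            mc_sweeps_per_frame = 10))
    abs(mean(out$truth$rg) - 1.2)
  }, numeric(1))
  expect_lt(rg_err[2], rg_err[1])
})

test_that("emitted frames have no heavy-atom pair under the steric floor", {
  # the chain invariant: non-bonded protein heavy atoms never interpenetrate
  for (fx in list(fx_coil(), list(ensemble = fx_adduct()$ens))) {
    ens <- fx$ensemble
    a <- ens$topology$atoms
    heavy <- a$id[a$heavy & !a$ligand]
    res <- a$res_index[heavy]
    for (f in seq_len(n_frames(ens))) {
      xyz <- get_frame(ens, f)[heavy, ] / 0.1  # Angstrom
      expect_equal(idpensemble:::.cpp_clash_count(xyz, as.integer(res), 2.5), 0)
    }
  }
})

test_that("pseudo-ligand construction is well-formed and reproducible", {
  fx <- fx_adduct()
  top <- fx$ens$topology
  ring <- top$ring_groups$ligand_ring
  expect_length(ring, 6)
  geom <- ring_geometry(fx$ens, 1, ring, ring)
  expect_lt(geom$theta, 1e-4)
  lig <- top$atoms[top$atoms$ligand, ]
  expect_setequal(unique(lig$element), c("C", "O", "H", "CL"))
  expect_equal(sum(lig$donor), 2)
  # tethered ligand always has a protein heavy atom within the 6 A cutoff
  expect_true(all(bound_frames(fx$ens)))
  # reproducible placement
  cfg <- generator_config(n_frames = 2, seed = 7)
  e1 <- attach_pseudo_ligand(sample_ensemble(cfg)$ensemble, 5, seed = 9)
  e2 <- attach_pseudo_ligand(sample_ensemble(cfg)$ensemble, 5, seed = 9)
  expect_identical(e1$coords, e2$coords)
  expect_error(attach_pseudo_ligand(sample_ensemble(cfg)$ensemble, 99), "range")
})

test_that("pseudo-observables follow the stated linear-noise model", {
  cfg <- generator_config(n_frames = 5, seed = 21,
                          observable_model = list(baseline = 10, delta = 0,
                                                  sigma = 0))
  out <- sample_ensemble(cfg)
  so <- synth_observables(out$ensemble, out$truth, seed = 1)
  expect_true(all(so$observables$values == 10))
  cfg2 <- generator_config(n_frames = 5, seed = 21,
                           observable_model = list(baseline = 10, delta = 2,
                                                   sigma = 0))
  out2 <- sample_ensemble(cfg2)
  so2 <- synth_observables(out2$ensemble, out2$truth, seed = 1)
  expect_equal(unname(so2$observables$values),
               unname(10 + 2 * out2$truth$states), tolerance = 1e-12)
  # uniform ground-truth weights reproduce the unbiased ensemble means
  expect_equal(unname(so2$observables$targets),
               unname(colMeans(10 + 2 * out2$truth$states)), tolerance = 1e-12)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(generator_config(helix_propensity = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(helix_cooperativity = 1), "cooperativity")
  expect_error(generator_config(rg_target = -1), "positive")
  expect_error(generator_config(n_frames = 0), "n_frames")
})
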