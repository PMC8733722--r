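test_that("exchange diagonal closes the Fock-matrix decomposition", {
  fx <- make_fixture(seed = 5)
  mf <- fx$mf
  sx <- sigma_x(mf)
  eri <- mf$eri_mo
  vh <- vapply(seq_len(4), function(p) {
    2 * sum(vapply(1:2, function(i) eri[p, p, i, i], numeric(1)))
  }, numeric(1))
  h_mo <- crossprod(mf$mo_coeff, fx$H$h_core %*% mf$mo_coeff)
  expect_equal(diag(h_mo) + vh + sx, mf$orbital_energies, tolerance = 1e-10)

  fx0 <- make_fixture(seed = 5, scale = 0)
  expect_equal(sigma_x(fx0$mf), rep(0, 4))
})

test_that("dimer exchange diagonal matches the hand contraction", {
  mf <- solve_rhf(build_hubbard_dimer(1, 2))
  ## bonding orbital: sigma_x = -(bb|bb) = -U/2
  expect_equal(sigma_x(mf)[1], -2 / 2, tolerance = 1e-12)
})

test_that("dynamic self-energies match the spin-orbital oracle", {
  grid <- test_grid(n = 50)
  eta <- 1e-3
  fixtures <- c(list(list(mf = solve_rhf(build_hubbard_dimer(1, 2)))),
                lapply(c(11, 23, 37), function(s) make_fixture(seed = s)))
  for (fx in fixtures) {
    mf <- fx$mf
    p <- mf$n_occ  # HOMO
    for (flag in c(TRUE, FALSE)) {
      sig <- sigma_pt2(mf, states = p, include_sox = flag, eta = eta)
      tag <- if (flag) "pt2" else "pt2-ring"
      expect_lt(
        max(abs(evaluate_selfenergy(sig, p, grid) -
                  sos_selfenergy(mf, tag, p, grid, eta = eta))),
        1e-10
      )
    }
    cs <- solve_casida(build_casida(mf, "rpa"))
    W <- build_w_residues(mf, cs, eta = eta)
    sg <- sigma_gw(mf, W, states = p)
    expect_lt(
      max(abs(evaluate_selfenergy(sg, p, grid) -
                sos_selfenergy(mf, "gw", p, grid, cs = cs, eta = eta))),
      1e-10
    )
    ss <- sigma_sosex(mf, W, states = p)
    expect_lt(
      max(abs(evaluate_selfenergy(ss, p, grid) -
                sos_selfenergy(mf, "sosex", p, grid, cs = cs, eta = eta))),
      1e-10
    )
  }
})

test_that("unscreened limits pin GW to the ring and SOSEX to SOX", {
  grid <- test_grid(n = 50)
  for (s in c(11, 23, 37)) {
    fx <- make_fixture(seed = s)
    mf <- fx$mf
    p <- 2
    Wb <- bare_screening(mf, eta = 1e-3)
    ring <- sigma_pt2(mf, states = p, include_sox = FALSE, eta = 1e-3)
    gw_b <- sigma_gw(mf, Wb, states = p)
    expect_lt(max(abs(evaluate_selfenergy(gw_b, p, grid) -
                        evaluate_selfenergy(ring, p, grid))), 1e-10)

    full <- sigma_pt2(mf, states = p, include_sox = TRUE, eta = 1e-3)
    sox_vals <- evaluate_selfenergy(full, p, grid) -
      evaluate_selfenergy(ring, p, grid)
    sosex_b <- sigma_sosex(mf, Wb, states = p)
    expect_lt(max(abs(evaluate_selfenergy(sosex_b, p, grid) - sox_vals)),
              1e-10)
  }
})

test_that("every correlation piece vanishes in the zero-interaction limit", {
  fx <- make_fixture(seed = 3, scale = 0)
  mf <- fx$mf
  grid <- test_grid(n = 20)
  sig <- sigma_pt2(mf, states = 1:2)
  expect_equal(max(abs(evaluate_selfenergy(sig, 2, grid))), 0)
  W <- screened_interaction(mf, "rpa")
  expect_equal(max(abs(evaluate_selfenergy(sigma_gw(mf, W, 1:2), 2, grid))), 0)
  expect_equal(max(abs(evaluate_selfenergy(sigma_sosex(mf, W, 1:2), 2, grid))), 0)
  dg <- gw_density_matrix(mf, W)
  expect_equal(max(abs(dg$delta_gamma)), 0)
  qp <- solve_graphical(sigma_gw(mf, W, 1:2), mf, 2)
  expect_equal(qp$E_qp, mf$orbital_energies[2], tolerance = 1e-8)
  expect_equal(qp$Z, 1, tolerance = 1e-10)
})

test_that("self-energies shrink smoothly as the interaction is scaled off", {
  fx <- make_fixture(seed = 11)
  base <- fx$mf$eri_mo
  grid <- test_grid(n = 11)
  prev <- Inf
  for (l in c(1, 0.3, 0.1, 0.03)) {
    mfl <- fx$mf
    mfl$eri_mo <- base * l
    v <- max(abs(evaluate_selfenergy(sigma_pt2(mfl, states = 2), 2, grid)))
    expect_lt(v, prev + 1e-15)
    prev <- v
  }
  expect_lt(prev, 1e-3)  # ~ lambda^2 suppression at the smallest scale
})

test_that("sum rule: omega * sigma tends to the accumulated residues", {
  fx <- make_fixture(seed = 23)
  sig <- sigma_pt2(fx$mf, states = 2)
  pl <- sig$poles[["2"]]
  w <- 1e7
  expect_equal(Re(w * evaluate_selfenergy(sig, 2, w, eta = 0)),
               sum(pl$residue), tolerance = 1e-6)
})

test_that("GW has nonnegative residues and negative slope between poles", {
  fx <- make_fixture(seed = 23)
  W <- screened_interaction(fx$mf, "rpa")
  sg <- sigma_gw(fx$mf, W, states = 2)
  expect_true(all(sg$poles[["2"]]$residue >= 0))
  scan <- selfenergy_slope_scan(sg, 2, window = c(-2, 1.5))
  expect_identical(nrow(scan), 0L)
})

test_that("the slope scanner flags an injected pathological region", {
  ## a negative residue (double-pole-like pathology) makes the slope
  ## positive in a finite region away from the pole
  sig <- new_selfenergy(
    "model", 1L, stats::setNames(0, "1"),
    list("1" = data.frame(position = 0, residue = -0.05, side = +1)),
    eta = 1e-3
  )
  scan <- selfenergy_slope_scan(sig, 1, window = c(-1, 1))
  expect_gt(nrow(scan), 0)
})

test_that("self-energies from Cholesky factors track the exact ones", {
  fx <- make_fixture(seed = 37)
  ri <- cholesky_eri(fx$H, tol = 1e-6)
  mf_ri <- fx$mf
  mf_ri$eri_mo <- tensor_rotate(ri_reconstruct(ri), fx$mf$mo_coeff)
  grid <- test_grid(n = 20)
  a <- evaluate_selfenergy(sigma_pt2(fx$mf, states = 2), 2, grid)
  b <- evaluate_selfenergy(sigma_pt2(mf_ri, states = 2), 2, grid)
  expect_lt(max(abs(a - b)), 10 * ri$recon_tol)
})

test_that("gamma-GW oo/vv blocks reduce to the direct MP2 density", {
  fx <- make_fixture(seed = 11)
  mf <- fx$mf
  eps <- mf$orbital_energies
  eri <- mf$eri_mo
  occ <- 1:2; virt <- 3:4
  dg <- gw_density_matrix(mf, bare_screening(mf))$delta_gamma
  for (i in occ) for (j in occ) {
    acc <- 0
    for (k in occ) for (a in virt) for (b in virt) {
      acc <- acc - 2 * eri[i, a, k, b] * eri[j, a, k, b] /
        ((eps[i] + eps[k] - eps[a] - eps[b]) *
           (eps[j] + eps[k] - eps[a] - eps[b]))
    }
    expect_equal(dg[i, j], acc, tolerance = 1e-10)
  }
  for (a in virt) for (b in virt) {
    acc <- 0
    for (i in occ) for (j in occ) for (c in virt) {
      acc <- acc + 2 * eri[i, a, j, c] * eri[i, b, j, c] /
        ((eps[i] + eps[j] - eps[a] - eps[c]) *
           (eps[i] + eps[j] - eps[b] - eps[c]))
    }
    expect_equal(dg[a, b], acc, tolerance = 1e-10)
  }
})

test_that("gamma-GW correction is Hermitian with tame occupations", {
  for (s in c(11, 23)) {
    fx <- make_fixture(seed = s)
    dg <- gw_density_matrix(fx$mf, screened_interaction(fx$mf, "rpa"))
    expect_lt(max(abs(dg$delta_gamma - t(dg$delta_gamma))), 1e-12)
    expect_lte(dg$trace_deviation, 0.05)
    ev <- eigen(diag(fx$mf$occupations) + dg$delta_gamma,
                symmetric = TRUE)$values
    expect_true(all(ev >= -0.05 & ev <= 2.05))
  }
})

test_that("gamma-GW stays finite for degenerate orbital energies", {
  ## h_core with exactly degenerate occupied and virtual pairs
  h <- diag(c(-1, -1, 1, 1))
  eri <- array(0, c(4, 4, 4, 4))
  l <- diag(0.3, 4)
  eri <- eri + outer(l, l)
  H <- hamiltonian(h, eri, 4L, label = "degenerate")
  mf <- solve_rhf(H)
  expect_lt(abs(mf$orbital_energies[1] - mf$orbital_energies[2]), 1e-10)
  dg <- gw_density_matrix(mf, screened_interaction(mf, "rpa"))
  expect_true(all(is.finite(dg$delta_gamma)))
  expect_lt(max(abs(dg$delta_gamma - t(dg$delta_gamma))), 1e-12)
})

test_that("the static contraction rebuilds Hartree + exchange from gamma0", {
  fx <- make_fixture(seed = 23)
  mf <- fx$mf
  g0 <- diag(mf$occupations)
  shift <- static_gamma_correction(mf, g0, states = 1:4)
  eri <- mf$eri_mo
  vh <- vapply(1:4, function(p) {
    2 * sum(vapply(1:2, function(i) eri[p, p, i, i], numeric(1)))
  }, numeric(1))
  expect_equal(unname(shift), vh + mf$sigma_x_diag, tolerance = 1e-12)

  ## linearity and the zero map
  dg <- gw_density_matrix(mf, screened_interaction(mf, "rpa"))
  s1 <- static_gamma_correction(mf, dg$delta_gamma, 1:2)
  s2 <- static_gamma_correction(mf, 2.5 * dg$delta_gamma, 1:2)
  expect_equal(unname(s2), 2.5 * unname(s1), tolerance = 1e-12)
  expect_equal(unname(static_gamma_correction(mf, matrix(0, 4, 4), 1:2)),
               c(0, 0))
})

test_that("PT1 terms vanish at Hartree-Fock for both readings", {
  fx <- make_fixture(seed = 5)
  expect_equal(max(abs(pt1_static(fx$mf, 1:2, "static"))), 0)
  expect_lt(max(abs(pt1_static(fx$mf, 1:2, "singles"))), 1e-12)
})

test_that("frozen-core drops the frozen occupied from all pair sums", {
  fx <- make_fixture(seed = 11)
  mf <- fx$mf
  grid <- test_grid(n = 10)
  full <- sigma_pt2(mf, states = 2)
  froz <- sigma_pt2(mf, states = 2, frozen_core = 1L)
  expect_gt(max(abs(evaluate_selfenergy(full, 2, grid) -
                      evaluate_selfenergy(froz, 2, grid))), 1e-8)
  expect_true(all(abs(froz$poles[["2"]]$position) < 1e3))
  ## frozen pole list excludes positions involving orbital 1's energy only
  expect_lt(nrow(froz$poles[["2"]]), nrow(full$poles[["2"]]))
})
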