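make_model_sigma <- function(static = 0, poles = NULL, eta = 0) {
  if (is.null(poles)) {
    poles <- data.frame(position = numeric(0), residue = numeric(0),
                        side = numeric(0))
  }
  new_selfenergy("model", 1L, stats::setNames(static, "1"),
                 list("1" = poles), eta)
}

model_mf <- function(eps_p) list(orbital_energies = eps_p, n_occ = 1L)

test_that("a constant self-energy shifts the level rigidly with Z = 1", {
  sig <- make_model_sigma(static = 0.17)
  qp <- solve_graphical(sig, model_mf(-0.5), 1, window = c(-2, 1),
                        grid_step = 1e-3, root_tol = 1e-10)
  expect_identical(nrow(qp$roots), 1L)
  expect_equal(qp$E_qp, -0.5 + 0.17, tolerance = 1e-8)
  expect_equal(qp$Z, 1, tolerance = 1e-12)
})

test_that("the single-pole model reproduces its quadratic closed form", {
  eps_p <- -0.5; r <- 0.04; w0 <- -0.9
  sig <- make_model_sigma(
    poles = data.frame(position = w0, residue = r, side = -1)
  )
  qp <- solve_graphical(sig, model_mf(eps_p), 1, window = c(-2, 1),
                        grid_step = 1e-3, root_tol = 1e-12)
  disc <- sqrt((eps_p - w0)^2 / 4 + r)
  expect_equal(sort(qp$roots$E), sort(c((eps_p + w0) / 2 + disc,
                                        (eps_p + w0) / 2 - disc)),
               tolerance = 1e-8)
  expect_equal(qp$roots$Z, 1 / (1 + r / (qp$roots$E - w0)^2),
               tolerance = 1e-8)
  expect_equal(sum(qp$roots$Z), 1, tolerance = 1e-8)
})

test_that("the largest-weight crossing is selected and all are reported", {
  ## two poles flanking the level: the nearer, weaker pole fragments the
  ## spectrum; selection must follow the weight, not the energy order
  eps_p <- -0.5
  poles <- data.frame(position = c(-0.45, -1.2), residue = c(0.002, 0.05),
                      side = c(-1, -1))
  sig <- make_model_sigma(poles = poles)
  qp <- solve_graphical(sig, model_mf(eps_p), 1, window = c(-2.2, 0.5),
                        grid_step = 5e-4)
  expect_gte(nrow(qp$roots), 3L)
  ## dense-grid enumeration oracle: the selected root maximizes Z
  expect_equal(qp$Z, max(qp$roots$Z[qp$roots$valid]), tolerance = 1e-12)
  expect_false(qp$E_qp == qp$highest_root &&
                 which.max(qp$roots$Z) != nrow(qp$roots))
  expect_lte(sum(qp$roots$Z[qp$roots$valid]), 1 + 1e-6)
})

test_that("every reported root satisfies the quasiparticle equation", {
  fx <- make_fixture(seed = 11)
  W <- screened_interaction(fx$mf, "rpa")
  sg <- sigma_gw(fx$mf, W, states = 1:2)
  for (p in 1:2) {
    qp <- solve_graphical(sg, fx$mf, p)
    resid <- abs(qp$roots$E - fx$mf$orbital_energies[p] -
                   Re(evaluate_selfenergy(sg, p, qp$roots$E)))
    ## residual bounded by tolerance times the local slope 1/Z
    expect_true(all(resid <= 1e-6 / pmax(abs(qp$roots$Z), 1e-3)))
    expect_true(qp$Z > 0 && qp$Z <= 1)
  }
})

test_that("analytic and finite-difference spectral weights agree", {
  fx <- make_fixture(seed = 23)
  W <- screened_interaction(fx$mf, "rpa")
  sg <- sigma_gw(fx$mf, W, states = 1:2)
  h <- 1e-5
  for (p in 1:2) {
    qp <- solve_graphical(sg, fx$mf, p)
    e <- qp$E_qp
    d_an <- Re(selfenergy_derivative(sg, p, e))
    d_fd <- Re(evaluate_selfenergy(sg, p, e + h) -
                 evaluate_selfenergy(sg, p, e - h)) / (2 * h)
    expect_lt(abs(1 / (1 - d_an) - 1 / (1 - d_fd)), 1e-6)
  }
})

test_that("with no self-energy the scan returns the Koopmans IP exactly", {
  fx <- make_fixture(seed = 5)
  res <- compute_ip(fx$mf, "none", n_scan = 2)
  expect_identical(res$ip_eV, koopmans_levels(fx$mf, 1)$ip_eV)
  expect_identical(res$state, fx$mf$n_occ)
})

test_that("the dimer GW pipeline is deterministic and benchmarked to FCI", {
  H <- build_hubbard_dimer(1, 2)
  run <- function() compute_ip(solve_rhf(H), "gw", n_scan = 1)$ip_eV
  ip1 <- run(); ip2 <- run()
  expect_identical(ip1, ip2)   # bit-for-bit reproducible
  err_eV <- ip1 - fci_ip(H) * HARTREE_TO_EV
  expect_lt(abs(err_eV), 1.5)  # coarse sanity band for this model system
})

test_that("widening the window never changes an interior selected root", {
  fx <- make_fixture(seed = 11)
  W <- screened_interaction(fx$mf, "rpa")
  sg <- sigma_gw(fx$mf, W, states = 2)
  e0 <- fx$mf$orbital_energies[2]
  qp1 <- solve_graphical(sg, fx$mf, 2, window = e0 + c(-1, 1))
  qp2 <- solve_graphical(sg, fx$mf, 2, window = e0 + c(-2, 2))
  expect_equal(qp1$E_qp, qp2$E_qp, tolerance = 1e-8)
})

test_that("an empty window raises a no-root error naming the remedy", {
  sig <- make_model_sigma(static = 0.5)
  err <- tryCatch(
    solve_graphical(sig, model_mf(-0.5), 1, window = c(-0.4, -0.3),
                    grid_step = 1e-3),
    error = identity
  )
  expect_s3_class(err, "mbpt_no_root_error")
  expect_match(conditionMessage(err), "window")
})

test_that("a state can overtake the mean-field HOMO after correction", {
  ## imported reference whose HOMO feels a strong repulsive potential:
  ## the quasiparticle scan must pick the deeper state instead
  fx <- make_fixture(seed = 11)
  mf <- fx$mf
  cont <- meanfield_container(mf)
  cont$vxc_diag[2] <- cont$vxc_diag[2] + 1.6
  mfi <- import_meanfield(cont, mo_hamiltonian(mf))
  res <- compute_ip(mfi, "gw", n_scan = 2, window_halfwidth = 2.5)
  expect_identical(res$state, 1L)
  expect_gt(res$solutions[["1"]]$E_qp, res$solutions[["2"]]$E_qp)
})

test_that("the spectral function is a normalized Lorentzian at zeroth order", {
  sig <- make_model_sigma(eta = 1e-3)
  mf1 <- model_mf(-0.5)
  grid <- seq(-4, 3, by = 2e-4)
  A <- spectral_function(sig, mf1, 1, grid, eta = 1e-3)
  expect_equal(grid[which.max(A)], -0.5, tolerance = 5e-4)
  expect_equal(sum(A) * 2e-4, 1, tolerance = 5e-3)
})

test_that("GW spectral weight integrates to one and peaks at the root", {
  mf <- solve_rhf(build_hubbard_dimer(1, 2))
  W <- screened_interaction(mf, "rpa")
  sg <- sigma_gw(mf, W, states = 1)
  step <- 5e-4
  grid <- seq(-9, 9, by = step)
  A <- spectral_function(sg, mf, 1, grid)
  expect_gte(sum(A) * step, 0.99)
  expect_lte(sum(A) * step, 1.01)
  qp <- solve_graphical(sg, mf, 1)
  expect_lt(abs(grid[which.max(A)] - qp$E_qp), 2 * step + 1e-6)
})
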