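# Shared fixtures, all generated in code at test time.

# Standard interacting 4-orbital fixture family.
make_fixture <- function(seed, n_orb = 4, n_elec = 4, scale = 0.2) {
  H <- build_random_hamiltonian(n_orb, n_elec, seed = seed,
                                interaction_scale = scale)
  list(H = H, mf = solve_rhf(H))
}

# A frequency grid that stays clear of self-energy poles (irrational offset).
test_grid <- function(lo = -1.5, hi = 1.0, n = 50) {
  seq(lo, hi, length.out = n) + 0.0137
}

# The fixture Hamiltonian re-expressed in its own converged MO basis,
# for mean-field import round trips.
mo_hamiltonian <- function(mf) {
  H <- mf$hamiltonian
  hamiltonian(
    crossprod(mf$mo_coeff, H$h_core %*% mf$mo_coeff),
    mf$eri_mo, H$n_elec, e_nuc = H$e_nuc,
    label = paste0(H$label, "|mo")
  )
}

# JSON-style container from a solved mean field (optionally perturbed).
meanfield_container <- function(mf, vxc_diag = mf$sigma_x_diag) {
  list(
    orbital_energies = mf$orbital_energies,
    occupations = mf$occupations,
    sigma_x_diag = mf$sigma_x_diag,
    vxc_diag = vxc_diag,
    e_total = mf$e_total,
    label = "container"
  )
}

# Engineered two-level reference whose exchange coupling can close the
# TDHF stability gap: a stand-in for a mean field that is not the lowest
# mean-field solution.  ERIs stay PSD for u <= 0.6.
unstable_reference <- function(u, gap = 0.2) {
  eri <- array(0, c(2, 2, 2, 2))
  eri[1, 1, 1, 1] <- 0.6
  eri[2, 2, 2, 2] <- 0.6
  eri[1, 1, 2, 2] <- u
  eri[2, 2, 1, 1] <- u
  H <- hamiltonian(diag(c(-gap / 2, gap / 2)), eri, 2L,
                   label = sprintf("unstable(u=%g)", u))
  cont <- list(
    orbital_energies = c(-gap / 2, gap / 2),
    occupations = c(2, 0),
    sigma_x_diag = c(0, 0),
    vxc_diag = c(0, 0),
    e_total = 0,
    label = "engineered"
  )
  import_meanfield(cont, H)
}
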