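#' Restricted Hartree-Fock solver
#'
#' Deterministic closed-shell RHF in the orthonormal input basis of the
#' Hamiltonian: core-Hamiltonian guess followed by DIIS-accelerated SCF
#' iterations.  Convergence is measured on the maximum absolute element
#' of the Fock-density commutator `[F, D]`, which vanishes at a
#' stationary point; orbital energies are the eigenvalues of the
#' converged Fock matrix.
#'
#' The returned model defines the non-interacting Green's function used
#' by every self-energy: per-orbital energies, occupations (0 or 2), the
#' diagonal exchange expectation values, and the diagonal of the
#' mean-field exchange-correlation potential.  For a Hartree-Fock
#' reference the latter equals the exchange diagonal, so the static part
#' of the self-energy difference vanishes and the dynamic correlation
#' self-energy alone shifts the orbital energies.
#'
#' @param H an [hamiltonian()].
#' @param conv_tol convergence threshold on `max(abs([F, D]))` (Hartree).
#' @param max_iter maximum SCF iterations.
#' @param diis_size DIIS subspace size.
#'
#' @return An object of class `mbpt_meanfield` with fields
#'   `orbital_energies`, `mo_coeff`, `occupations`, `sigma_x_diag`,
#'   `vxc_diag`, `reference_kind`, `e_total`, `hamiltonian`, `eri_mo`,
#'   `n_occ`, `fock_mo`, `conv_tol`.
#' @export
solve_rhf <- function(H, conv_tol = 1e-10, max_iter = 200, diis_size = 8) {
  n <- H$n_orb
  n_occ <- H$n_elec %/% 2L
  h <- H$h_core
  eri_jmat <- matrix(H$eri, n^2, n^2)                # (pq) x (rs)
  eri_kmat <- matrix(aperm(H$eri, c(1, 3, 4, 2)), n^2, n^2)  # rows (mu,nu), cols (la,si) of (mu la|si nu)

  fock_of <- function(D) {
    J <- matrix(eri_jmat %*% as.vector(D), n, n)
    K <- matrix(eri_kmat %*% as.vector(D), n, n)
    h + J - 0.5 * K
  }

  dens_of <- function(C) 2 * tcrossprod(C[, seq_len(n_occ), drop = FALSE])

  asc <- function(e) {
    ord <- order(e$values)
    list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
  }
  e0 <- asc(eigen(h, symmetric = TRUE))
  C <- e0$vectors
  D <- dens_of(C)
  err_hist <- list()
  fock_hist <- list()
  trace <- numeric(0)
  converged <- FALSE
  F_mat <- fock_of(D)
  for (it in seq_len(max_iter)) {
    err <- F_mat %*% D - D %*% F_mat
    res <- max(abs(err))
    trace <- c(trace, res)
    if (res <= conv_tol) {
      converged <- TRUE
      break
    }
    ## DIIS extrapolation
    err_hist <- c(err_hist, list(err))
    fock_hist <- c(fock_hist, list(F_mat))
    if (length(err_hist) > diis_size) {
      err_hist <- err_hist[-1]
      fock_hist <- fock_hist[-1]
    }
    m <- length(err_hist)
    F_use <- F_mat
    if (m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (a in seq_len(m)) for (b in seq_len(m)) {
        B[a, b] <- sum(err_hist[[a]] * err_hist[[b]])
      }
      B[m + 1, seq_len(m)] <- -1
      B[seq_len(m), m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      coef <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(coef) && all(is.finite(coef))) {
        F_use <- Reduce(`+`, Map(`*`, fock_hist, coef))
      }
    }
    eF <- asc(eigen(F_use, symmetric = TRUE))
    C <- eF$vectors
    D <- dens_of(C)
    F_mat <- fock_of(D)
  }
  if (!converged) {
    abort_convergence(
      paste(
        "RHF did not converge; a lower-energy symmetry-broken solution may",
        "exist for this system"
      ),
      residual_history = trace
    )
  }
  ## canonical orbitals of the converged Fock matrix, ascending energies
  eF <- asc(eigen(fock_of(D), symmetric = TRUE))
  C <- eF$vectors
  eps <- eF$values
  ## fix sign convention: largest-magnitude element positive
  for (p in seq_len(n)) {
    k <- which.max(abs(C[, p]))
    if (C[k, p] < 0) C[, p] <- -C[, p]
  }
  D <- dens_of(C)
  F_mat <- fock_of(D)
  e_total <- 0.5 * sum(D * (h + F_mat)) + H$e_nuc

  eri_mo <- tensor_rotate(H$eri, C)
  occ <- seq_len(n_occ)
  sigma_x <- vapply(seq_len(n), function(p) {
    -sum(vapply(occ, function(i) eri_mo[p, i, i, p], numeric(1)))
  }, numeric(1))

  structure(
    list(
      orbital_energies = eps,
      mo_coeff = C,
      occupations = c(rep(2, n_occ), rep(0, n - n_occ)),
      sigma_x_diag = sigma_x,
      vxc_diag = sigma_x,          # HF reference: static self-energy difference is zero
      reference_kind = "HF",
      e_total = e_total,
      hamiltonian = H,
      eri_mo = eri_mo,
      n_occ = n_occ,
      fock_mo = crossprod(C, F_mat %*% C),
      conv_tol = conv_tol
    ),
    class = "mbpt_meanfield"
  )
}

#' @export
print.mbpt_meanfield <- function(x, ...) {
  cat(sprintf(
    "<mbpt_meanfield> %s reference, %d orbitals (%d occupied), E = %.10f Ha\n",
    x$reference_kind, length(x$orbital_energies), x$n_occ, x$e_total
  ))
  invisible(x)
}

#' Export a mean-field model to a JSON container
#'
#' Serializes the fields needed to rebuild the non-interacting Green's
#' function (orbital energies, occupations, exchange and xc-potential
#' diagonals, total energy, label).  Integrals are not stored; pass a
#' companion FCIDUMP when re-importing if dynamic self-energies are
#' needed.
#'
#' @param mf an `mbpt_meanfield`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_meanfield <- function(mf, path) {
  obj <- list(
    orbital_energies = mf$orbital_energies,
    occupations = mf$occupations,
    sigma_x_diag = mf$sigma_x_diag,
    vxc_diag = mf$vxc_diag,
    e_total = mf$e_total,
    label = if (!is.null(mf$hamiltonian)) mf$hamiltonian$label else "imported"
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Import a mean-field model from a JSON container
#'
#' Adapter through which non-Hartree-Fock starting points (e.g. global
#' hybrid functionals with boosted exact exchange) enter: the container
#' provides orbital energies, occupations and the diagonal expectation
#' values of the Fock exchange operator and of the actual mean-field
#' exchange-correlation potential.  Downstream self-energies then use
#' the one-shot construction
#' `delta_sigma_pp(w) = sigma_x_pp - vxc_pp + sigma_c_pp(w)`.
#' The orbitals of the container are taken as the working basis
#' (`mo_coeff` is the identity), so a companion Hamiltonian, when given,
#' must already be expressed in that molecular-orbital basis.
#'
#' @param container path to a JSON file, or an equivalent named list.
#' @param hamiltonian optional [hamiltonian()] carrying MO-basis
#'   integrals for dynamic self-energies.
#' @return An `mbpt_meanfield` with `reference_kind = "imported(<label>)"`.
#' @export
import_meanfield <- function(container, hamiltonian = NULL) {
  obj <- if (is.character(container)) {
    jsonlite::read_json(container, simplifyVector = TRUE)
  } else {
    container
  }
  required <- c("orbital_energies", "occupations", "sigma_x_diag", "vxc_diag")
  for (f in required) {
    if (is.null(obj[[f]])) {
      abort_schema(sprintf("mean-field container is missing field '%s'", f),
                   field = f)
    }
  }
  eps <- as.numeric(obj$orbital_energies)
  occ <- as.numeric(obj$occupations)
  n <- length(eps)
  if (!all(occ %in% c(0, 2))) {
    abort_unsupported("occupations must be closed-shell (0 or 2)")
  }
  if (is.unsorted(eps)) {
    abort_schema("orbital_energies must be ascending")
  }
  if (any(diff(occ) > 0)) {
    abort_schema("occupied orbitals must precede virtuals")
  }
  n_occ <- as.integer(sum(occ) / 2)
  if (!is.null(hamiltonian)) {
    if (hamiltonian$n_orb != n) {
      abort_schema("companion Hamiltonian dimension mismatch")
    }
  }
  label <- if (!is.null(obj$label)) obj$label else "imported"
  structure(
    list(
      orbital_energies = eps,
      mo_coeff = diag(n),
      occupations = occ,
      sigma_x_diag = as.numeric(obj$sigma_x_diag),
      vxc_diag = as.numeric(obj$vxc_diag),
      reference_kind = sprintf("imported(%s)", label),
      e_total = if (!is.null(obj$e_total)) as.numeric(obj$e_total) else NA_real_,
      hamiltonian = hamiltonian,
      eri_mo = if (!is.null(hamiltonian)) hamiltonian$eri else NULL,
      n_occ = n_occ,
      fock_mo = diag(eps, n),
      conv_tol = NA_real_
    ),
    class = "mbpt_meanfield"
  )
}

#' Highest occupied Koopmans levels
#'
#' The `n_states` highest occupied orbital energies, reported highest
#' first as minus-orbital-energy in eV: the Koopmans estimate of the
#' ionization potential for each state, i.e. the zeroth-order (no
#' self-energy) limit of the quasiparticle scan.  Scanning several
#' states rather than only the mean-field HOMO matters because the
#' mean-field ordering need not match the quasiparticle ordering.
#'
#' @param mf an `mbpt_meanfield`.
#' @param n_states number of occupied states, at most `mf$n_occ`.
#' @return A data frame with columns `state` (MO index, highest first)
#'   and `ip_eV` (`-orbital energy` in eV).
#' @export
koopmans_levels <- function(mf, n_states = min(4L, mf$n_occ)) {
  if (n_states > mf$n_occ) {
    abort_input("n_states exceeds the number of occupied orbitals")
  }
  states <- seq(mf$n_occ, by = -1L, length.out = n_states)
  data.frame(
    state = states,
    ip_eV = -mf$orbital_energies[states] * HARTREE_TO_EV
  )
}

#' Static part of the self-energy difference
#'
#' `sigma_x - vxc` per orbital: identically zero for a native
#' Hartree-Fock reference, nonzero for imported hybrid starting points.
#' @noRd
static_delta_sigma <- function(mf) {
  mf$sigma_x_diag - mf$vxc_diag
}

#' MO-basis ERIs of a mean-field model (or error when absent)
#' @noRd
require_integrals <- function(mf) {
  if (is.null(mf$eri_mo)) {
    abort_capability(
      "this operation needs two-electron integrals; the mean-field model has none"
    )
  }
  mf$eri_mo
}
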