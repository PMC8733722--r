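#' Second-quantized Hamiltonian in an orthonormal orbital basis
#'
#' Container for the system definition used by every other component:
#' one-electron integrals, two-electron repulsion integrals (ERIs) in
#' chemists' notation `(pq|rs)`, the electron count and a constant
#' nuclear-repulsion offset.  Only closed-shell systems (even electron
#' count) are supported; open-shell inputs are rejected rather than
#' silently spin-averaged.
#'
#' @param h_core `n_orb x n_orb` symmetric one-electron matrix (Hartree).
#' @param eri rank-4 array, `eri[p,q,r,s] = (pq|rs)` in chemists'
#'   notation with full 8-fold permutational symmetry (Hartree).
#' @param n_elec even electron count, at most `2 * n_orb`.
#' @param e_nuc constant energy offset (Hartree).
#' @param label free-text identifier.
#'
#' @return An object of class `mbpt_hamiltonian` with fields `n_orb`,
#'   `n_elec`, `e_nuc`, `h_core`, `eri`, `label`.
#' @export
hamiltonian <- function(h_core, eri, n_elec, e_nuc = 0, label = "") {
  h_core <- as.matrix(h_core)
  n_orb <- nrow(h_core)
  if (ncol(h_core) != n_orb) {
    abort_format("h_core must be square")
  }
  if (!is.array(eri) || length(dim(eri)) != 4L || any(dim(eri) != n_orb)) {
    abort_format("eri must be an n_orb^4 array")
  }
  if (max(abs(h_core - t(h_core))) > 1e-12) {
    abort_format("h_core must be symmetric to 1e-12")
  }
  if (eri_symmetry_error(eri) > 1e-12) {
    abort_format("eri must have 8-fold permutational symmetry to 1e-12")
  }
  n_elec <- as.integer(n_elec)
  if (n_elec %% 2L != 0L) {
    abort_unsupported("odd electron counts are not supported (closed-shell only)")
  }
  if (n_elec < 0L || n_elec > 2L * n_orb) {
    abort_format("n_elec must lie in [0, 2 * n_orb]")
  }
  structure(
    list(
      n_orb = n_orb, n_elec = n_elec, e_nuc = as.numeric(e_nuc),
      h_core = h_core, eri = eri, label = as.character(label)
    ),
    class = "mbpt_hamiltonian"
  )
}

#' @export
print.mbpt_hamiltonian <- function(x, ...) {
  cat(sprintf(
    "<mbpt_hamiltonian> %s: %d orbitals, %d electrons, e_nuc = %.8f Ha\n",
    if (nzchar(x$label)) x$label else "(unnamed)", x$n_orb, x$n_elec, x$e_nuc
  ))
  invisible(x)
}

#' Two-site Hubbard dimer Hamiltonian
#'
#' The standard exactly solvable two-electron test system: hopping `-t`
#' between two sites and on-site repulsion `U`.  In the site basis
#' `h_core = [[0, -t], [-t, 0]]` and the only nonzero ERIs are
#' `(11|11) = (22|22) = U`.
#'
#' @param t hopping amplitude, positive (Hartree).
#' @param U on-site repulsion, nonnegative (Hartree).
#'
#' @return An [hamiltonian()] with two orbitals and two electrons.
#' @export
build_hubbard_dimer <- function(t = 1, U = 2) {
  stopifnot(t > 0, U >= 0)
  h <- matrix(c(0, -t, -t, 0), 2, 2)
  eri <- array(0, c(2, 2, 2, 2))
  eri[1, 1, 1, 1] <- U
  eri[2, 2, 2, 2] <- U
  hamiltonian(h, eri, n_elec = 2L,
              label = sprintf("hubbard-dimer(t=%g,U=%g)", t, U))
}

#' Seeded random closed-shell Hamiltonian
#'
#' Deterministic generator of small Hamiltonians used as desk-scale
#' stand-ins for molecular systems.  The ERI tensor is assembled as
#' `sum_m L[m] (x) L[m]` from random symmetric matrices `L[m]`, which
#' guarantees positive semidefiniteness and 8-fold symmetry by
#' construction.  The one-electron part is a well-spread diagonal plus a
#' small random symmetric perturbation, so that Hartree-Fock gaps stay
#' open for interaction scales well below the level spacing.
#'
#' @param n_orb orbital count (small values recommended so that the
#'   exact full-CI references stay tractable).
#' @param n_elec even electron count.
#' @param seed integer seed; identical seeds give bitwise-identical
#'   Hamiltonians.
#' @param interaction_scale magnitude of the two-electron integrals
#'   (Hartree); `0` gives a non-interacting system.
#'
#' @return An [hamiltonian()].
#' @export
build_random_hamiltonian <- function(n_orb = 4, n_elec = 4, seed = 1,
                                     interaction_scale = 0.2) {
  n_orb <- as.integer(n_orb)
  n_elec <- as.integer(n_elec)
  if (n_elec > 2L * n_orb) {
    abort_format("n_elec exceeds 2 * n_orb")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  spread <- seq(-2, 2, length.out = n_orb)
  pert <- matrix(stats::rnorm(n_orb^2, sd = 0.05), n_orb)
  h <- diag(spread, n_orb) + (pert + t(pert)) / 2

  eri <- array(0, c(n_orb, n_orb, n_orb, n_orb))
  if (interaction_scale > 0) {
    n_aux <- (n_orb * (n_orb + 1L)) %/% 2L   # full Cholesky rank
    for (m in seq_len(n_aux)) {
      l <- matrix(stats::rnorm(n_orb^2), n_orb)
      l <- (l + t(l)) / 2 * sqrt(interaction_scale / n_aux)
      eri <- eri + outer(l, l)
    }
  }
  hamiltonian(h, eri, n_elec = n_elec,
              label = sprintf("random(n=%d,seed=%d)", n_orb, seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Pivoted Cholesky factorization of the ERI tensor
#'
#' Decomposes the `(pq) x (rs)` matrix unfolding of the ERI tensor as
#' `sum_m L[m] (x) L[m]` with a guaranteed maximum absolute
#' reconstruction error, playing the role of the resolution-of-the-
#' identity factorization used in production Gaussian-basis codes, but
#' with a controllable error bound instead of a fitted auxiliary basis.
#'
#' @param H an [hamiltonian()].
#' @param tol requested bound on the max absolute reconstruction error
#'   (Hartree).
#'
#' @return An object of class `mbpt_ri_factors` with fields `n_aux`,
#'   `L` (array `n_aux x n_orb x n_orb`, each slice symmetric) and
#'   `recon_tol`, the achieved bound.
#' @export
cholesky_eri <- function(H, tol = 1e-8) {
  n <- H$n_orb
  m <- matrix(H$eri, n^2, n^2)
  d <- diag(m)
  if (min(d) < -tol) {
    abort_mbpt(
      sprintf("ERI matrix has a negative diagonal element (%.3e): not PSD", min(d)),
      "mbpt_non_psd_error"
    )
  }
  vecs <- list()
  resid_diag <- d
  piv_hist <- integer(0)
  repeat {
    piv <- which.max(resid_diag)
    dmax <- resid_diag[piv]
    if (dmax <= tol) break
    if (dmax < -tol) {
      abort_mbpt(
        sprintf("negative pivot %.3e beyond tolerance: not PSD", dmax),
        "mbpt_non_psd_error"
      )
    }
    col <- m[, piv]
    for (v in vecs) col <- col - v * v[piv]
    l <- col / sqrt(dmax)
    vecs[[length(vecs) + 1L]] <- l
    resid_diag <- resid_diag - l^2
    resid_diag <- pmax(resid_diag, 0)
    piv_hist <- c(piv_hist, piv)
    if (length(vecs) >= n^2) break
  }
  n_aux <- length(vecs)
  L <- array(0, c(max(n_aux, 1L), n, n))
  if (n_aux > 0) {
    for (k in seq_len(n_aux)) {
      lk <- matrix(vecs[[k]], n, n)
      L[k, , ] <- (lk + t(lk)) / 2
    }
  }
  if (n_aux == 0) L <- array(0, c(0L, n, n))
  recon <- ri_reconstruct(L, n)
  achieved <- if (length(recon)) max(abs(recon - H$eri)) else 0
  structure(
    list(n_aux = n_aux, L = L, recon_tol = achieved),
    class = "mbpt_ri_factors"
  )
}

#' Rebuild an ERI tensor from Cholesky/RI factors
#'
#' @param L `n_aux x n_orb x n_orb` factor array (or an
#'   `mbpt_ri_factors` object).
#' @param n_orb orbital count (ignored when `L` is an `mbpt_ri_factors`).
#' @return rank-4 ERI array.
#' @export
ri_reconstruct <- function(L, n_orb = NULL) {
  if (inherits(L, "mbpt_ri_factors")) {
    n_orb <- dim(L$L)[2]
    L <- L$L
  }
  n_aux <- dim(L)[1]
  n <- n_orb
  eri <- array(0, c(n, n, n, n))
  for (k in seq_len(n_aux)) {
    lk <- matrix(L[k, , ], n, n)
    eri <- eri + outer(lk, lk)
  }
  eri
}
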