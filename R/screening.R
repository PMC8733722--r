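#' Build Casida coupling matrices
#'
#' Assembles the linear-response `(A, B)` matrices over occupied-virtual
#' pairs `(i, a)` for the kernel families used to screen the Coulomb
#' interaction:
#'
#' * `A[ia,jb] = delta_ij delta_ab (e_a - e_i) + 2 (ia|jb) - k (ij|ab)`
#' * `B[ia,jb] = 2 (ia|jb) - k (ib|aj)`
#'
#' with `k = 0` for the random-phase approximation (ring diagrams only),
#' `k = 1` for time-dependent Hartree-Fock (interacting electron-hole
#' pairs), and `k = alpha` for an exchange-scaled hybrid kernel that
#' mirrors a time-dependent calculation with a global hybrid carrying a
#' fraction `alpha` of exact exchange (no semilocal kernel is included).
#'
#' @param mf an `mbpt_meanfield` with integrals.
#' @param kernel `"rpa"`, `"tdhf"`, or `"tddft"`.
#' @param alpha exchange fraction for `kernel = "tddft"`.
#' @return A list with `A`, `B`, `pairs` (matrix of `(i, a)` indices),
#'   and `kernel`.
#' @export
build_casida <- function(mf, kernel = c("rpa", "tdhf", "tddft"), alpha = 1) {
  kernel <- match.arg(kernel)
  k <- switch(kernel, rpa = 0, tdhf = 1, tddft = alpha)
  eri <- require_integrals(mf)
  eps <- mf$orbital_energies
  n <- length(eps)
  n_occ <- mf$n_occ
  occ <- seq_len(n_occ)
  virt <- setdiff(seq_len(n), occ)
  pairs <- as.matrix(expand.grid(i = occ, a = virt))
  n_ov <- nrow(pairs)
  A <- matrix(0, n_ov, n_ov)
  B <- matrix(0, n_ov, n_ov)
  for (t1 in seq_len(n_ov)) {
    i <- pairs[t1, 1]; a <- pairs[t1, 2]
    for (t2 in seq_len(n_ov)) {
      j <- pairs[t2, 1]; b <- pairs[t2, 2]
      A[t1, t2] <- 2 * eri[i, a, j, b] - k * eri[i, j, a, b]
      B[t1, t2] <- 2 * eri[i, a, j, b] - k * eri[i, b, a, j]
      if (t1 == t2) A[t1, t2] <- A[t1, t2] + eps[a] - eps[i]
    }
  }
  list(A = A, B = B, pairs = pairs, kernel = kernel)
}

#' Solve the Casida eigenproblem
#'
#' Solves the symplectic response problem through the symmetrized form
#' `(A-B)^(1/2) (A+B) (A-B)^(1/2) Z = Omega^2 Z`, returning positive
#' excitation energies and `(X+Y)` amplitudes normalized so that
#' `(X+Y)^T (X-Y) = I`.
#'
#' A non-positive eigenvalue of `A-B` or of the symmetrized product
#' signals a mean-field instability (e.g. a triplet instability of the
#' underlying Hartree-Fock solution); the solver then raises an
#' `mbpt_instability_error` naming the offending eigenvalue instead of
#' silently producing complex excitation energies.
#'
#' @param casida output of [build_casida()] (or a list with `A`, `B`,
#'   `pairs`, `kernel`).
#' @return An object of class `mbpt_casida`: `kernel`, `omegas`
#'   (ascending, Hartree), `xpy` (`n_ov x n_s`, one column per
#'   excitation), `pairs`, `normalization = "(X+Y)^T (X-Y) = I"`.
#' @export
solve_casida <- function(casida) {
  A <- casida$A
  B <- casida$B
  amb <- A - B
  e_amb <- eigen((amb + t(amb)) / 2, symmetric = TRUE)
  if (min(e_amb$values) <= 0) {
    abort_instability(
      sprintf(
        "response instability: A-B has a non-positive eigenvalue (%.8e); the mean-field reference is not a stable minimum",
        min(e_amb$values)
      ),
      eigenvalue = min(e_amb$values)
    )
  }
  s_half <- e_amb$vectors %*% (sqrt(e_amb$values) * t(e_amb$vectors))
  cmat <- s_half %*% (A + B) %*% s_half
  ec <- eigen((cmat + t(cmat)) / 2, symmetric = TRUE)
  if (min(ec$values) <= 0) {
    abort_instability(
      sprintf(
        "response instability: (A-B)^(1/2)(A+B)(A-B)^(1/2) has a non-positive eigenvalue (%.8e)",
        min(ec$values)
      ),
      eigenvalue = min(ec$values)
    )
  }
  ord <- order(ec$values)
  om2 <- ec$values[ord]
  z <- ec$vectors[, ord, drop = FALSE]
  omegas <- sqrt(om2)
  xpy <- s_half %*% z %*% diag(1 / sqrt(omegas), length(omegas))
  ## deterministic sign convention (eigenvector signs are arbitrary and
  ## all physical quantities are even in each amplitude column)
  for (s in seq_len(ncol(xpy))) {
    k <- which.max(abs(xpy[, s]))
    if (xpy[k, s] < 0) xpy[, s] <- -xpy[, s]
  }
  structure(
    list(
      kernel = casida$kernel,
      omegas = omegas,
      xpy = xpy,
      pairs = casida$pairs,
      normalization = "(X+Y)^T (X-Y) = I"
    ),
    class = "mbpt_casida"
  )
}

#' Screened-interaction pole expansion
#'
#' Contracts the bare transition integrals with the Casida amplitudes to
#' form the residues of the correlation part of the screened Coulomb
#' interaction,
#' `w_pq^s = sqrt(2) * sum_ia (pq|ia) (X+Y)^s_ia`,
#' for all molecular-orbital pairs `(p, q)`.  The spin-adaptation
#' constant `sqrt(2)` is pinned by the requirement that a GW self-energy
#' assembled from an unscreened (truncated) interaction coincide with
#' the direct ring term of second-order perturbation theory.
#'
#' @param mf an `mbpt_meanfield` with integrals.
#' @param cs an `mbpt_casida` solution.
#' @param eta default broadening attached to the interaction (Hartree).
#' @return An object of class `mbpt_screened`: `kernel`, `omegas`,
#'   `residues` (`n_orb x n_orb x n_s`), `eta`, plus the generating
#'   `xpy`/`pairs` (kept for the screened-exchange contraction).
#' @export
build_w_residues <- function(mf, cs, eta = 1e-3) {
  eri <- require_integrals(mf)
  n <- length(mf$orbital_energies)
  n_s <- length(cs$omegas)
  pairs <- cs$pairs
  n_ov <- nrow(pairs)
  ## M[(pq), t] = (pq | i_t a_t)
  M <- matrix(0, n * n, n_ov)
  for (t in seq_len(n_ov)) {
    M[, t] <- as.vector(eri[, , pairs[t, 1], pairs[t, 2]])
  }
  wmat <- sqrt(2) * (M %*% cs$xpy)
  structure(
    list(
      kernel = cs$kernel,
      omegas = cs$omegas,
      residues = array(wmat, c(n, n, n_s)),
      eta = eta,
      xpy = cs$xpy,
      pairs = pairs
    ),
    class = "mbpt_screened"
  )
}

#' Convenience wrapper: screened interaction from a mean field
#'
#' @param mf an `mbpt_meanfield` with integrals.
#' @param kernel,alpha passed to [build_casida()].
#' @param eta broadening (Hartree).
#' @return An `mbpt_screened`.
#' @export
screened_interaction <- function(mf, kernel = "rpa", alpha = 1, eta = 1e-3) {
  build_w_residues(mf, solve_casida(build_casida(mf, kernel, alpha)), eta = eta)
}

#' Unscreened (truncated) interaction in pole form
#'
#' Replaces the Casida amplitudes by unit vectors and the excitation
#' energies by the bare orbital-energy gaps: the screening series is cut
#' at zeroth order, so the "screened" interaction carries the bare
#' Coulomb matrix elements.  A GW self-energy built on this object
#' equals the PT2 ring term, and the screened-exchange correction
#' equals bare SOX; both identities are enforced in the test suite and
#' pin every normalization constant of the pole expansion.
#'
#' @param mf an `mbpt_meanfield` with integrals.
#' @param eta broadening (Hartree).
#' @return An `mbpt_screened` with one pole per occupied-virtual pair.
#' @export
bare_screening <- function(mf, eta = 1e-3) {
  eps <- mf$orbital_energies
  n <- length(eps)
  n_occ <- mf$n_occ
  occ <- seq_len(n_occ)
  virt <- setdiff(seq_len(n), occ)
  pairs <- as.matrix(expand.grid(i = occ, a = virt))
  n_ov <- nrow(pairs)
  cs <- structure(
    list(
      kernel = "bare",
      omegas = eps[pairs[, 2]] - eps[pairs[, 1]],
      xpy = diag(n_ov),
      pairs = pairs,
      normalization = "(X+Y)^T (X-Y) = I"
    ),
    class = "mbpt_casida"
  )
  build_w_residues(mf, cs, eta = eta)
}
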