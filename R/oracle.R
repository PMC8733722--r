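#' Exact full configuration interaction ground state
#'
#' Brute-force exact diagonalization of the second-quantized Hamiltonian
#' in a fixed Sz sector of the determinant space.  Serves as the
#' numerically exact reference (within the orbital basis) that all
#' perturbative results are judged against on small systems.
#'
#' Determinants are ordered spin-orbital occupation lists (all up spins
#' before all down spins) and matrix elements follow the Slater-Condon
#' rules; the lowest eigenvalue of the dense Hamiltonian matrix is
#' returned.
#'
#' @param H an [hamiltonian()].
#' @param n_elec electron count for the sector (defaults to `H$n_elec`;
#'   may differ, e.g. for cation energies).
#' @param sz total Sz of the sector (half-integer).
#' @param max_dim determinant-space cap for the dense diagonalization.
#'
#' @return An object of class `mbpt_fci` with fields `n_elec`, `energy`
#'   (Hartree), `spin_sector`, `basis_dim`.
#' @export
fci_ground_state <- function(H, n_elec = H$n_elec, sz = 0, max_dim = 4000) {
  n <- H$n_orb
  n_up <- as.integer(round(n_elec / 2 + sz))
  n_dn <- as.integer(n_elec - n_up)
  if (n_up < 0 || n_dn < 0 || n_up > n || n_dn > n) {
    abort_input("impossible (n_elec, sz) sector for this orbital count")
  }
  dets_up <- enumerate_occupations(n, n_up)
  dets_dn <- enumerate_occupations(n, n_dn)
  dim_tot <- length(dets_up) * length(dets_dn)
  if (dim_tot > max_dim) {
    abort_resource(
      sprintf("determinant space too large (%d > %d)", dim_tot, max_dim),
      basis_dim = dim_tot
    )
  }
  ## spin orbitals: 1..n = up, n+1..2n = down
  dets <- vector("list", dim_tot)
  k <- 0L
  for (du in dets_up) for (dd in dets_dn) {
    k <- k + 1L
    dets[[k]] <- c(du, dd + n)
  }
  so <- spinorb_integrals(H)
  Hmat <- matrix(0, dim_tot, dim_tot)
  for (a in seq_len(dim_tot)) {
    for (b in a:dim_tot) {
      el <- slater_condon(dets[[a]], dets[[b]], so)
      Hmat[a, b] <- el
      Hmat[b, a] <- el
    }
  }
  vals <- eigen(Hmat, symmetric = TRUE, only.values = TRUE)$values
  structure(
    list(
      n_elec = as.integer(n_elec),
      energy = min(vals) + H$e_nuc,
      spin_sector = sz,
      basis_dim = dim_tot
    ),
    class = "mbpt_fci"
  )
}

enumerate_occupations <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

## Spin-orbital integral accessors (1..n up, n+1..2n down).
spinorb_integrals <- function(H) {
  n <- H$n_orb
  spat <- function(P) ((P - 1L) %% n) + 1L
  spin <- function(P) (P - 1L) %/% n
  list(
    n = n,
    h = function(P, Q) {
      if (spin(P) != spin(Q)) return(0)
      H$h_core[spat(P), spat(Q)]
    },
    ## physicists' notation <PQ|RS> = (pr|qs) with spin deltas
    g = function(P, Q, R, S) {
      if (spin(P) != spin(R) || spin(Q) != spin(S)) return(0)
      H$eri[spat(P), spat(R), spat(Q), spat(S)]
    }
  )
}

## Slater-Condon matrix element between two ordered spin-orbital lists.
slater_condon <- function(d1, d2, so) {
  common <- intersect(d1, d2)
  r1 <- setdiff(d1, d2)
  r2 <- setdiff(d2, d1)
  nd <- length(r1)
  if (nd > 2L) return(0)
  g <- so$g
  h <- so$h
  if (nd == 0L) {
    e <- sum(vapply(d1, function(P) h(P, P), numeric(1)))
    if (length(d1) > 1L) {
      for (a in seq_along(d1)) {
        for (b in seq_along(d1)) {
          if (a < b) {
            P <- d1[a]; Q <- d1[b]
            e <- e + g(P, Q, P, Q) - g(P, Q, Q, P)
          }
        }
      }
    }
    return(e)
  }
  sgn <- excitation_sign(d1, d2, r1, r2)
  if (nd == 1L) {
    P <- r1; Q <- r2
    e <- h(P, Q)
    for (R in common) e <- e + g(P, R, Q, R) - g(P, R, R, Q)
    return(sgn * e)
  }
  P1 <- min(r1); P2 <- max(r1)
  Q1 <- min(r2); Q2 <- max(r2)
  sgn * (g(P1, P2, Q1, Q2) - g(P1, P2, Q2, Q1))
}

## Relative phase between determinants: replace the removed orbitals by
## the added ones (both in ascending order) inside the first list, then
## count the inversions needed to sort the result.
excitation_sign <- function(d1, d2, r1, r2) {
  r1 <- sort(r1); r2 <- sort(r2)
  mapped <- d1
  for (k in seq_along(r1)) {
    mapped[mapped == r1[k]] <- r2[k]
  }
  inv <- 0L
  m <- length(mapped)
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      if (mapped[a] > mapped[b]) inv <- inv + 1L
    }
  }
  if (inv %% 2L == 0L) 1 else -1
}

#' Exact ionization potential from total-energy differences
#'
#' `IP = E0(N-1) - E0(N)`, both sectors solved exactly by
#' [fci_ground_state()].  The cation sector is solved at `Sz = +1/2`
#' (the `-1/2` sector is degenerate in the absence of magnetic fields).
#'
#' @param H an [hamiltonian()].
#' @param max_dim determinant-space cap passed through.
#' @return Ionization potential in Hartree.
#' @export
fci_ip <- function(H, max_dim = 4000) {
  e_n <- fci_ground_state(H, H$n_elec, sz = 0, max_dim = max_dim)
  e_cat <- fci_ground_state(H, H$n_elec - 1L, sz = 0.5, max_dim = max_dim)
  e_cat$energy - e_n$energy
}

#' Brute-force spin-orbital sum-over-states self-energies
#'
#' Slow, literal nested-loop evaluation of each diagrammatic correlation
#' self-energy in the spin-orbital basis, without spin adaptation and
#' without any factorization.  This is the independent reference that
#' the production (spin-adapted, vectorized) self-energies are tested
#' against; it shares no code path with them beyond the mean-field
#' inputs.
#'
#' Tags: `"pt2-ring"` (direct second-order term), `"sox"` (second-order
#' exchange), `"pt2"` (their sum), `"gw"` (first order in a given
#' screened interaction), `"sosex"` (screened second-order exchange with
#' the given screened interaction).  The `gw` and `sosex` tags require a
#' Casida solution `cs`, whose singlet amplitudes are expanded over both
#' spin channels before the loops.
#'
#' @param mf an `mbpt_meanfield` carrying integrals.
#' @param order_spec diagram tag (see above).
#' @param p spatial MO index of the diagonal element.
#' @param omega_grid frequencies (Hartree).
#' @param cs `mbpt_casida` solution, for the screened tags.
#' @param eta broadening (Hartree); poles below the Fermi level get
#'   `-i eta`, poles above `+i eta`.
#' @return Complex vector of `sigma_c_pp(omega)` values.
#' @export
sos_selfenergy <- function(mf, order_spec, p, omega_grid, cs = NULL,
                           eta = 0) {
  eri <- require_integrals(mf)
  n <- length(mf$orbital_energies)
  n_occ <- mf$n_occ
  ## spin orbitals: 1..n up, n+1..2n down; same spatial energies
  eps_so <- c(mf$orbital_energies, mf$orbital_energies)
  occ_so <- c(seq_len(n_occ), n + seq_len(n_occ))
  virt_so <- setdiff(seq_len(2 * n), occ_so)
  spat <- function(P) ((P - 1L) %% n) + 1L
  spin <- function(P) (P - 1L) %/% n
  ## chemists' notation (PQ|RS) with spin deltas
  cg <- function(P, Q, R, S) {
    if (spin(P) != spin(Q) || spin(R) != spin(S)) return(0)
    eri[spat(P), spat(Q), spat(R), spat(S)]
  }
  P0 <- p  # external spin orbital: up channel of spatial p
  den_2p1h <- function(w, I, A, B) w + eps_so[I] - eps_so[A] - eps_so[B] + 1i * eta
  den_2h1p <- function(w, I, J, A) w + eps_so[A] - eps_so[I] - eps_so[J] - 1i * eta

  ring <- function(w) {
    acc <- 0 + 0i
    for (I in occ_so) for (A in virt_so) for (B in virt_so) {
      num <- cg(P0, A, I, B)^2
      if (num != 0) acc <- acc + num / den_2p1h(w, I, A, B)
    }
    for (I in occ_so) for (J in occ_so) for (A in virt_so) {
      num <- cg(P0, I, J, A)^2
      if (num != 0) acc <- acc + num / den_2h1p(w, I, J, A)
    }
    acc
  }
  sox <- function(w) {
    acc <- 0 + 0i
    for (I in occ_so) for (A in virt_so) for (B in virt_so) {
      num <- cg(P0, A, I, B) * cg(P0, B, I, A)
      if (num != 0) acc <- acc - num / den_2p1h(w, I, A, B)
    }
    for (I in occ_so) for (J in occ_so) for (A in virt_so) {
      num <- cg(P0, I, J, A) * cg(P0, J, I, A)
      if (num != 0) acc <- acc - num / den_2h1p(w, I, J, A)
    }
    acc
  }

  so_modes <- NULL
  if (order_spec %in% c("gw", "sosex")) {
    if (is.null(cs)) {
      abort_input("screened-interaction tags need a Casida solution 'cs'")
    }
    ## expand singlet (X+Y) over the two spin channels of each ov pair
    pairs <- cs$pairs
    n_s <- length(cs$omegas)
    so_pairs <- rbind(
      cbind(pairs[, 1], pairs[, 2]),                 # up channel (I, A)
      cbind(pairs[, 1] + n, pairs[, 2] + n)          # down channel
    )
    xpy_so <- rbind(cs$xpy, cs$xpy) / sqrt(2)
    so_modes <- list(omegas = cs$omegas, pairs = so_pairs, xpy = xpy_so,
                     n_s = n_s)
  }

  gw_fun <- function(w) {
    n_s <- so_modes$n_s
    acc <- 0 + 0i
    for (s in seq_len(n_s)) {
      om <- so_modes$omegas[s]
      ## residue w^s_{P0,M} by literal loops over spin-orbital ov pairs
      wres <- function(M) {
        v <- 0
        for (t in seq_len(nrow(so_modes$pairs))) {
          I <- so_modes$pairs[t, 1]; A <- so_modes$pairs[t, 2]
          v <- v + cg(P0, M, I, A) * so_modes$xpy[t, s]
        }
        v
      }
      for (I in occ_so) {
        acc <- acc + wres(I)^2 / (w - eps_so[I] + om - 1i * eta)
      }
      for (A in virt_so) {
        acc <- acc + wres(A)^2 / (w - eps_so[A] - om + 1i * eta)
      }
    }
    acc
  }

  sosex_fun <- function(w) {
    n_s <- so_modes$n_s
    acc <- 0 + 0i
    for (s in seq_len(n_s)) {
      om <- so_modes$omegas[s]
      np <- nrow(so_modes$pairs)
      for (A in virt_so) {
        u1 <- 0; u2 <- 0
        for (t in seq_len(np)) {
          I <- so_modes$pairs[t, 1]; B <- so_modes$pairs[t, 2]
          u1 <- u1 + cg(P0, A, I, B) * so_modes$xpy[t, s]
          u2 <- u2 + cg(P0, B, I, A) * so_modes$xpy[t, s]
        }
        acc <- acc - u1 * u2 / (w - eps_so[A] - om + 1i * eta)
      }
      for (I in occ_so) {
        u3 <- 0; u4 <- 0
        for (t in seq_len(np)) {
          K <- so_modes$pairs[t, 1]; B <- so_modes$pairs[t, 2]
          u3 <- u3 + cg(P0, I, B, K) * so_modes$xpy[t, s]
          u4 <- u4 + cg(P0, K, B, I) * so_modes$xpy[t, s]
        }
        acc <- acc - u3 * u4 / (w - eps_so[I] + om - 1i * eta)
      }
    }
    acc
  }

  fun <- switch(order_spec,
    "pt2-ring" = ring,
    "sox" = sox,
    "pt2" = function(w) ring(w) + sox(w),
    "gw" = gw_fun,
    "sosex" = sosex_fun,
    abort_input(sprintf("unknown diagram tag '%s'", order_spec))
  )
  vapply(omega_grid, fun, complex(1))
}
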