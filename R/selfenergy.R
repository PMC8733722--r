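#' Diagonal Fock-exchange expectation values
#'
#' `sigma_x_pp = - sum_i (pi|ip)` with `i` over occupied spatial
#' orbitals (spin-adapted closed-shell form).
#'
#' @param mf an `mbpt_meanfield` with integrals.
#' @return Numeric vector over all orbitals (Hartree).
#' @export
sigma_x <- function(mf) {
  eri <- require_integrals(mf)
  n <- length(mf$orbital_energies)
  occ <- seq_len(mf$n_occ)
  vapply(seq_len(n), function(p) {
    -sum(vapply(occ, function(i) eri[p, i, i, p], numeric(1)))
  }, numeric(1))
}

## Internal constructor for the diagonal self-energy container.
new_selfenergy <- function(method, states, static_pp, poles, eta) {
  structure(
    list(
      method = method,
      states = as.integer(states),
      static_pp = static_pp,   # named by state
      poles = poles,           # per state: data.frame(position, residue, side)
      eta = eta
    ),
    class = "mbpt_selfenergy"
  )
}

#' @export
print.mbpt_selfenergy <- function(x, ...) {
  np <- vapply(x$poles, nrow, integer(1))
  cat(sprintf(
    "<mbpt_selfenergy> %s, states {%s}, %s poles per state, eta = %g Ha\n",
    x$method, paste(x$states, collapse = ", "),
    paste(np, collapse = "/"), x$eta
  ))
  invisible(x)
}

#' Second-order (PT2) correlation self-energy
#'
#' Spin-adapted diagonal second-order self-energy with single poles in
#' the two particle - one hole (2p1h) and two hole - one particle
#' (2h1p) channels:
#'
#' * 2p1h: residue `(pa|ib) * (2 (pa|ib) - (pb|ia))` at `e_a + e_b - e_i`
#' * 2h1p: residue `(pi|ja) * (2 (pi|ja) - (pj|ia))` at `e_i + e_j - e_a`
#'
#' With `include_sox = FALSE` only the direct (ring) factor-2 numerators
#' are kept: the term shared between PT2 and GW.  The second-order
#' exchange (SOX) contribution carries the crossed numerators.
#'
#' @param mf an `mbpt_meanfield` with integrals.
#' @param states MO indices to cover (default: all occupied).
#' @param include_sox include the second-order exchange diagram.
#' @param eta broadening (Hartree).
#' @param include_pt1,pt1_variant first-order static term for non-HF
#'   references; see [pt1_static()].  Default off; identically zero for
#'   a Hartree-Fock reference by Brillouin's theorem.
#' @param frozen_core occupied MO indices excluded from all pair sums.
#' @return An `mbpt_selfenergy`.
#' @export
sigma_pt2 <- function(mf, states = seq_len(mf$n_occ), include_sox = TRUE,
                      eta = 1e-3, include_pt1 = FALSE,
                      pt1_variant = c("static", "singles"),
                      frozen_core = integer(0)) {
  eri <- require_integrals(mf)
  eps <- mf$orbital_energies
  n <- length(eps)
  occ <- setdiff(seq_len(mf$n_occ), frozen_core)
  virt <- setdiff(seq_len(n), seq_len(mf$n_occ))
  sox_w <- if (include_sox) 1 else 0

  poles <- lapply(states, function(p) {
    pos <- numeric(0); res <- numeric(0); side <- numeric(0)
    for (i in occ) for (a in virt) for (b in virt) {
      v <- eri[p, a, i, b]
      x <- eri[p, b, i, a]
      r <- v * (2 * v - sox_w * x)
      if (r != 0) {
        pos <- c(pos, eps[a] + eps[b] - eps[i])
        res <- c(res, r)
        side <- c(side, +1)
      }
    }
    for (i in occ) for (j in occ) for (a in virt) {
      v <- eri[p, i, j, a]
      x <- eri[p, j, i, a]
      r <- v * (2 * v - sox_w * x)
      if (r != 0) {
        pos <- c(pos, eps[i] + eps[j] - eps[a])
        res <- c(res, r)
        side <- c(side, -1)
      }
    }
    data.frame(position = pos, residue = res, side = side)
  })
  names(poles) <- as.character(states)

  static <- stats::setNames(rep(0, length(states)), as.character(states))
  if (include_pt1) {
    static <- static + pt1_static(mf, states, match.arg(pt1_variant))
  }
  new_selfenergy(
    if (include_sox) "PT2" else "PT2-ring",
    states, static, poles, eta
  )
}

#' First-order (PT1) static term for non-Hartree-Fock references
#'
#' When the mean field is not Hartree-Fock, Brillouin's theorem breaks
#' down and first-order terms appear in the strict order-by-order
#' expansion.  Their algebraic composition is convention-dependent, so
#' two readings are provided:
#'
#' * `"static"`: the diagonal first-order potential difference
#'   `sigma_x_pp - vxc_pp` evaluated with the reference density matrix;
#' * `"singles"`: additionally the static single-excitation shift
#'   `sum_{q != p} |dF_pq|^2 / (e_p - e_q)` from the off-diagonal
#'   elements of the Hartree-Fock operator built with the reference
#'   orbitals (requires integrals; zero at Hartree-Fock).
#'
#' Both vanish identically for a native Hartree-Fock reference.
#'
#' @param mf an `mbpt_meanfield`.
#' @param states MO indices.
#' @param variant `"static"` or `"singles"`.
#' @return Named numeric vector of static shifts (Hartree).
#' @export
pt1_static <- function(mf, states, variant = c("static", "singles")) {
  variant <- match.arg(variant)
  out <- static_delta_sigma(mf)[states]
  if (variant == "singles") {
    eri <- require_integrals(mf)
    if (is.null(mf$hamiltonian)) {
      abort_capability("the 'singles' PT1 variant needs a companion Hamiltonian")
    }
    eps <- mf$orbital_energies
    n <- length(eps)
    occ <- seq_len(mf$n_occ)
    ## HF Fock operator in the reference MO basis
    f <- crossprod(mf$mo_coeff, mf$hamiltonian$h_core %*% mf$mo_coeff)
    for (i in occ) {
      f <- f + 2 * eri[, , i, i] - eri[, i, i, ]
    }
    for (k in seq_along(states)) {
      p <- states[k]
      dq <- setdiff(seq_len(n), p)
      out[k] <- out[k] + sum(f[p, dq]^2 / (eps[p] - eps[dq]))
    }
  }
  stats::setNames(out, as.character(states))
}

#' GW correlation self-energy from a screened-interaction pole expansion
#'
#' `sigma_c_pp(w) = sum_s [ sum_i (w_pi^s)^2 / (w - e_i + Omega_s - i eta)
#'                        + sum_a (w_pa^s)^2 / (w - e_a - Omega_s + i eta) ]`
#'
#' All residues are squares, so the real part of the frequency
#' derivative is negative everywhere away from the poles: the correct
#' analytic structure of a single-pole self-energy.
#'
#' @param mf an `mbpt_meanfield`.
#' @param W an `mbpt_screened` built on the same mean field.
#' @param states MO indices to cover.
#' @param eta broadening (Hartree); defaults to the interaction's.
#' @param frozen_core occupied MO indices excluded from the hole sums.
#' @return An `mbpt_selfenergy` whose static part is the one-shot
#'   `sigma_x - vxc` difference (zero for a Hartree-Fock reference).
#' @export
sigma_gw <- function(mf, W, states = seq_len(mf$n_occ), eta = W$eta,
                     frozen_core = integer(0)) {
  eps <- mf$orbital_energies
  n <- length(eps)
  if (dim(W$residues)[1] != n) {
    abort_capability("screened interaction does not cover this orbital space")
  }
  occ <- setdiff(seq_len(mf$n_occ), frozen_core)
  virt <- setdiff(seq_len(n), seq_len(mf$n_occ))
  omegas <- W$omegas
  poles <- lapply(states, function(p) {
    wp <- matrix(W$residues[p, , ], nrow = n)   # q x s
    pos_occ <- outer(eps[occ], omegas, `-`)     # e_i - Omega_s
    res_occ <- wp[occ, , drop = FALSE]^2
    pos_virt <- outer(eps[virt], omegas, `+`)   # e_a + Omega_s
    res_virt <- wp[virt, , drop = FALSE]^2
    data.frame(
      position = c(as.vector(pos_occ), as.vector(pos_virt)),
      residue = c(as.vector(res_occ), as.vector(res_virt)),
      side = c(rep(-1, length(pos_occ)), rep(+1, length(pos_virt)))
    )
  })
  names(poles) <- as.character(states)
  static <- stats::setNames(static_delta_sigma(mf)[states], as.character(states))
  new_selfenergy("GW", states, static, poles, eta)
}

#' Screened second-order exchange (SOSEX) correction
#'
#' Second-order-exchange topology with one interaction line screened:
#' the bare electron-hole pair of each SOX channel is replaced by the
#' collective excitations of the screened interaction, in both places
#' where the pair indices enter the numerator.  With the screening
#' truncated (see [bare_screening()]) the correction collapses to the
#' bare SOX diagram, which pins the construction; with an RPA-screened
#' interaction it is the screened-exchange vertex correction added on
#' top of GW.  The result is returned as an additive correction (its
#' static part is zero).
#'
#' @inheritParams sigma_gw
#' @return An `mbpt_selfenergy` with `method = "SOSEX"`.
#' @export
sigma_sosex <- function(mf, W, states = seq_len(mf$n_occ), eta = W$eta,
                        frozen_core = integer(0)) {
  eri <- require_integrals(mf)
  eps <- mf$orbital_energies
  n <- length(eps)
  if (is.null(W$xpy)) {
    abort_capability("SOSEX needs the generating response amplitudes in W")
  }
  occ <- setdiff(seq_len(mf$n_occ), frozen_core)
  virt <- setdiff(seq_len(n), seq_len(mf$n_occ))
  omegas <- W$omegas
  n_s <- length(omegas)
  pairs <- W$pairs
  n_ov <- nrow(pairs)
  xpy <- W$xpy

  poles <- lapply(states, function(p) {
    pos <- numeric(0); res <- numeric(0); side <- numeric(0)
    for (s in seq_len(n_s)) {
      for (a in virt) {
        t1 <- 0; t2 <- 0
        for (t in seq_len(n_ov)) {
          i <- pairs[t, 1]; b <- pairs[t, 2]
          t1 <- t1 + eri[p, a, i, b] * xpy[t, s]
          t2 <- t2 + eri[p, b, i, a] * xpy[t, s]
        }
        r <- -t1 * t2
        if (r != 0) {
          pos <- c(pos, eps[a] + omegas[s])
          res <- c(res, r)
          side <- c(side, +1)
        }
      }
      for (i in occ) {
        t3 <- 0; t4 <- 0
        for (t in seq_len(n_ov)) {
          k <- pairs[t, 1]; b <- pairs[t, 2]
          t3 <- t3 + eri[p, i, k, b] * xpy[t, s]
          t4 <- t4 + eri[p, k, b, i] * xpy[t, s]
        }
        r <- -t3 * t4
        if (r != 0) {
          pos <- c(pos, eps[i] - omegas[s])
          res <- c(res, r)
          side <- c(side, -1)
        }
      }
    }
    data.frame(position = pos, residue = res, side = side)
  })
  names(poles) <- as.character(states)
  static <- stats::setNames(rep(0, length(states)), as.character(states))
  new_selfenergy("SOSEX", states, static, poles, eta)
}

#' Add two diagonal self-energy models on the same states
#'
#' @param a,b `mbpt_selfenergy` objects covering the same states.
#' @param method label for the combined model.
#' @return An `mbpt_selfenergy`.
#' @export
selfenergy_add <- function(a, b, method = paste(a$method, b$method, sep = "+")) {
  if (!identical(a$states, b$states)) {
    abort_input("self-energy models cover different states")
  }
  poles <- stats::setNames(lapply(as.character(a$states), function(s) {
    rbind(a$poles[[s]], b$poles[[s]])
  }), as.character(a$states))
  new_selfenergy(method, a$states, a$static_pp + b$static_pp, poles, a$eta)
}

#' Add a per-state static shift to a self-energy model
#' @param sigma an `mbpt_selfenergy`.
#' @param shifts named (by state) or positional numeric vector (Hartree).
#' @param method new label (default: keep).
#' @return An `mbpt_selfenergy`.
#' @export
selfenergy_shift <- function(sigma, shifts, method = sigma$method) {
  sigma$static_pp <- sigma$static_pp + shifts
  sigma$method <- method
  sigma
}

#' Evaluate a diagonal self-energy difference
#'
#' `delta_sigma_pp(w) = static_pp + sum_k r_k / (w - pos_k + i side_k eta)`,
#' complex-valued; the quasiparticle equation uses its real part.
#'
#' @param sigma an `mbpt_selfenergy`.
#' @param state covered MO index.
#' @param omega frequency or vector of frequencies (Hartree).
#' @param eta override of the stored broadening.
#' @return Complex vector.
#' @export
evaluate_selfenergy <- function(sigma, state, omega, eta = sigma$eta) {
  key <- as.character(state)
  if (!key %in% names(sigma$poles)) {
    abort_capability(sprintf("state %s not covered by this self-energy", key))
  }
  pl <- sigma$poles[[key]]
  st <- sigma$static_pp[[key]]
  vapply(omega, function(w) {
    st + sum(pl$residue / (w - pl$position + 1i * pl$side * eta))
  }, complex(1))
}

#' Frequency derivative of a diagonal self-energy difference
#'
#' Analytic residue-sum derivative, used for spectral weights.
#'
#' @inheritParams evaluate_selfenergy
#' @return Complex vector `d sigma / d w`.
#' @export
selfenergy_derivative <- function(sigma, state, omega, eta = sigma$eta) {
  key <- as.character(state)
  pl <- sigma$poles[[key]]
  vapply(omega, function(w) {
    -sum(pl$residue / (w - pl$position + 1i * pl$side * eta)^2)
  }, complex(1))
}

#' Scan for pathological positive-slope regions
#'
#' The exact self-energy has a negative real frequency derivative away
#' from its poles; a positive slope produces spectral weights above one
#' and signals a pathological analytic structure (double poles and the
#' like in higher-order approximations).  This diagnostic walks a grid,
#' skips a safety radius around every pole, and reports the grid
#' segments where the real part of the analytic derivative is positive.
#'
#' @param sigma an `mbpt_selfenergy`.
#' @param state covered MO index.
#' @param window `c(lo, hi)` scan window (Hartree).
#' @param grid_step grid spacing (Hartree).
#' @param exclude_radius half-width of the exclusion zone around each
#'   pole (Hartree); defaults to `5 * eta`.
#' @return A data frame with columns `omega` and `slope` for the
#'   offending grid points (zero rows when the analytic structure is
#'   clean).
#' @export
selfenergy_slope_scan <- function(sigma, state, window, grid_step = 2e-3,
                                  exclude_radius = 5 * sigma$eta) {
  grid <- seq(window[1], window[2], by = grid_step)
  pl <- sigma$poles[[as.character(state)]]
  keep <- vapply(grid, function(w) {
    !length(pl$position) || min(abs(w - pl$position)) > exclude_radius
  }, logical(1))
  grid <- grid[keep]
  slope <- Re(selfenergy_derivative(sigma, state, grid))
  bad <- slope > 0
  data.frame(omega = grid[bad], slope = slope[bad])
}

#' Linearized GW correction to the one-particle reduced density matrix
#'
#' First-order-in-W correction to the mean-field (spin-summed) density
#' matrix, obtained from the energy-integrated `G0 Sigma_c G0` with the
#' GW pole expansion.  All pole sums are closed-form; the
#' occupied-occupied, virtual-virtual, and occupied-virtual blocks are
#' assembled from analytically combined expressions in which the
#' degenerate-denominator limits have already been taken, so no
#' numerical frequency integration and no divided differences appear.
#'
#' With the screening truncated ([bare_screening()]), the
#' occupied-occupied and virtual-virtual blocks reduce to the direct
#' (ring) part of the unrelaxed MP2 one-particle density matrix, which
#' is the independent check applied in the test suite.
#'
#' @param mf an `mbpt_meanfield` (Hartree-Fock-like reference; at a
#'   self-consistent GW Green's function the correction would vanish).
#' @param W an `mbpt_screened`.
#' @param frozen_core occupied MO indices excluded from the hole sums.
#' @return An object of class `mbpt_dgamma`: `delta_gamma` (symmetric
#'   matrix, spin-summed electrons) and `trace_deviation` (absolute
#'   trace, electrons; linearization does not conserve particle number
#'   exactly).
#' @export
gw_density_matrix <- function(mf, W, frozen_core = integer(0)) {
  eps <- mf$orbital_energies
  n <- length(eps)
  occ <- setdiff(seq_len(mf$n_occ), frozen_core)
  virt <- setdiff(seq_len(n), seq_len(mf$n_occ))
  omegas <- W$omegas
  n_s <- length(omegas)
  w <- W$residues
  dg <- matrix(0, n, n)

  ## oo block: holes dug by the virtual-side poles
  for (i in occ) for (j in occ) {
    acc <- 0
    for (s in seq_len(n_s)) {
      da <- (eps[i] - eps[virt] - omegas[s]) * (eps[j] - eps[virt] - omegas[s])
      acc <- acc - sum(w[i, virt, s] * w[j, virt, s] / da)
    }
    dg[i, j] <- acc
  }
  ## vv block: particles promoted by the occupied-side poles
  for (a in virt) for (b in virt) {
    acc <- 0
    for (s in seq_len(n_s)) {
      da <- (eps[occ] - eps[a] - omegas[s]) * (eps[occ] - eps[b] - omegas[s])
      acc <- acc + sum(w[a, occ, s] * w[b, occ, s] / da)
    }
    dg[a, b] <- acc
  }
  ## ov block (and its transpose), analytically combined form
  for (i in occ) for (a in virt) {
    d <- eps[i] - eps[a]
    acc <- 0
    for (s in seq_len(n_s)) {
      acc <- acc + sum(w[i, virt, s] * w[a, virt, s] /
                         ((eps[i] - eps[virt] - omegas[s]) * d))
      acc <- acc - sum(w[i, occ, s] * w[a, occ, s] /
                         (d * (eps[occ] - omegas[s] - eps[a])))
    }
    dg[i, a] <- acc
    dg[a, i] <- acc
  }
  structure(
    list(delta_gamma = dg, trace_deviation = abs(sum(diag(dg)))),
    class = "mbpt_dgamma"
  )
}

#' Static Hartree and exchange shifts from a density-matrix correction
#'
#' Contracts a (spin-summed) density-matrix correction with the bare
#' Coulomb interaction to produce the per-state static self-energy
#' shift
#' `shift_p = sum_rs dg_rs (pp|rs) - 1/2 sum_rs dg_rs (pr|sp)`:
#' the first-order change of the Hartree plus Fock-exchange expectation
#' values.  Feeding the full mean-field density matrix itself rebuilds
#' the Hartree + exchange diagonal of the Fock operator exactly, which
#' fixes the spin conventions.
#'
#' @param mf an `mbpt_meanfield` with integrals.
#' @param dgamma an `mbpt_dgamma` (or a bare matrix).
#' @param states MO indices to evaluate.
#' @return Named numeric vector of shifts (Hartree).
#' @export
static_gamma_correction <- function(mf, dgamma, states = seq_len(mf$n_occ)) {
  eri <- require_integrals(mf)
  dg <- if (inherits(dgamma, "mbpt_dgamma")) dgamma$delta_gamma else dgamma
  out <- vapply(states, function(p) {
    sum(dg * eri[p, p, , ]) - 0.5 * sum(dg * eri[p, , , p])
  }, numeric(1))
  stats::setNames(out, as.character(states))
}
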