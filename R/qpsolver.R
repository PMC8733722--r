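#' Graphical solution of the quasiparticle equation
#'
#' Solves `w - e_p = Re delta_sigma_pp(w)` for one state by walking a
#' frequency grid, bracketing every sign change of
#' `f(w) = w - e_p - Re delta_sigma_pp(w)`, and refining each bracket by
#' bisection.  Every crossing gets a spectral weight
#' `Z = 1 / (1 - d Re delta_sigma / d w)` from the analytic residue-sum
#' derivative; crossings whose weight falls outside `(0, 1]` (grid
#' artifacts inside pole regions, or pathological analytic structure)
#' are reported but never selected.  Among the valid crossings the one
#' with the largest spectral weight — the principal quasiparticle peak —
#' is selected; the energetically highest root is also reported so the
#' choice is auditable.
#'
#' @param sigma an `mbpt_selfenergy` covering `p`.
#' @param mf the `mbpt_meanfield` defining `e_p`.
#' @param p MO index.
#' @param window `c(lo, hi)` search window (Hartree); default
#'   `e_p +/- 1`.
#' @param grid_step grid spacing (Hartree).  A warning is issued when it
#'   exceeds the broadening, since poles could then slip between grid
#'   points.
#' @param root_tol bisection tolerance (Hartree).
#' @return An object of class `mbpt_qpsolution`: `state`, `roots` (data
#'   frame with `E`, `Z`, `valid`), `selected` (row index), `E_qp`, `Z`,
#'   `highest_root`, `diagnostics`.
#' @export
solve_graphical <- function(sigma, mf, p, window = NULL, grid_step = 2e-3,
                            root_tol = 1e-8) {
  eps_p <- mf$orbital_energies[p]
  if (is.null(window)) window <- c(eps_p - 1, eps_p + 1)
  if (sigma$eta > 0 && grid_step > 2 * sigma$eta) {
    warning(sprintf(
      "grid step (%g) exceeds twice the broadening (%g): poles could be skipped",
      grid_step, sigma$eta
    ), call. = FALSE)
  }
  f <- function(w) w - eps_p - Re(evaluate_selfenergy(sigma, p, w))
  grid <- seq(window[1], window[2], by = grid_step)
  if (grid[length(grid)] < window[2]) grid <- c(grid, window[2])
  fv <- f(grid)

  roots <- numeric(0)
  for (k in seq_len(length(grid) - 1)) {
    if (fv[k] == 0) {
      roots <- c(roots, grid[k])
    } else if (fv[k] * fv[k + 1] < 0) {
      lo <- grid[k]; hi <- grid[k + 1]
      flo <- fv[k]
      while (hi - lo > root_tol) {
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (fm == 0) { lo <- mid; hi <- mid; break }
        if (flo * fm < 0) hi <- mid else { lo <- mid; flo <- fm }
      }
      cand <- (lo + hi) / 2
      ## discard sign changes across a bare pole (f stays large there)
      if (abs(f(cand)) < 1e-3) roots <- c(roots, cand)
    }
  }
  if (fv[length(fv)] == 0) roots <- c(roots, grid[length(grid)])
  roots <- sort(unique(roots))
  if (!length(roots)) {
    abort_mbpt(
      sprintf(
        "no quasiparticle solution in [%.4f, %.4f] Ha for state %d; widen the search window",
        window[1], window[2], p
      ),
      "mbpt_no_root_error",
      list(window = window, state = p)
    )
  }
  zval <- 1 / (1 - Re(selfenergy_derivative(sigma, p, roots)))
  valid <- zval > 0 & zval <= 1
  slope_up <- sum(diff(Re(evaluate_selfenergy(sigma, p, grid))) > 0)
  sel <- if (any(valid)) which(valid)[which.max(zval[valid])] else NA_integer_
  structure(
    list(
      state = p,
      roots = data.frame(E = roots, Z = zval, valid = valid),
      selected = sel,
      E_qp = if (!is.na(sel)) roots[sel] else NA_real_,
      Z = if (!is.na(sel)) zval[sel] else NA_real_,
      highest_root = roots[length(roots)],
      diagnostics = list(
        window = window, grid_step = grid_step, root_tol = root_tol,
        n_positive_slope_segments = slope_up
      )
    ),
    class = "mbpt_qpsolution"
  )
}

#' @export
print.mbpt_qpsolution <- function(x, ...) {
  cat(sprintf(
    "<mbpt_qpsolution> state %d: %d root(s), E_qp = %.6f Ha (Z = %.4f)\n",
    x$state, nrow(x$roots), x$E_qp, x$Z
  ))
  invisible(x)
}

#' Ionization potential from a multi-state quasiparticle scan
#'
#' Builds the requested self-energy, solves the quasiparticle equation
#' for the `n_scan` highest occupied states, and returns
#' `IP = -max_p E_qp` over the scanned states in eV.  Scanning several
#' states (four by default) cures the possible incorrect ordering of
#' the mean-field levels: the state hosting the highest quasiparticle
#' root need not be the mean-field HOMO.
#'
#' Methods: `"none"` (Koopmans), `"pt0"` (static shift only), `"pt2"`,
#' `"pt2-ring"`, `"gw"`, `"gw+sosex"`, `"gw+gamma"`.  GW-family methods
#' screen the interaction with the kernel selected by `w_kernel`.
#'
#' @param mf an `mbpt_meanfield`.
#' @param sigma_method method tag (above).
#' @param n_scan number of occupied states scanned (capped at
#'   `mf$n_occ`).
#' @param w_kernel `"rpa"`, `"tdhf"`, or `"tddft"` for the screening
#'   kernel of the GW-family methods.
#' @param alpha exchange fraction for `w_kernel = "tddft"`.
#' @param eta broadening (Hartree).
#' @param window_halfwidth half-width of each state's search window
#'   (Hartree).
#' @param grid_step quasiparticle grid spacing (Hartree).
#' @param include_pt1,pt1_variant first-order static term for PT2 on
#'   non-Hartree-Fock references (see [pt1_static()]).
#' @param frozen_core occupied MO indices excluded from correlation
#'   sums.
#' @return A list: `ip_eV`, `state` (hosting the highest root),
#'   `solutions` (per scanned state), `method`, `settings`.
#' @export
compute_ip <- function(mf,
                       sigma_method = c("gw", "none", "pt0", "pt2", "pt2-ring",
                                        "gw+sosex", "gw+gamma"),
                       n_scan = 4L,
                       w_kernel = "rpa", alpha = 1,
                       eta = 1e-3,
                       window_halfwidth = 1.0, grid_step = 2e-3,
                       include_pt1 = FALSE, pt1_variant = "static",
                       frozen_core = integer(0)) {
  sigma_method <- match.arg(sigma_method)
  n_scan <- min(as.integer(n_scan), mf$n_occ)
  states <- seq(mf$n_occ, by = -1L, length.out = n_scan)

  if (sigma_method == "none") {
    sols <- lapply(states, function(p) {
      structure(
        list(
          state = p,
          roots = data.frame(E = mf$orbital_energies[p], Z = 1, valid = TRUE),
          selected = 1L,
          E_qp = mf$orbital_energies[p], Z = 1,
          highest_root = mf$orbital_energies[p],
          diagnostics = list()
        ),
        class = "mbpt_qpsolution"
      )
    })
  } else {
    sigma <- build_sigma(mf, sigma_method, states,
                         w_kernel = w_kernel, alpha = alpha, eta = eta,
                         include_pt1 = include_pt1, pt1_variant = pt1_variant,
                         frozen_core = frozen_core)
    sols <- lapply(states, function(p) {
      solve_graphical(
        sigma, mf, p,
        window = mf$orbital_energies[p] + c(-1, 1) * window_halfwidth,
        grid_step = grid_step
      )
    })
  }
  e_qp <- vapply(sols, function(s) s$E_qp, numeric(1))
  best <- which.max(e_qp)
  list(
    ip_eV = -e_qp[best] * HARTREE_TO_EV,
    state = states[best],
    solutions = stats::setNames(sols, as.character(states)),
    method = sigma_method,
    settings = list(
      w_kernel = w_kernel, alpha = alpha, eta = eta,
      window_halfwidth = window_halfwidth, grid_step = grid_step,
      n_scan = n_scan, include_pt1 = include_pt1
    )
  )
}

## Assemble the self-energy model for a method tag.
build_sigma <- function(mf, sigma_method, states, w_kernel = "rpa", alpha = 1,
                        eta = 1e-3, include_pt1 = FALSE,
                        pt1_variant = "static", frozen_core = integer(0)) {
  static_only <- function() {
    poles <- stats::setNames(
      rep(list(data.frame(position = numeric(0), residue = numeric(0),
                          side = numeric(0))), length(states)),
      as.character(states)
    )
    new_selfenergy(
      "PT0", states,
      stats::setNames(static_delta_sigma(mf)[states], as.character(states)),
      poles, eta
    )
  }
  if (sigma_method == "pt0") return(static_only())
  if (sigma_method %in% c("pt2", "pt2-ring")) {
    return(sigma_pt2(
      mf, states, include_sox = (sigma_method == "pt2"), eta = eta,
      include_pt1 = include_pt1, pt1_variant = pt1_variant,
      frozen_core = frozen_core
    ))
  }
  W <- screened_interaction(mf, kernel = w_kernel, alpha = alpha, eta = eta)
  sg <- sigma_gw(mf, W, states, eta = eta, frozen_core = frozen_core)
  if (sigma_method == "gw") return(sg)
  if (sigma_method == "gw+sosex") {
    return(selfenergy_add(
      sg, sigma_sosex(mf, W, states, eta = eta, frozen_core = frozen_core),
      method = "GW+SOSEX"
    ))
  }
  ## gw+gamma: GW plus the static Hartree/exchange shift from the
  ## linearized GW density-matrix correction
  dg <- gw_density_matrix(mf, W, frozen_core = frozen_core)
  shifts <- static_gamma_correction(mf, dg, states)
  selfenergy_shift(sg, shifts, method = "GW+gammaGW")
}

#' Diagonal spectral function
#'
#' `A_p(w) = (1/pi) |Im G_pp(w)|` from the diagonal Dyson inversion,
#' with the broadening added to the (tiny) imaginary part of the
#' self-energy so that every quasiparticle pole appears as a Lorentzian
#' of width `eta`.  Normalized per spin: the integral over a wide
#' window tends to one.
#'
#' @param sigma an `mbpt_selfenergy` covering `p` (may have no poles).
#' @param mf the `mbpt_meanfield`.
#' @param p MO index.
#' @param omega_grid frequencies (Hartree).
#' @param eta Lorentzian broadening (Hartree).
#' @return Numeric vector of `A_p` values (1/Hartree).
#' @export
spectral_function <- function(sigma, mf, p, omega_grid, eta = sigma$eta) {
  eps_p <- mf$orbital_energies[p]
  sig <- evaluate_selfenergy(sigma, p, omega_grid)
  gam <- eta + abs(Im(sig))
  de <- omega_grid - eps_p - Re(sig)
  (1 / pi) * gam / (de^2 + gam^2)
}
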