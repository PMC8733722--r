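#' Hartree to electron-volt conversion factor
#'
#' All internal energies are in Hartree atomic units; conversion to eV is
#' applied only at reporting boundaries (CODATA 2018 value).
#'
#' @format A length-one numeric.
#' @export
HARTREE_TO_EV <- 27.211386245988

## Condition constructors -------------------------------------------------

mbpt_error <- function(message, class, data = list()) {
  structure(
    class = c(class, "mbpt_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
}

abort_mbpt <- function(message, class, data = list()) {
  stop(mbpt_error(message, class, data))
}

#' @noRd
abort_format <- function(message, ...) {
  abort_mbpt(message, "mbpt_format_error", list(...))
}

#' @noRd
abort_unsupported <- function(message, ...) {
  abort_mbpt(message, "mbpt_unsupported_system_error", list(...))
}

#' @noRd
abort_instability <- function(message, eigenvalue) {
  abort_mbpt(message, "mbpt_instability_error", list(eigenvalue = eigenvalue))
}

#' @noRd
abort_convergence <- function(message, residual_history) {
  abort_mbpt(message, "mbpt_convergence_error",
             list(residual_history = residual_history))
}

#' @noRd
abort_schema <- function(message, field = NULL) {
  abort_mbpt(message, "mbpt_schema_error", list(field = field))
}

#' @noRd
abort_capability <- function(message) {
  abort_mbpt(message, "mbpt_capability_error")
}

#' @noRd
abort_resource <- function(message, ...) {
  abort_mbpt(message, "mbpt_resource_error", list(...))
}

#' @noRd
abort_input <- function(message) {
  abort_mbpt(message, "mbpt_input_error")
}

## Small numerical helpers ------------------------------------------------

#' Symmetric matrix square root via eigendecomposition
#' @noRd
sym_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (any(e$values <= 0)) {
    abort_instability(
      sprintf(
        "matrix is not positive definite (smallest eigenvalue %.6e)",
        min(e$values)
      ),
      eigenvalue = min(e$values)
    )
  }
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

#' Rotate a rank-4 chemists'-notation integral tensor into a new basis
#'
#' Applies the same orthogonal coefficient matrix to all four indices,
#' one mode at a time.  Used to transform ERIs from the input basis to
#' the molecular-orbital basis.
#' @noRd
tensor_rotate <- function(eri, coeff) {
  n <- dim(eri)[1]
  x <- eri
  for (k in 1:4) {
    m <- matrix(x, n, n^3)
    x <- array(crossprod(coeff, m), c(n, n, n, n))
    x <- aperm(x, c(2, 3, 4, 1))
  }
  x
}

#' Maximum absolute deviation from 8-fold permutational ERI symmetry
#' @noRd
eri_symmetry_error <- function(eri) {
  max(
    max(abs(eri - aperm(eri, c(2, 1, 3, 4)))),
    max(abs(eri - aperm(eri, c(1, 2, 4, 3)))),
    max(abs(eri - aperm(eri, c(3, 4, 1, 2))))
  )
}
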