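#' Read a Hamiltonian from an FCIDUMP file
#'
#' Parses the Molpro-style FCIDUMP interchange format: a `&FCI ... &END`
#' (or `/`) namelist header carrying `NORB` and `NELEC`, followed by one
#' value line per permutation-unique integral with 1-based indices in
#' chemists' notation.  Lines with `k = l = 0` are one-electron
#' integrals, the `0 0 0 0` line is the constant offset, and the full
#' 8-fold permutational symmetry of the ERI tensor is completed on read.
#' Point-group labels (`ORBSYM`, `ISYM`) are accepted and ignored; all
#' systems are treated as C1.  Only real orbitals and even electron
#' counts are supported.
#'
#' @param path path to an FCIDUMP file.
#' @return An [hamiltonian()].
#' @export
read_fcidump <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !grepl("^&", lines[[1]])) {
    abort_format("FCIDUMP must start with a namelist header ('&FCI ...')")
  }
  ## collect header lines up to &END or /
  hdr_end <- NA_integer_
  for (i in seq_along(lines)) {
    if (grepl("(&END|/)\\s*$", lines[[i]], ignore.case = TRUE)) {
      hdr_end <- i
      break
    }
  }
  if (is.na(hdr_end)) {
    abort_format("FCIDUMP header is not terminated by '&END' or '/'")
  }
  header <- paste(lines[1:hdr_end], collapse = " ")
  get_field <- function(name) {
    m <- regmatches(
      header,
      regexpr(sprintf("%s\\s*=\\s*[0-9]+", name), header, ignore.case = TRUE)
    )
    if (!length(m)) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  n_orb <- get_field("NORB")
  n_elec <- get_field("NELEC")
  if (is.na(n_orb) || is.na(n_elec)) {
    abort_format("FCIDUMP header must define NORB and NELEC")
  }
  if (n_elec %% 2L != 0L) {
    abort_unsupported("FCIDUMP with odd NELEC: closed-shell systems only")
  }

  h <- matrix(0, n_orb, n_orb)
  eri <- array(0, c(n_orb, n_orb, n_orb, n_orb))
  e_nuc <- 0
  body <- lines[-seq_len(hdr_end)]
  for (line in body) {
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) != 5L) {
      abort_format(sprintf("malformed FCIDUMP value line: '%s'", line))
    }
    val <- suppressWarnings(as.numeric(tok[1]))
    idx <- suppressWarnings(as.integer(tok[2:5]))
    if (is.na(val) || anyNA(idx)) {
      abort_format(sprintf("malformed FCIDUMP value line: '%s'", line))
    }
    if (any(idx < 0L) || any(idx > n_orb)) {
      abort_format(sprintf("orbital index out of range in line: '%s'", line))
    }
    i <- idx[1]; j <- idx[2]; k <- idx[3]; l <- idx[4]
    if (i == 0L && j == 0L && k == 0L && l == 0L) {
      e_nuc <- val
    } else if (k == 0L && l == 0L) {
      if (i == 0L || j == 0L) {
        abort_format(sprintf("invalid one-electron index in line: '%s'", line))
      }
      h[i, j] <- val
      h[j, i] <- val
    } else if (i > 0L && j > 0L && k > 0L && l > 0L) {
      perms <- list(
        c(i, j, k, l), c(j, i, k, l), c(i, j, l, k), c(j, i, l, k),
        c(k, l, i, j), c(l, k, i, j), c(k, l, j, i), c(l, k, j, i)
      )
      for (p in perms) eri[p[1], p[2], p[3], p[4]] <- val
    } else {
      abort_format(sprintf("invalid index pattern in line: '%s'", line))
    }
  }
  hamiltonian(h, eri, n_elec = n_elec, e_nuc = e_nuc,
              label = basename(path))
}

#' Write a Hamiltonian to an FCIDUMP file
#'
#' Emits the permutation-unique nonzero integrals with 17 significant
#' digits, so that a write/read round trip reproduces the Hamiltonian to
#' better than 1e-14.  The constant offset line is always written.
#'
#' @param H an [hamiltonian()].
#' @param path output file path.
#' @param zero_tol entries with absolute value at or below this are
#'   skipped (the `0 0 0 0` offset line is always kept).
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(H, path, zero_tol = 0) {
  n <- H$n_orb
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "&FCI NORB=%d,NELEC=%d,MS2=0,", n, H$n_elec
  ), con)
  writeLines(sprintf(" ORBSYM=%s", paste(rep("1", n), collapse = ",")), con)
  writeLines(" ISYM=1,", con)
  writeLines("&END", con)

  fmt <- function(val, i, j, k, l) {
    sprintf("%.17e %d %d %d %d", val, i, j, k, l)
  }
  out <- character(0)
  ## permutation-unique ERI loop: p >= q, r >= s, (pq) >= (rs)
  for (p in seq_len(n)) for (q in seq_len(p)) {
    pq <- p * (p - 1) / 2 + q
    for (r in seq_len(p)) for (s in seq_len(r)) {
      rs <- r * (r - 1) / 2 + s
      if (rs > pq) next
      v <- H$eri[p, q, r, s]
      if (abs(v) > zero_tol) out <- c(out, fmt(v, p, q, r, s))
    }
  }
  for (p in seq_len(n)) for (q in seq_len(p)) {
    v <- H$h_core[p, q]
    if (abs(v) > zero_tol) out <- c(out, fmt(v, p, q, 0L, 0L))
  }
  out <- c(out, fmt(H$e_nuc, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(path)
}
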