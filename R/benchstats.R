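#' Load a reference ionization-potential set
#'
#' JSON schema: `{"basis": "...", "provenance": "...", "entries":
#' {"label": ip_eV, ...}}`.  Unknown top-level fields are accepted with
#' a warning (forward compatibility); duplicate labels, non-positive or
#' non-finite IPs are schema errors.
#'
#' @param path JSON file path.
#' @return An object of class `mbpt_refset`: `entries` (named numeric,
#'   eV), `provenance`, `basis`.
#' @export
load_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  known <- c("basis", "provenance", "entries")
  extra <- setdiff(names(obj), known)
  if (length(extra)) {
    warning(sprintf("ignoring unknown reference fields: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  if (is.null(obj$entries) || !length(obj$entries)) {
    abort_schema("reference set must carry a non-empty 'entries' map",
                 field = "entries")
  }
  labels <- names(obj$entries)
  if (is.null(labels) || any(!nzchar(labels))) {
    abort_schema("every reference entry needs a label", field = "entries")
  }
  if (anyDuplicated(labels)) {
    abort_schema(sprintf("duplicate reference label '%s'",
                         labels[duplicated(labels)][1]), field = "entries")
  }
  ips <- vapply(obj$entries, function(v) {
    if (!is.numeric(v) || length(v) != 1L) {
      abort_schema("reference IPs must be scalar numbers", field = "entries")
    }
    as.numeric(v)
  }, numeric(1))
  if (any(!is.finite(ips)) || any(ips <= 0)) {
    abort_schema("reference IPs must be positive and finite", field = "entries")
  }
  structure(
    list(
      entries = ips,
      provenance = if (is.null(obj$provenance)) "" else obj$provenance,
      basis = if (is.null(obj$basis)) "" else obj$basis
    ),
    class = "mbpt_refset"
  )
}

#' Save a reference set (or computed result map) as JSON
#'
#' Round-trips with [load_reference()].
#'
#' @param ref an `mbpt_refset`, or a named numeric vector of IPs (eV).
#' @param path output path.
#' @param provenance,basis metadata used when `ref` is a bare vector.
#' @return `path`, invisibly.
#' @export
save_results <- function(ref, path, provenance = "", basis = "") {
  if (!inherits(ref, "mbpt_refset")) {
    ref <- structure(
      list(entries = ref, provenance = provenance, basis = basis),
      class = "mbpt_refset"
    )
  }
  jsonlite::write_json(
    list(
      basis = ref$basis,
      provenance = ref$provenance,
      entries = as.list(ref$entries)
    ),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' Mean absolute error of HOMO energies against a reference set
#'
#' `MAE = (1/N) sum_i |e_HOMO,i - e_HOMO,i^ref|` over the intersection
#' of labels, with `e_HOMO^ref = -IP^ref`.  Computed values are HOMO
#' energies in eV (i.e. minus the predicted IPs).
#'
#' @param computed named numeric vector of HOMO energies (eV).
#' @param reference an `mbpt_refset`.
#' @return MAE in eV, with attributes `n` (intersection size) and
#'   `missing` (labels present on only one side).
#' @export
mae <- function(computed, reference) {
  ref_homo <- -reference$entries
  shared <- intersect(names(computed), names(ref_homo))
  if (!length(shared)) {
    abort_input("no common labels between computed values and reference set")
  }
  miss <- union(setdiff(names(computed), shared), setdiff(names(ref_homo), shared))
  out <- mean(abs(computed[shared] - ref_homo[shared]))
  attr(out, "n") <- length(shared)
  attr(out, "missing") <- miss
  out
}

#' Box-and-whisker statistics with outlier detection
#'
#' Median and quartiles by linear interpolation between order statistics
#' (the common box-plot convention, recorded in the output for
#' auditability); whiskers extend to the most extreme data points within
#' 1.5 interquartile ranges of the box; everything beyond is an
#' outlier.
#'
#' @param errors numeric vector (eV), optionally named for outlier
#'   labelling.
#' @return An object of class `mbpt_errorstats`: `n`, `mae`, `median`,
#'   `q1`, `q3`, `whisker_lo`, `whisker_hi`, `outliers` (named numeric),
#'   `quartile_convention`.
#' @export
box_stats <- function(errors) {
  if (!length(errors)) {
    abort_input("cannot compute box statistics of an empty error list")
  }
  qs <- stats::quantile(errors, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- errors >= lo_fence & errors <= hi_fence
  out <- errors[!inside]
  if (is.null(names(out)) && length(out)) {
    names(out) <- rep("", length(out))
  }
  structure(
    list(
      n = length(errors),
      mae = mean(abs(errors)),
      median = qs[2], q1 = qs[1], q3 = qs[3],
      whisker_lo = if (any(inside)) min(errors[inside]) else qs[1],
      whisker_hi = if (any(inside)) max(errors[inside]) else qs[3],
      outliers = out,
      quartile_convention = "linear interpolation (type 7)"
    ),
    class = "mbpt_errorstats"
  )
}

#' @export
print.mbpt_errorstats <- function(x, ...) {
  cat(sprintf(
    "n = %d  MAE = %.4f eV  median = %.4f  box = [%.4f, %.4f]  whiskers = [%.4f, %.4f]  outliers = %d\n",
    x$n, x$mae, x$median, x$q1, x$q3, x$whisker_lo, x$whisker_hi,
    length(x$outliers)
  ))
  invisible(x)
}

#' Per-method benchmark comparison report
#'
#' Compares one or more result maps (label -> HOMO energy in eV) against
#' a reference set: per-method mean absolute error and box/whisker
#' statistics of the signed errors
#' `e_HOMO^method - e_HOMO^reference`.
#'
#' @param results named list of named numeric vectors (one per method).
#' @param reference an `mbpt_refset`.
#' @return A list with `table` (data frame, one row per method) and
#'   `stats` (list of `mbpt_errorstats`).
#' @export
compare_report <- function(results, reference) {
  ref_homo <- -reference$entries
  stats_list <- list()
  rows <- lapply(names(results), function(m) {
    comp <- results[[m]]
    shared <- intersect(names(comp), names(ref_homo))
    if (!length(shared)) {
      abort_input(sprintf("method '%s' shares no labels with the reference", m))
    }
    err <- comp[shared] - ref_homo[shared]
    st <- box_stats(err)
    stats_list[[m]] <<- st
    data.frame(
      method = m, n = st$n, mae_eV = st$mae, median_eV = st$median,
      q1_eV = st$q1, q3_eV = st$q3, n_outliers = length(st$outliers)
    )
  })
  list(table = do.call(rbind, rows), stats = stats_list)
}
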