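#' A current-voltage sweep
#'
#' @param voltages voltages in V, strictly increasing, length >= 2
#' @param currents currents in A, same length
#' @param label optional text label (e.g. membrane composition, time point)
#' @return object of class `iv_record`
#' @export
iv_record <- function(voltages, currents, label = "") {
  stopifnot(is.numeric(voltages), is.numeric(currents),
            length(voltages) == length(currents), length(voltages) >= 2)
  if (any(diff(voltages) <= 0)) stop("voltages must be strictly increasing")
  structure(list(voltages = voltages, currents = currents, label = label),
            class = "iv_record")
}

#' @export
print.iv_record <- function(x, ...) {
  cat(sprintf("I-V sweep '%s': %d points, V in [%.3g, %.3g] V\n",
              x$label, length(x$voltages), min(x$voltages), max(x$voltages)))
  invisible(x)
}

#' Fit a linear conductance model to an I-V sweep
#'
#' Ordinary least-squares line `I = G (V - V_m)`: the slope is the membrane
#' conductance G and the zero-current crossing the reversal potential V_m.
#' When the fitted conductance is (numerically) zero the reversal potential
#' is undefined and flagged; a V_m outside the swept range is flagged as
#' extrapolated.
#'
#' @param iv an [iv_record()]
#' @param area_cm2 optional membrane area in cm^2; when given, the specific
#'   conductance G/area (S/cm^2) is reported as well
#' @return object of class `iv_fit` with fields `G` (S), `V_m` (V),
#'   `specific_conductance` (S/cm^2 or NA), `r2`, `extrapolated`,
#'   `vm_defined`
#' @export
#' @examples
#' iv <- iv_record(seq(-0.06, 0.06, length.out = 7),
#'                 2e-9 * (seq(-0.06, 0.06, length.out = 7) - 0.015))
#' fit_iv(iv)
fit_iv <- function(iv, area_cm2 = NULL) {
  stopifnot(inherits(iv, "iv_record"))
  if (stats::sd(iv$voltages) == 0) stop("singular fit: all voltages equal")
  fit <- stats::lm(currents ~ voltages, data = iv[c("voltages", "currents")])
  G <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  vm_defined <- is.finite(G) && abs(G) > 0 &&
    abs(b / G) < 10 * diff(range(iv$voltages)) + max(abs(iv$voltages))
  V_m <- if (vm_defined) -b / G else NA_real_
  ss_tot <- sum((iv$currents - mean(iv$currents))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  structure(list(
    G = G,
    V_m = V_m,
    specific_conductance = if (!is.null(area_cm2)) G / area_cm2 else NA_real_,
    r2 = r2,
    vm_defined = vm_defined,
    extrapolated = vm_defined &&
      (V_m < min(iv$voltages) || V_m > max(iv$voltages)),
    n = length(iv$voltages),
    label = iv$label
  ), class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("I-V fit '%s' (n = %d):\n", x$label, x$n))
  cat(sprintf("  G   = %.4g S", x$G))
  if (is.finite(x$specific_conductance)) {
    cat(sprintf("  (%.4g S/cm^2)", x$specific_conductance))
  }
  cat("\n")
  if (x$vm_defined) {
    cat(sprintf("  V_m = %.4g V%s\n", x$V_m,
                if (x$extrapolated) "  [extrapolated]" else ""))
  } else {
    cat("  V_m undefined (zero conductance)\n")
  }
  cat(sprintf("  r^2 = %.4f\n", x$r2))
  invisible(x)
}

#' Read / write I-V sweeps as CSV
#'
#' Two-column CSV dialect `voltage_V, current_A` with a header row and '.'
#' decimal separator.
#'
#' @param path file path
#' @param label label attached to the record (defaults to the file name)
#' @return [read_iv_csv()] returns an [iv_record()]
#' @export
read_iv_csv <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("I-V file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("voltage_V", "current_A")
  if (!all(need %in% names(df))) {
    stop(sprintf("file '%s' must have columns %s (row 1 is the header)",
                 path, paste(need, collapse = ", ")))
  }
  bad <- which(!is.finite(df$voltage_V) | !is.finite(df$current_A))
  if (length(bad)) {
    stop(sprintf("file '%s': non-numeric value at data row %d", path, bad[1]))
  }
  o <- order(df$voltage_V)
  iv_record(df$voltage_V[o], df$current_A[o], label = label)
}

#' @param iv an [iv_record()] to write
#' @rdname read_iv_csv
#' @export
write_iv_csv <- function(iv, path) {
  stopifnot(inherits(iv, "iv_record"))
  utils::write.csv(
    data.frame(voltage_V = iv$voltages, current_A = iv$currents),
    path, row.names = FALSE)
  invisible(path)
}

#' JSON report for an I-V fit
#'
#' @param fit an `iv_fit`
#' @param path optional output path; when omitted the JSON string is returned
#' @return JSON string (invisibly when written to file)
#' @export
iv_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "iv_fit"))
  obj <- list(G_S = fit$G, Vm_V = fit$V_m,
              specific_conductance_S_per_cm2 = fit$specific_conductance,
              r2 = fit$r2)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
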