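#' Construct a gridded free-energy profile
#'
#' @param grid strictly increasing xi values (Angstrom).
#' @param values A(xi) in kcal/mol; `+Inf` marks uncovered (empty) bins and
#'   `NA` marks coverage gaps reported by an estimator.
#' @param reference label of the zero point (default `"reagent_minimum"`).
#' @param estimator `"wham"`, `"ui"`, or other label.
#' @param details optional estimator diagnostics.
#' @return An object of class `fe_profile`.
#' @export
fe_profile <- function(grid, values, reference = "reagent_minimum",
                       estimator = "unknown", details = NULL) {
  grid <- as.numeric(grid); values <- as.numeric(values)
  if (length(grid) != length(values)) stop("grid and values lengths differ")
  if (any(diff(grid) <= 0)) stop("profile grid must be strictly increasing")
  structure(list(grid = grid, values = values, reference = reference,
                 estimator = estimator, details = details),
            class = "fe_profile")
}

#' @export
print.fe_profile <- function(x, ...) {
  fin <- is.finite(x$values)
  cat(sprintf("Free-energy profile (%s), %d grid points on [%.3f, %.3f] A\n",
              x$estimator, length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  reference: %s; covered bins: %d; A range [%.3f, %.3f] kcal/mol\n",
              x$reference, sum(fin),
              min(x$values[fin]), max(x$values[fin])))
  invisible(x)
}

# shift profile values so the minimum over the reagent basin is zero
shift_to_reference <- function(values, grid, reference, basins) {
  fin <- is.finite(values)
  if (!any(fin)) stop("profile has no covered bins")
  if (identical(reference, "reagent_minimum") && !is.null(basins$reagent)) {
    sel <- fin & grid >= basins$reagent[1] & grid <= basins$reagent[2]
    if (!any(sel)) stop("no covered bins in the reagent basin")
    values - min(values[sel])
  } else {
    values - min(values[fin])
  }
}

#' Default basin hints for stationary-point extraction
#'
#' Reagent basin -2.5..-0.5 A and product basin 0.5..2.0 A, bracketing the
#' reagent and product minima of the reference reaction-coordinate range.
#'
#' @return List with `reagent` and `product` length-2 intervals (Angstrom).
#' @export
default_basins <- function() list(reagent = c(-2.5, -0.5), product = c(0.5, 2.0))
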