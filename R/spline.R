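#' Truncated power basis function
#'
#' Evaluates the truncated power term \eqn{(t - \kappa)_+^p}: zero at or below
#' the knot, \eqn{(t-\kappa)^p} above it. These terms join polynomial pieces
#' smoothly and are the building blocks of the spline design matrices used
#' throughout the package.
#'
#' @param t Numeric vector of ages (years).
#' @param kappa Knot location (years).
#' @param power Power of the term, 1 (linear), 2 (quadratic) or 3 (cubic).
#' @return Numeric vector, same length as `t`.
#' @examples
#' truncated_power(c(0.5, 2, 3), kappa = 1, power = 3)
#' @export
truncated_power <- function(t, kappa, power = 3) {
  stopifnot(power %in% c(1, 2, 3))
  pmax(t - kappa, 0)^power
}

#' Spline specification for a growth-curve design
#'
#' Describes one function of age: a plain polynomial (up to cubic), or a
#' linear/quadratic/cubic smoothing spline built from a polynomial plus
#' truncated power terms at the given knots.
#'
#' @param form One of `"intercept"`, `"linear"`, `"quadratic"`,
#'   `"cubic_slope"`, `"linear_spline"`, `"quadratic_spline"`,
#'   `"cubic_spline"`.
#' @param knots Ordered numeric vector of knot ages (years); must be empty
#'   for the pure polynomial forms.
#' @return An object of class `spline_spec`.
#' @examples
#' spline_spec("cubic_spline", knots = c(1, 8, 12))
#' spline_spec("cubic_slope")
#' @export
spline_spec <- function(form = c("cubic_spline", "cubic_slope", "linear_spline",
                                 "quadratic_spline", "quadratic", "linear",
                                 "intercept"),
                        knots = numeric()) {
  form <- match.arg(form)
  spline_forms <- c("linear_spline", "quadratic_spline", "cubic_spline")
  if (form %in% spline_forms) {
    if (length(knots) == 0) stop("spline form '", form, "' requires knots")
    if (is.unsorted(knots, strictly = TRUE)) {
      stop("knots must be strictly increasing")
    }
  } else if (length(knots) > 0) {
    stop("form '", form, "' takes no knots")
  }
  structure(list(form = form, knots = as.numeric(knots)),
            class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  k <- if (length(x$knots)) paste0("(", paste(x$knots, collapse = ", "), ")") else ""
  cat("<spline_spec> ", x$form, k, "\n", sep = "")
  invisible(x)
}

# polynomial degree and truncated-power power for each form
spline_degree <- function(spec) {
  switch(spec$form,
         intercept = 0L, linear = 1L, quadratic = 2L,
         cubic_slope = 3L, linear_spline = 1L,
         quadratic_spline = 2L, cubic_spline = 3L)
}

spline_tp_power <- function(spec) {
  switch(spec$form,
         linear_spline = 1L, quadratic_spline = 2L, cubic_spline = 3L, 0L)
}

# column names excluding the intercept; spline terms are named by their power
# (ls/qs/cs) and knot index so different bases can coexist in one data frame
spline_colnames <- function(spec) {
  deg <- spline_degree(spec)
  nm <- c("age", "age2", "age3")[seq_len(deg)]
  pw <- spline_tp_power(spec)
  if (pw > 0) {
    tag <- c("ls", "qs", "cs")[pw]
    nm <- c(nm, paste0(tag, seq_along(spec$knots)))
  }
  nm
}

#' Spline design matrix
#'
#' Builds the fixed- or random-effect design matrix for a vector of ages under
#' a given [spline_spec()]. Columns are, in order: the intercept, the
#' polynomial terms in age, then one truncated power term per knot.
#'
#' @param ages Numeric vector of ages in years (finite, non-negative).
#' @param spec A [spline_spec()].
#' @param intercept Include the leading column of ones (default `TRUE`).
#' @return Numeric matrix with named columns.
#' @examples
#' design_matrix(c(0, 2), spline_spec("cubic_spline", c(1, 8, 12)))
#' @export
design_matrix <- function(ages, spec, intercept = TRUE) {
  stopifnot(inherits(spec, "spline_spec"), all(is.finite(ages)))
  deg <- spline_degree(spec)
  cols <- lapply(seq_len(deg), function(j) ages^j)
  pw <- spline_tp_power(spec)
  if (pw > 0) {
    cols <- c(cols, lapply(spec$knots, function(k) truncated_power(ages, k, pw)))
  }
  X <- do.call(cbind, c(list(rep(1, length(ages))), cols))
  colnames(X) <- c("(Intercept)", spline_colnames(spec))
  if (!intercept) X <- X[, -1, drop = FALSE]
  X
}

# Antiderivative of the basis evaluated at t: F(t) such that F'(t) = basis(t).
# Monomial t^j integrates to t^(j+1)/(j+1); (t-k)_+^p to (t-k)_+^(p+1)/(p+1),
# which is exact across the knot because the term vanishes below it.
design_antiderivative <- function(t, spec) {
  deg <- spline_degree(spec)
  cols <- list(t)
  cols <- c(cols, lapply(seq_len(deg), function(j) t^(j + 1) / (j + 1)))
  pw <- spline_tp_power(spec)
  if (pw > 0) {
    cols <- c(cols, lapply(spec$knots, function(k) {
      pmax(t - k, 0)^(pw + 1L) / (pw + 1L)
    }))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- c("(Intercept)", spline_colnames(spec))
  X
}

#' Exact integral of a spline curve over a window
#'
#' Closed-form \eqn{\int_a^b x(t)'\theta \, dt} for a curve expressed in a
#' truncated power basis, using the antiderivatives of the monomial and
#' truncated power terms. Used to compute the window AUC phenotypes.
#'
#' @param spec A [spline_spec()].
#' @param coef Coefficient vector (intercept first), length `ncol` of the
#'   design matrix.
#' @param a,b Window bounds in years, `a < b`.
#' @return The integral (a scalar).
#' @examples
#' sp <- spline_spec("cubic_slope")
#' integrate_spline(sp, c(0, 1, 0, 0), 0, 1) # int_0^1 t dt = 0.5
#' @export
integrate_spline <- function(spec, coef, a, b) {
  stopifnot(a < b, length(coef) == length(spline_colnames(spec)) + 1L)
  Fab <- design_antiderivative(c(a, b), spec)
  drop((Fab[2, ] - Fab[1, ]) %*% coef)
}

#' CAR(1) correlation matrix
#'
#' Continuous first-order autoregressive correlation between within-subject
#' measurements: entry \eqn{(s,t)} is \eqn{\phi^{|age_s - age_t|}}, so
#' correlation decays with the time separation between visits.
#'
#' @param ages Numeric vector of measurement ages (years).
#' @param phi Correlation parameter in `[0, 1)`.
#' @return Correlation matrix of dimension `length(ages)`.
#' @examples
#' car1_matrix(c(1, 2, 3), 0.5)
#' @export
car1_matrix <- function(ages, phi) {
  if (!is.numeric(phi) || length(phi) != 1 || phi < 0 || phi >= 1) {
    stop("phi must be a single value in [0, 1)")
  }
  d <- abs(outer(ages, ages, "-"))
  if (phi == 0) {
    m <- diag(length(ages))
  } else {
    m <- phi^d
  }
  m
}
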