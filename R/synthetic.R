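# Benchmark relationship generator.
#
# Two families of 12 trivariate functional relationships of a uniform
# driver r ~ U(0, 1):
#   * "fig6":   X = r, Y = f(r), Z = f(r) (the circle is the exception,
#               with Y = cos 2*pi*r, Z = sin 2*pi*r) -- the noiseless
#               generality benchmark.
#   * "table1": X = f_x(r), Y = f_y(r), Z = f_z(r) with per-axis atoms --
#               the noisy equitability benchmark.
# The published benchmark names the functions but not their formulas; the
# concrete forms below follow the conventions of the MIC equitability
# literature and are frozen here so that scores are stable.

atom_funs <- list(
  linear      = function(r) r,
  exponential = function(r) 2^(10 * r),
  logarithm   = function(r) log2(r + 0.01),
  quadratic   = function(r) 4 * (r - 0.5)^2,
  parabola    = function(r) 4 * (r - 0.5)^2,
  cubic       = function(r) (2 * r - 1)^3,
  sin_low     = function(r) sin(4 * pi * r),
  sine        = function(r) sin(4 * pi * r),
  cosine      = function(r) cos(4 * pi * r),
  sin_high    = function(r) sin(16 * pi * r),
  step        = function(r) floor(4 * r),
  polynomial  = function(r) r^3 - r,
  power       = function(r) r^4,
  # monotone piecewise line, breakpoint at r = 0.5, slopes 0.5 and 1.5
  piecewise   = function(r) ifelse(r < 0.5, 0.5 * r, 0.25 + 1.5 * (r - 0.5)),
  lin_x_cos   = function(r) r * cos(4 * pi * r),
  lin_x_sin   = function(r) r * sin(4 * pi * r),
  sin_p_lin   = function(r) sin(4 * pi * r) + r,
  cos_p_lin   = function(r) cos(4 * pi * r) + r,
  exp_p_par   = function(r) 2^(10 * r) + 4 * (r - 0.5)^2
)

# fig6 rows in the benchmark table's order.  `coin` marks relationships
# whose branch is chosen per point by an independent fair coin (the same
# draw feeds Y and Z, which remain equal).
fig6_defs <- list(
  list(id = 1,  name = "linear",       f = "linear"),
  list(id = 2,  name = "exponential",  f = "exponential"),
  list(id = 3,  name = "logarithmic",  f = "logarithm"),
  list(id = 4,  name = "quadratic",    f = "quadratic"),
  list(id = 5,  name = "cubic",        f = "cubic"),
  list(id = 6,  name = "sin_low",      f = "sin_low"),
  list(id = 7,  name = "sin_high",     f = "sin_high"),
  list(id = 8,  name = "circle",       f = NA),
  list(id = 9,  name = "step",         f = "step"),
  list(id = 10, name = "two_lines",    f = NA),
  list(id = 11, name = "x_line",       f = NA),
  list(id = 12, name = "x_curve",      f = NA)
)

table1_defs <- list(
  list(id = 1,  name = "lin_lin_lin",  fx = "linear",     fy = "linear",    fz = "linear"),
  list(id = 2,  name = "lin_lincos_linsin", fx = "linear", fy = "lin_x_cos", fz = "lin_x_sin"),
  list(id = 3,  name = "lin_poly_sinlin",   fx = "linear", fy = "polynomial", fz = "sin_p_lin"),
  list(id = 4,  name = "lin_piece_lin",     fx = "linear", fy = "piecewise",  fz = "linear"),
  list(id = 5,  name = "lin_cos_par",       fx = "linear", fy = "cosine",     fz = "parabola"),
  list(id = 6,  name = "lin_exp_lin",       fx = "linear", fy = "exponential", fz = "linear"),
  list(id = 7,  name = "lin_sin_log",       fx = "linear", fy = "sine",       fz = "logarithm"),
  list(id = 8,  name = "lin_exppar_coslin", fx = "linear", fy = "exp_p_par",  fz = "cos_p_lin"),
  list(id = 9,  name = "lin_sin_cos",       fx = "linear", fy = "sine",       fz = "cosine"),
  list(id = 10, name = "poly_cos_sinlin",   fx = "polynomial", fy = "cosine", fz = "sin_p_lin"),
  list(id = 11, name = "lin_poly_poly",     fx = "linear", fy = "polynomial", fz = "polynomial"),
  list(id = 12, name = "lin_pow_lin",       fx = "linear", fy = "power",      fz = "linear")
)

#' Catalog of benchmark relationships
#'
#' @param family `"fig6"` (noiseless generality set: `X = r`,
#'   `Y = Z = f(r)`) or `"table1"` (noisy equitability set:
#'   `X = f_x(r)`, `Y = f_y(r)`, `Z = f_z(r)`).
#' @return Data frame with columns `id`, `family`, `name` for the 12
#'   relationships of the family, in the published row order.
#' @export
relationship_catalog <- function(family = c("fig6", "table1")) {
  family <- match.arg(family)
  defs <- if (family == "fig6") fig6_defs else table1_defs
  data.frame(id = vapply(defs, `[[`, numeric(1), "id"),
             family = family,
             name = vapply(defs, `[[`, character(1), "name"),
             stringsAsFactors = FALSE)
}

#' Noise scale for a target coefficient of determination
#'
#' Returns the standard deviation `sigma` of additive Gaussian noise such
#' that the population R-squared of `f(r) + eps` regressed on `f(r)` equals
#' `r2`:  `sigma = sd(f) * sqrt((1 - r2) / r2)`.
#'
#' @param f_values Clean signal values (nonconstant when `r2 < 1`).
#' @param r2 Target coefficient of determination, in `(0, 1]`.
#' @return Noise standard deviation (0 when `r2 = 1`).
#' @export
sigma_for_r2 <- function(f_values, r2) {
  if (!is.numeric(r2) || length(r2) != 1L || r2 <= 0 || r2 > 1)
    stop("r2 must be in (0, 1]", call. = FALSE)
  if (r2 == 1) return(0)
  s <- stats::sd(f_values)
  if (!is.finite(s) || s == 0)
    stop("constant signal cannot be calibrated to r2 < 1", call. = FALSE)
  s * sqrt((1 - r2) / r2)
}

# Evaluate the three clean coordinates of one relationship.
# branch: per-point U(0,1) draw used by the coin-flip relationships.
relationship_coords <- function(id, family, r, branch) {
  if (family == "fig6") {
    def <- fig6_defs[[id]]
    switch(def$name,
      circle = list(x = r, y = cos(2 * pi * r), z = sin(2 * pi * r),
                    clean = c(TRUE, FALSE, FALSE)),
      two_lines = {
        f <- ifelse(branch < 0.5, r, 0.5 * r)
        list(x = r, y = f, z = f, clean = c(TRUE, FALSE, FALSE))
      },
      x_line = {
        f <- ifelse(branch < 0.5, r, 1 - r)
        list(x = r, y = f, z = f, clean = c(TRUE, FALSE, FALSE))
      },
      x_curve = {
        f <- ifelse(branch < 0.5, 1, -1) * (2 * r - 1)^2
        list(x = r, y = f, z = f, clean = c(TRUE, FALSE, FALSE))
      },
      {
        f <- atom_funs[[def$f]](r)
        list(x = r, y = f, z = f, clean = c(TRUE, FALSE, FALSE))
      })
  } else {
    def <- table1_defs[[id]]
    list(x = atom_funs[[def$fx]](r),
         y = atom_funs[[def$fy]](r),
         z = atom_funs[[def$fz]](r),
         clean = c(def$fx == "linear", FALSE, FALSE))
  }
}

#' Generate a benchmark trivariate sample
#'
#' Draws `n` i.i.d. driver values `r ~ U(0, 1)`, evaluates the chosen
#' relationship, and adds independent Gaussian noise calibrated by
#' [sigma_for_r2()] to every non-identity coordinate (a coordinate equal to
#' `r` itself stays clean).  Fully reproducible from `seed`; the global RNG
#' state is restored on exit.
#'
#' @param id Relationship id, 1 to 12.
#' @param family `"fig6"` or `"table1"`.
#' @param n Sample size.
#' @param r2 Target coefficient of determination in `(0, 1]`; 1 means
#'   noiseless.
#' @param seed Integer seed.
#' @return A [tri_sample()] with attribute `spec` recording the settings.
#' @examples
#' d <- generate_relationship(1, "fig6", n = 100, r2 = 1, seed = 7)
#' qotic(d$x, d$y, d$z)
#' @export
generate_relationship <- function(id, family = c("fig6", "table1"), n,
                                  r2 = 1, seed = 1L) {
  family <- match.arg(family)
  id <- as.integer(id)
  if (id < 1L || id > 12L) stop("id must be in 1..12", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  r <- stats::runif(n)
  branch <- stats::runif(n)
  co <- relationship_coords(id, family, r, branch)
  vals <- list(x = co$x, y = co$y, z = co$z)
  for (a in 1:3) {
    if (co$clean[a] || r2 == 1) next
    sigma <- sigma_for_r2(vals[[a]], r2)
    vals[[a]] <- vals[[a]] + stats::rnorm(n, 0, sigma)
  }
  s <- tri_sample(vals$x, vals$y, vals$z)
  attr(s, "spec") <- list(id = id, family = family, n = n, r2 = r2,
                          seed = seed)
  s
}
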