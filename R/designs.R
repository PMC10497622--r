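#' Substrate-concentration grids (in units of Km)
#'
#' Three standard sampling grids used throughout the bias simulations, all
#' expressed relative to `Km = 1`: the default grid spanning the Michaelis
#' constant (0.35-2.45), a grid entirely below Km (0.07-0.35) and one
#' entirely above it (1.4-8.4). `scale` maps them to physical
#' concentrations (multiplies every element).
#'
#' @param scale Multiplicative factor applied to the grid (default 1).
#' @return Numeric vector of initial substrate concentrations, ascending.
#' @export
default_s0_grid <- function(scale = 1) scale * seq(0.35, 2.45, by = 0.35)

#' @rdname default_s0_grid
#' @export
below_km_grid <- function(scale = 1) scale * seq(0.07, 0.35, by = 0.07)

#' @rdname default_s0_grid
#' @export
above_km_grid <- function(scale = 1) scale * seq(1.4, 8.4, by = 1.4)

#' Single-time-point sampling plan
#'
#' Describes one of the two sampling strategies:
#' \describe{
#'   \item{constant_conversion}{every `s0` is sampled at the time reaching
#'     the same conversion fraction `target_fraction`;}
#'   \item{constant_time}{all `s0` share one reaction time, chosen so that
#'     the lowest `s0` reaches `target_fraction` — conversion then
#'     decreases with increasing `s0`.}
#' }
#'
#' @param strategy `"constant_conversion"` or `"constant_time"`.
#' @param s0_grid Strictly positive, strictly ascending concentrations.
#' @param target_fraction Conversion fraction in (0, 1) applied at every
#'   `s0` (constant_conversion) or at the lowest `s0` only (constant_time).
#' @param params [kinetic_parameters()] used for simulation (optional if
#'   the spec is only used to describe a plan, required by
#'   [simulate_design()]).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(strategy = c("constant_time", "constant_conversion"),
                        s0_grid = default_s0_grid(),
                        target_fraction = 0.5,
                        params = NULL) {
  strategy <- match.arg(strategy)
  if (length(s0_grid) < 1L || any(!is.finite(s0_grid) | s0_grid <= 0))
    stop("s0_grid must be non-empty and strictly positive", call. = FALSE)
  if (is.unsorted(s0_grid, strictly = TRUE))
    stop("s0_grid must be strictly ascending", call. = FALSE)
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      target_fraction <= 0 || target_fraction >= 1)
    stop("target_fraction must be in (0, 1)", call. = FALSE)
  if (!is.null(params)) stopifnot(inherits(params, "kinetic_parameters"))
  structure(list(strategy = strategy, s0_grid = as.numeric(s0_grid),
                 target_fraction = target_fraction, params = params),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("Sampling plan: %s, f = %g, %d substrate concentrations (%g-%g)\n",
              x$strategy, x$target_fraction, length(x$s0_grid),
              min(x$s0_grid), max(x$s0_grid)))
  invisible(x)
}

#' Simulate the noiseless dataset implied by a sampling plan
#'
#' Generates one exact measurement per substrate concentration from the
#' integrated rate equation. Under `constant_conversion`, `p = f * s0` and
#' `t` follows from [time_to_product()]. Under `constant_time`, the shared
#' time `t_star` is the time to reach `f` at the lowest `s0`; products at
#' the other concentrations come from [product_at_time()].
#'
#' @param spec A [design_spec()] with non-NULL `params`.
#' @return An object of class `mm_dataset`: list with `design`,
#'   `measurements` (an `mm_measurements` table) and `t_star` (the shared
#'   time, `NA` for constant-conversion plans).
#' @examples
#' kp <- kinetic_parameters(1, 1)
#' d <- simulate_design(design_spec("constant_time", target_fraction = 0.5,
#'                                  params = kp))
#' round(d$t_star, 4) # 0.8681
#' @export
simulate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  if (is.null(spec$params))
    stop("design_spec has no kinetic parameters to simulate from",
         call. = FALSE)
  g <- spec$s0_grid
  f <- spec$target_fraction
  if (spec$strategy == "constant_conversion") {
    p <- f * g
    t <- time_to_product(spec$params, g, p)
    t_star <- NA_real_
  } else {
    t_star <- time_to_product(spec$params, g[1], f * g[1])
    p <- product_at_time(spec$params, g, t_star)
    t <- rep(t_star, length(g))
  }
  structure(list(design = spec,
                 measurements = measurements(s0 = g, t = t, p = p),
                 t_star = t_star),
            class = "mm_dataset")
}

#' @export
print.mm_dataset <- function(x, ...) {
  print(x$design)
  if (!is.na(x$t_star)) cat(sprintf("Shared time t* = %g\n", x$t_star))
  print.data.frame(cbind(x$measurements[c("s0", "t", "p")],
                         conversion = conversion(x$measurements)),
                   row.names = FALSE, digits = 4)
  invisible(x)
}
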