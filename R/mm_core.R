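#' Kinetic parameter set for an irreversible single-substrate enzyme
#'
#' Bundles the limiting rate `V` and the Michaelis constant `Km`, together
#' with the derived specificity constant `V/Km` and, when the total enzyme
#' concentration `E0` is supplied, the turnover number `kcat = V/E0`.
#' Units are carried as labels only; no conversion is performed.
#'
#' @param V Limiting (maximum) rate, concentration/time. Must be > 0.
#' @param Km Michaelis constant, concentration. Must be > 0.
#' @param E0 Optional total enzyme concentration; enables `kcat`.
#' @param conc_unit,time_unit Unit labels (metadata only).
#' @return An object of class `kinetic_parameters`: a list with elements
#'   `V`, `Km`, `specificity` (= V/Km), and optionally `E0`, `kcat`.
#' @examples
#' kp <- kinetic_parameters(V = 1, Km = 1)
#' initial_rate(kp, s0 = 1) # V/2 at s0 = Km
#' @export
kinetic_parameters <- function(V, Km, E0 = NULL,
                               conc_unit = "arb", time_unit = "arb") {
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V) || V <= 0)
    stop("invalid parameters: V must be a single positive finite number",
         call. = FALSE)
  if (!is.numeric(Km) || length(Km) != 1L || !is.finite(Km) || Km <= 0)
    stop("invalid parameters: Km must be a single positive finite number",
         call. = FALSE)
  out <- list(V = V, Km = Km, specificity = V / Km,
              conc_unit = conc_unit, time_unit = time_unit)
  if (!is.null(E0)) {
    if (!is.numeric(E0) || length(E0) != 1L || !is.finite(E0) || E0 <= 0)
      stop("invalid parameters: E0 must be a single positive finite number",
           call. = FALSE)
    out$E0 <- E0
    out$kcat <- V / E0
  }
  structure(out, class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (irreversible single-substrate HMM model)\n")
  cat(sprintf("  V  = %g %s/%s\n", x$V, x$conc_unit, x$time_unit))
  cat(sprintf("  Km = %g %s\n", x$Km, x$conc_unit))
  cat(sprintf("  V/Km = %g 1/%s\n", x$specificity, x$time_unit))
  if (!is.null(x$kcat))
    cat(sprintf("  E0 = %g %s, kcat = %g 1/%s\n",
                x$E0, x$conc_unit, x$kcat, x$time_unit))
  invisible(x)
}

#' Validated table of single-time-point measurements
#'
#' One row per observation of product concentration `p` at time `t` in a
#' reaction started at substrate concentration `s0`. Enforces `s0 > 0`,
#' `0 <= p < s0`, `t >= 0`, and `p == 0` whenever `t == 0`.
#'
#' @param s0 Initial substrate concentrations (one per row).
#' @param t Elapsed times.
#' @param p Product concentrations at time `t`.
#' @param replicate Optional integer replicate labels.
#' @param label Optional character labels.
#' @return A `data.frame` of class `mm_measurements` with columns
#'   `s0`, `t`, `p`, `replicate`, `label`.
#' @export
measurements <- function(s0, t, p, replicate = NA_integer_,
                         label = NA_character_) {
  n <- max(length(s0), length(t), length(p))
  m <- data.frame(s0 = rep_len(as.numeric(s0), n),
                  t = rep_len(as.numeric(t), n),
                  p = rep_len(as.numeric(p), n),
                  replicate = rep_len(as.integer(replicate), n),
                  label = rep_len(as.character(label), n),
                  stringsAsFactors = FALSE)
  validate_measurements(m)
}

validate_measurements <- function(m) {
  bad <- function(cond, msg) if (any(cond)) {
    stop(sprintf("invalid measurement (row %d): %s", which(cond)[1], msg),
         call. = FALSE)
  }
  bad(!is.finite(m$s0) | m$s0 <= 0, "s0 must be positive")
  bad(!is.finite(m$t) | m$t < 0, "t must be >= 0")
  bad(!is.finite(m$p) | m$p < 0, "p must be >= 0")
  bad(m$p >= m$s0, "p must be < s0 (reaction cannot exceed completion)")
  bad(m$t == 0 & m$p > 0, "p must be 0 at t = 0")
  class(m) <- c("mm_measurements", "data.frame")
  m
}

#' Initial rate from the Henri-Michaelis-Menten equation
#'
#' Computes `v = V * s0 / (Km + s0)`, the hyperbolic dependence of the
#' initial (steady-state) rate on the initial substrate concentration.
#'
#' @param params A [kinetic_parameters()] object.
#' @param s0 Initial substrate concentration(s), >= 0. Vectorized.
#' @return Rate(s); 0 at `s0 = 0`, bounded above by `V`.
#' @export
initial_rate <- function(params, s0) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(!is.finite(s0) | s0 < 0))
    stop("s0 must be finite and >= 0", call. = FALSE)
  params$V * s0 / (params$Km + s0)
}

#' Time to reach a given product concentration (integrated rate equation)
#'
#' The implicit integrated form of the HMM equation for an irreversible,
#' uninhibited single-substrate reaction:
#' `t = p/V + (Km/V) * log(s0 / (s0 - p))`.
#'
#' @param params A [kinetic_parameters()] object.
#' @param s0 Initial substrate concentration(s).
#' @param p Product concentration(s), `0 <= p < s0`.
#' @return Time(s); 0 at `p = 0`, strictly increasing in `p`.
#' @export
time_to_product <- function(params, s0, p) {
  stopifnot(inherits(params, "kinetic_parameters"))
  n <- max(length(s0), length(p))
  s0 <- rep_len(s0, n); p <- rep_len(p, n)
  if (any(!is.finite(s0) | s0 <= 0))
    stop("s0 must be finite and > 0", call. = FALSE)
  if (any(p < 0))
    stop("p must be >= 0", call. = FALSE)
  if (any(p >= s0))
    stop("p must be < s0 (reaction cannot exceed completion)", call. = FALSE)
  p / params$V + (params$Km / params$V) * log(s0 / (s0 - p))
}

# W(exp(y)) on the principal branch, stable for large y where exp(y)
# overflows. Solves w + log(w) = y by Newton from the asymptotic start.
lambert_w_exp <- function(y) {
  out <- numeric(length(y))
  small <- y < 700
  if (any(small)) out[small] <- pracma::lambertWp(exp(y[small]))
  if (any(!small)) {
    yy <- y[!small]
    w <- yy - log(yy)
    for (i in 1:50) {
      dw <- (yy - w - log(w)) * w / (w + 1)
      w <- w + dw
      if (all(abs(dw) <= 1e-14 * abs(w))) break
    }
    out[!small] <- w
  }
  out
}

#' Product concentration at a given time
#'
#' Inverts the integrated rate equation. The default uses the closed-form
#' Lambert-W substrate-depletion solution
#' `s(t) = Km * W((s0/Km) * exp((s0 - V t)/Km))`, `p = s0 - s(t)`;
#' `method = "bisect"` brackets the implicit equation with [stats::uniroot()]
#' and serves as an independent numerical oracle.
#'
#' @param params A [kinetic_parameters()] object.
#' @param s0 Initial substrate concentration(s).
#' @param t Time(s), >= 0. Vectorized (recycled against `s0`).
#' @param method `"lambertw"` (closed form, default) or `"bisect"`.
#' @return Product concentration(s) in `[0, s0)`; 0 at `t = 0`.
#' @export
product_at_time <- function(params, s0, t, method = c("lambertw", "bisect")) {
  stopifnot(inherits(params, "kinetic_parameters"))
  method <- match.arg(method)
  n <- max(length(s0), length(t))
  s0 <- rep_len(s0, n); t <- rep_len(t, n)
  if (any(!is.finite(s0) | s0 <= 0))
    stop("s0 must be finite and > 0", call. = FALSE)
  if (any(!is.finite(t) | t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  V <- params$V; Km <- params$Km
  p <- if (method == "lambertw") {
    y <- log(s0 / Km) + (s0 - V * t) / Km
    s0 - Km * lambert_w_exp(y)
  } else {
    vapply(seq_len(n), function(i) {
      if (t[i] == 0) return(0)
      f <- function(pp) time_to_product(params, s0[i], pp) - t[i]
      stats::uniroot(f, c(0, s0[i] * (1 - 1e-15)), tol = 1e-14)$root
    }, numeric(1))
  }
  p[t == 0] <- 0
  pmin(pmax(p, 0), s0 * (1 - .Machine$double.eps))
}

#' Fraction of substrate converted
#'
#' `f = p / s0`, the dimensionless conversion fraction of a measurement.
#'
#' @param m An `mm_measurements` table (or any data.frame with `s0`, `p`),
#'   or a numeric vector of product concentrations.
#' @param s0 Initial substrate concentration(s); required when `m` is numeric.
#' @return Conversion fraction(s) in `[0, 1)`.
#' @export
conversion <- function(m, s0 = NULL) {
  if (is.data.frame(m)) return(m$p / m$s0)
  if (is.null(s0)) stop("s0 required when m is a numeric vector", call. = FALSE)
  if (any(m < 0 | m >= s0)) stop("need 0 <= p < s0", call. = FALSE)
  m / s0
}
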