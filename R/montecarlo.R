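#' Experimental-error model
#'
#' Two bounded error models for product readings (or, as a control, for
#' true initial rates):
#' \describe{
#'   \item{relative_uniform}{each reading `x` becomes `x * (1 + u)` with
#'     `u ~ Uniform(-magnitude, +magnitude)` — "errors of up to" a
#'     percentage, which implies a hard bound and excludes a Gaussian;}
#'   \item{absolute_uniform_of_lowest}{each reading gets an additive
#'     `Uniform(-a, +a)` error with `a = magnitude` times the noiseless
#'     reading at the lowest substrate concentration;}
#'   \item{none}{identity (noiseless control).}
#' }
#'
#' @param kind Error kind (see above).
#' @param magnitude Maximum fractional error (e.g. 0.05, 0.10) or, for the
#'   absolute model, the fraction of the lowest-`s0` reading (e.g. 0.20).
#' @param target `"product"` perturbs product readings of a simulated
#'   dataset; `"rate"` perturbs true initial rates (the "real v" control).
#' @return An object of class `error_model`.
#' @export
error_model <- function(kind = c("relative_uniform",
                                 "absolute_uniform_of_lowest", "none"),
                        magnitude = 0, target = c("product", "rate")) {
  kind <- match.arg(kind)
  target <- match.arg(target)
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude < 0)
    stop("magnitude must be a single non-negative number", call. = FALSE)
  structure(list(kind = kind, magnitude = magnitude, target = target),
            class = "error_model")
}

#' Apply an error model to a simulated dataset or to rates
#'
#' Draws one independent error per reading. Perturbed product readings are
#' clipped to the open interval `(0, s0)` (clipping events are counted in
#' the `n_clipped` attribute); perturbed rates are clipped to be positive.
#' With a seed, the perturbation is exactly reproducible.
#'
#' @param x An `mm_dataset` (from [simulate_design()]), an
#'   `mm_measurements` table, or an `mm_rates` data.frame (for
#'   `target = "rate"` models).
#' @param model An [error_model()].
#' @param seed Optional integer seed for reproducibility.
#' @return A perturbed copy of `x` with attribute `n_clipped`.
#' @export
perturb <- function(x, model, seed = NULL) {
  stopifnot(inherits(model, "error_model"))
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "mm_dataset")) {
    x$measurements <- perturb(as.data.frame(x$measurements), model)
    attr(x, "n_clipped") <- attr(x$measurements, "n_clipped")
    return(x)
  }
  if (inherits(x, "mm_rates") || (is.data.frame(x) && "v_hat" %in% names(x))) {
    x$v_hat <- pmax(perturb_values(x$v_hat, model), .Machine$double.xmin)
    return(x)
  }
  if (is.data.frame(x) && all(c("s0", "t", "p") %in% names(x))) {
    eps <- 1e-12
    p <- perturb_values(x$p, model)
    clipped <- pmin(pmax(p, eps * x$s0), x$s0 * (1 - eps))
    x$p <- clipped
    out <- validate_measurements(as.data.frame(x))
    attr(out, "n_clipped") <- sum(clipped != p)
    return(out)
  }
  stop("don't know how to perturb this object", call. = FALSE)
}

perturb_values <- function(v, model) {
  n <- length(v)
  switch(model$kind,
         none = v,
         relative_uniform =
           v * (1 + stats::runif(n, -model$magnitude, model$magnitude)),
         absolute_uniform_of_lowest = {
           a <- model$magnitude * v[1] # readings ordered by ascending s0
           v + stats::runif(n, -a, a)
         })
}

#' Replicated error-propagation study
#'
#' For each condition (conversion fraction x error model), simulates the
#' noiseless sampling plan, applies the error model independently
#' `n_runs` times, estimates the parameters with each requested estimator,
#' and summarizes the replicate distribution: ranges, largest per-run
#' standard error (as percent of the estimate) and mean +/- sample SD.
#'
#' The `real_v` control condition replaces the single-time-point data by
#' true initial rates (for the rate-based estimators) or by measurements
#' at a very short time, `t = 0.001 * Km/V` (for the integrated
#' estimator), perturbed with the same error model.
#'
#' @param fractions Target conversion fractions (constant-time plans).
#' @param models List of [error_model()] objects (target `"product"`).
#' @param estimators Subset of `c("hanes_woolf", "hyperbolic", "integrated")`.
#' @param n_runs Replicates per condition (default 18).
#' @param seed Root seed for the whole study.
#' @param grid,params,strategy Sampling plan (see [design_spec()]).
#' @param include_real_v Add the true-initial-rate control condition.
#' @return A data.frame of class `mm_mc_study`, one row per condition x
#'   estimator: `f`, `error_kind`, `magnitude`, `estimator`, `n_runs`,
#'   `n_failed`, `min_V`, `max_V`, `min_Km`, `max_Km`, `min_ratio`,
#'   `max_ratio`, `largest_se_pct_V`, `largest_se_pct_Km`, `mean_V`,
#'   `sd_V`, `mean_Km`, `sd_Km`. The root seed is kept in the `seed`
#'   attribute.
#' @export
run_study <- function(fractions = c(0.1, 0.3, 0.6),
                      models = list(error_model("relative_uniform", 0.05)),
                      estimators = c("hanes_woolf", "integrated"),
                      n_runs = 18,
                      seed = 1,
                      grid = default_s0_grid(),
                      params = kinetic_parameters(1, 1),
                      strategy = "constant_time",
                      include_real_v = TRUE) {
  estimators <- match.arg(estimators,
                          c("hanes_woolf", "hyperbolic", "integrated"),
                          several.ok = TRUE)
  set.seed(seed)
  conds <- list()
  for (model in models) {
    if (include_real_v)
      conds[[length(conds) + 1L]] <- list(f = NA_real_, model = model)
    for (f in fractions)
      conds[[length(conds) + 1L]] <- list(f = f, model = model)
  }
  rows <- list()
  for (cond in conds) {
    is_real_v <- is.na(cond$f)
    if (is_real_v) {
      rates0 <- structure(
        data.frame(s0 = grid, v_hat = initial_rate(params, grid),
                   method = "true", stringsAsFactors = FALSE),
        class = c("mm_rates", "data.frame"))
      t_short <- 0.001 * params$Km / params$V
      ds0 <- list(measurements = measurements(
        s0 = grid, t = t_short, p = product_at_time(params, grid, t_short)))
    } else {
      ds0 <- simulate_design(design_spec(strategy, grid, cond$f, params))
    }
    rate_model <- error_model(cond$model$kind, cond$model$magnitude, "rate")
    fits <- replicate(n_runs, {
      res <- list()
      if (is_real_v) {
        r <- perturb(rates0, rate_model)
        mpert <- perturb(as.data.frame(ds0$measurements), cond$model)
      } else {
        dpert <- perturb(ds0, cond$model)
        r <- chord_rate(dpert$measurements)
        mpert <- dpert$measurements
      }
      for (est in estimators) {
        res[[est]] <- tryCatch(switch(est,
          hanes_woolf = fit_hanes_woolf(r),
          hyperbolic = fit_hyperbolic(r),
          integrated = fit_integrated(mpert)),
          error = function(e) NULL)
      }
      res
    }, simplify = FALSE)
    for (est in estimators) {
      per <- Filter(Negate(is.null), lapply(fits, `[[`, est))
      n_failed <- n_runs - length(per)
      get <- function(fld) vapply(per, `[[`, numeric(1), fld)
      V <- get("V"); Km <- get("Km"); ratio <- get("ratio")
      rows[[length(rows) + 1L]] <- data.frame(
        f = cond$f, error_kind = cond$model$kind,
        magnitude = cond$model$magnitude, estimator = est,
        n_runs = n_runs, n_failed = n_failed,
        min_V = min(V), max_V = max(V),
        min_Km = min(Km), max_Km = max(Km),
        min_ratio = min(ratio), max_ratio = max(ratio),
        largest_se_pct_V = 100 * max(get("se_V") / V),
        largest_se_pct_Km = 100 * max(get("se_Km") / Km),
        mean_V = mean(V), sd_V = stats::sd(V),
        mean_Km = mean(Km), sd_Km = stats::sd(Km),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("mm_mc_study", "data.frame")
  out
}
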