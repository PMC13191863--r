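#' Resolve a parameter distribution specification into a sampler
#'
#' Turns a `(kind, baseline, low, up)` specification into concrete family
#' parameters such that the family mean equals the baseline and the central
#' 95% interval matches `[low, up]` as closely as possible (least-squares on
#' the 2.5%/97.5% quantiles, with the mean matched exactly). The supported
#' families are those used for decision-model inputs: `beta` for
#' probabilities and utilities, `gamma` for costs, `lognormal` for positive
#' skewed quantities, `uniform`, and `fixed` (a point mass).
#'
#' Degenerate specifications are coerced: a baseline of exactly 0 with
#' `up > 0` (the log-normal disutility rows, which have no mass at zero)
#' and a baseline of exactly 1 for a beta (which would be a point mass)
#' become `uniform[low, up]`; the returned object carries `coerced = TRUE`
#' so callers can tell. A zero-width range collapses to `fixed`.
#'
#' @param kind one of `"beta"`, `"gamma"`, `"lognormal"`, `"uniform"`,
#'   `"fixed"`; alternatively a one-row data.frame with columns
#'   `kind`, `baseline`, `low`, `up` (and optionally `path`).
#' @param baseline,low,up numeric; `low <= baseline <= up` where present.
#' @return an object of class `msim_dist` with elements `kind`, `pars`,
#'   `mean`, `coerced`, and a quantile function `qfun(p)` that maps
#'   uniform deviates to draws (so sampling is reproducible from any
#'   uniform stream).
#' @examples
#' d <- resolve_distribution("beta", 0.21, 0.16, 0.29)
#' mean(d$qfun(runif(1e4)))  # ~0.21
#' @export
resolve_distribution <- function(kind, baseline = NULL, low = NULL, up = NULL) {
  if (is.data.frame(kind)) {
    stopifnot(nrow(kind) == 1L)
    baseline <- kind$baseline; low <- kind$low; up <- kind$up
    kind <- kind$kind
  }
  kind <- match.arg(kind, c("beta", "gamma", "lognormal", "uniform", "fixed"))
  if (kind == "fixed" || (!is.null(low) && !is.null(up) && low == up &&
                          baseline == low)) {
    return(structure(list(kind = "fixed", pars = list(value = baseline),
                          mean = baseline, coerced = FALSE,
                          qfun = function(p) rep(baseline, length(p))),
                     class = "msim_dist"))
  }
  if (is.null(low) || is.null(up))
    stop("low and up are required for kind = ", kind)
  if (low > baseline || baseline > up)
    stop(sprintf("infeasible specification: need low <= baseline <= up, got %g, %g, %g",
                 low, baseline, up))

  coerced <- FALSE
  if (baseline == 0 && up > 0) { kind <- "uniform"; coerced <- TRUE }
  if (kind == "beta" && baseline == 1 && low < 1) { kind <- "uniform"; coerced <- TRUE }
  if (kind == "beta" && (baseline < 0 || baseline > 1))
    stop("beta requested for a baseline outside [0,1]: ", baseline)

  if (kind == "uniform") {
    return(structure(list(kind = "uniform", pars = list(min = low, max = up),
                          mean = (low + up) / 2, coerced = coerced,
                          qfun = function(p) stats::qunif(p, low, up)),
                     class = "msim_dist"))
  }

  # objective: squared distance of the central 95% interval from [low, up],
  # searched over a dispersion parameter with the mean pinned at baseline
  qloss <- function(q025, q975) (q025 - low)^2 + (q975 - up)^2

  pars <- switch(kind,
    beta = {
      m <- baseline
      f <- function(logk) {
        k <- exp(logk)
        qloss(stats::qbeta(0.025, m * k, (1 - m) * k),
              stats::qbeta(0.975, m * k, (1 - m) * k))
      }
      k <- exp(stats::optimize(f, c(log(0.5), log(1e7)))$minimum)
      list(shape1 = m * k, shape2 = (1 - m) * k)
    },
    gamma = {
      m <- baseline
      f <- function(logs) {
        s <- exp(logs)
        qloss(stats::qgamma(0.025, shape = s, rate = s / m),
              stats::qgamma(0.975, shape = s, rate = s / m))
      }
      s <- exp(stats::optimize(f, c(log(1e-2), log(1e7)))$minimum)
      list(shape = s, rate = s / m)
    },
    lognormal = {
      m <- baseline
      f <- function(logsd) {
        sdl <- exp(logsd)
        mul <- log(m) - sdl^2 / 2   # keeps E[X] = baseline
        qloss(stats::qlnorm(0.025, mul, sdl), stats::qlnorm(0.975, mul, sdl))
      }
      sdl <- exp(stats::optimize(f, c(log(1e-6), log(3)))$minimum)
      list(meanlog = log(m) - sdl^2 / 2, sdlog = sdl)
    })

  qfun <- switch(kind,
    beta = function(p) stats::qbeta(p, pars$shape1, pars$shape2),
    gamma = function(p) stats::qgamma(p, shape = pars$shape, rate = pars$rate),
    lognormal = function(p) stats::qlnorm(p, pars$meanlog, pars$sdlog))

  structure(list(kind = kind, pars = pars, mean = baseline, coerced = coerced,
                 qfun = qfun),
            class = "msim_dist")
}

#' @export
print.msim_dist <- function(x, ...) {
  cat(sprintf("<msim_dist %s mean=%g%s>\n", x$kind, x$mean,
              if (x$coerced) " (coerced)" else ""))
  invisible(x)
}

# resolve every row of a distribution table once; returns a named list of
# msim_dist keyed by parameter path
resolve_all_distributions <- function(dist_table) {
  out <- lapply(seq_len(nrow(dist_table)), function(i)
    resolve_distribution(dist_table[i, , drop = FALSE]))
  names(out) <- dist_table$path
  out
}
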