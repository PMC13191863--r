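#' Age-band lookup tables
#'
#' A piecewise-constant table over contiguous, non-overlapping integer age
#' bands, used for age-specific quantities such as all-cause mortality,
#' disease-onset probabilities and healthy-state utilities. Lookups at ages
#' above the last band clamp to the last band (women aged 75+ use the
#' 75-79 band).
#'
#' @param low,high integer vectors of inclusive band boundaries (years).
#' @param values numeric vector, one value per band.
#' @return an object of class `age_band_table`.
#' @examples
#' tab <- age_band_table(c(40, 45), c(44, 49), c(0.001, 0.002))
#' ab_lookup(tab, 40:49)
#' @export
age_band_table <- function(low, high, values) {
  stopifnot(length(low) == length(high), length(low) == length(values),
            length(low) >= 1L)
  low <- as.integer(low); high <- as.integer(high)
  if (any(high < low)) stop("age bands must have high >= low")
  if (length(low) > 1L) {
    if (any(low[-1L] != high[-length(high)] + 1L))
      stop("age bands must be contiguous and non-overlapping")
  }
  structure(list(low = low, high = high, values = as.numeric(values)),
            class = "age_band_table")
}

#' Look up band values by age
#'
#' @param tab an [age_band_table()].
#' @param age integer vector of ages in years. Ages above the last band use
#'   the last band; ages below the first band are an error.
#' @return numeric vector of band values, one per age.
#' @export
ab_lookup <- function(tab, age) {
  stopifnot(inherits(tab, "age_band_table"))
  if (any(age < tab$low[1L]))
    stop("age below the first band (", tab$low[1L], ")")
  idx <- findInterval(age, tab$low)
  tab$values[idx]
}

#' @export
print.age_band_table <- function(x, ...) {
  df <- data.frame(band = sprintf("%d-%d", x$low, x$high), value = x$values)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
format.age_band_table <- function(x, ...) {
  paste(sprintf("%d-%d: %g", x$low, x$high, x$values), collapse = "; ")
}

# internal: serialize to a plain list for YAML/JSON round-trips
ab_to_list <- function(tab) {
  list(low = tab$low, high = tab$high, values = tab$values)
}

ab_from_list <- function(x) {
  age_band_table(x$low, x$high, x$values)
}
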