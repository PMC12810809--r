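#' Depth-marginal distribution specification
#'
#' A small specification object for the marginal distribution of true
#' pathological depth of invasion (pDOI, mm). The piecewise-error generator
#' ([generate_cohort()]) requires a family with support on (0, Inf)
#' (`"lognormal"` or `"gamma"`); the copula generator
#' ([generate_copula_cohort()]) additionally accepts `"normal"`, whose
#' occasional negative draws are truncated at 0 by the record invariant.
#'
#' @param family One of `"lognormal"`, `"gamma"`, `"normal"`.
#' @param ... Named parameters for the family: `meanlog`/`sdlog`
#'   (lognormal), `shape`/`rate` (gamma), `mean`/`sd` (normal).
#'
#' @return An object of class `"doi_dist"`.
#' @examples
#' doi_dist("lognormal", meanlog = log(8), sdlog = 0.95)
#' @export
doi_dist <- function(family = c("lognormal", "gamma", "normal"), ...) {
  family <- match.arg(family)
  pars <- list(...)
  needed <- switch(family,
    lognormal = c("meanlog", "sdlog"),
    gamma     = c("shape", "rate"),
    normal    = c("mean", "sd")
  )
  if (length(pars) && is.null(names(pars))) names(pars) <- needed[seq_along(pars)]
  missing <- setdiff(needed, names(pars))
  if (length(missing)) {
    stop("doi_dist: missing parameter(s) for family '", family, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (p in needed) {
    v <- pars[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("doi_dist: parameter '", p, "' must be a finite number", call. = FALSE)
    }
  }
  scale_par <- switch(family, lognormal = "sdlog", gamma = "rate", normal = "sd")
  if (pars[[scale_par]] <= 0) {
    stop("doi_dist: parameter '", scale_par, "' must be > 0", call. = FALSE)
  }
  if (family == "gamma" && pars$shape <= 0) {
    stop("doi_dist: parameter 'shape' must be > 0", call. = FALSE)
  }
  structure(c(list(family = family), pars[needed]), class = "doi_dist")
}

#' @export
print.doi_dist <- function(x, ...) {
  pars <- x[names(x) != "family"]
  cat("<doi_dist> ", x$family, "(",
      paste(sprintf("%s = %g", names(pars), unlist(pars)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# random draws and quantile function, dispatched on the family
r_doi_dist <- function(dist, n) {
  switch(dist$family,
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    gamma     = stats::rgamma(n, shape = dist$shape, rate = dist$rate),
    normal    = stats::rnorm(n, dist$mean, dist$sd)
  )
}

q_doi_dist <- function(dist, p) {
  switch(dist$family,
    lognormal = stats::qlnorm(p, dist$meanlog, dist$sdlog),
    gamma     = stats::qgamma(p, shape = dist$shape, rate = dist$rate),
    normal    = stats::qnorm(p, dist$mean, dist$sd)
  )
}

has_positive_support <- function(dist) dist$family %in% c("lognormal", "gamma")
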