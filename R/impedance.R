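#' Impedance (distance-decay) functions
#'
#' Impedance functions translate a travel cost (minutes) into a weight in
#' \[0, 1\] that models the declining propensity to travel as cost grows.
#' Three kinds are supported:
#'
#' \describe{
#'   \item{binary}{weight 1 for costs up to a threshold `d0`, 0 beyond —
#'     the classic 2SFCA catchment.}
#'   \item{stepwise}{a non-increasing staircase: weight `k_r` for costs in
#'     the bracket `(d_{r-1}, d_r]` (the first bracket starts at 0 and is
#'     closed at both ends), 0 beyond the last break — the E2SFCA form.}
#'   \item{gaussian}{`exp(-d^2 / (2 * sigma^2))`, optionally truncated to 0
#'     beyond a hard `cutoff`.}
#' }
#'
#' Bracket boundaries are closed on the right: a cost exactly equal to a
#' break belongs to the lower (larger-weight) bracket.
#'
#' @param d0 binary catchment threshold, minutes; must be positive.
#' @param breaks strictly increasing upper bracket bounds, minutes.
#' @param weights one weight per bracket, in (0, 1], non-increasing.
#' @param sigma Gaussian standard deviation, minutes; must be positive.
#' @param cutoff optional hard cutoff, minutes; weight is 0 beyond it.
#'
#' @return An object of class `fca_impedance`.
#' @examples
#' impedance_binary(15)
#' impedance_stepwise(c(10, 20, 30), c(0.945, 0.600, 0.242))
#' impedance_gaussian(15, cutoff = 45)
#' @seealso [gaussian_stepwise()] to discretize a Gaussian onto brackets,
#'   [impedance_weights()] to evaluate a specification over a cost matrix.
#' @export
impedance_binary <- function(d0) {
  if (!is.numeric(d0) || length(d0) != 1L || !is.finite(d0) || d0 <= 0)
    stop("binary impedance threshold `d0` must be a single positive number")
  structure(list(kind = "binary", d0 = as.numeric(d0)),
            class = "fca_impedance")
}

#' @rdname impedance_binary
#' @export
impedance_stepwise <- function(breaks, weights) {
  breaks <- as.numeric(breaks)
  weights <- as.numeric(weights)
  if (length(breaks) < 1L || anyNA(breaks) || any(breaks <= 0))
    stop("stepwise breaks must be positive numbers")
  if (is.unsorted(breaks, strictly = TRUE))
    stop("stepwise breaks must be strictly increasing")
  if (length(weights) != length(breaks))
    stop("need exactly one weight per bracket (", length(breaks), ")")
  if (anyNA(weights) || any(weights <= 0) || any(weights > 1))
    stop("stepwise weights must lie in (0, 1]")
  if (is.unsorted(rev(weights)))
    stop("stepwise weights must be non-increasing with cost")
  structure(list(kind = "stepwise", breaks = breaks, weights = weights),
            class = "fca_impedance")
}

#' @rdname impedance_binary
#' @export
impedance_gaussian <- function(sigma, cutoff = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("gaussian `sigma` must be a single positive number")
  if (!is.null(cutoff)) {
    if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
      stop("`cutoff` must be a single positive number")
    cutoff <- as.numeric(cutoff)
  }
  structure(list(kind = "gaussian", sigma = as.numeric(sigma),
                 cutoff = cutoff),
            class = "fca_impedance")
}

#' Discretize a Gaussian decay onto stepwise brackets
#'
#' Builds a stepwise impedance whose bracket weights are the Gaussian
#' `exp(-d^2 / (2 * sigma^2))` evaluated at each bracket's upper break,
#' with weight 0 beyond the last break. This is the standard way to
#' calibrate an E2SFCA staircase from a continuous decay: for example,
#' breaks (5, 10, 15, 20, 30, 45) minutes with `sigma = 15` give weights
#' 0.946, 0.801, 0.607, 0.411, 0.135, 0.011 (to 3 decimals).
#'
#' @inheritParams impedance_binary
#' @return An `fca_impedance` of kind `"stepwise"`.
#' @examples
#' gaussian_stepwise(c(5, 10, 15, 20, 30, 45), sigma = 15)
#' @export
gaussian_stepwise <- function(breaks, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single positive number")
  breaks <- as.numeric(breaks)
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  impedance_stepwise(breaks, exp(-breaks^2 / (2 * sigma^2)))
}

#' Evaluate an impedance specification over a cost matrix
#'
#' Produces the N x J weight matrix `W` with `W[i, j]` the impedance at
#' travel cost `costs[i, j]`. Unreachable pairs (infinite cost) always get
#' weight exactly 0. Row and column names of `costs` are carried through.
#'
#' @param spec an [fca_impedance][impedance_binary] object.
#' @param costs numeric matrix of travel costs (minutes), `Inf` for
#'   unreachable pairs; typically the `costs` element of a scenario.
#' @return numeric weight matrix with entries in \[0, 1\].
#' @examples
#' d <- matrix(c(5, 20, 12, 50), 2, 2)
#' impedance_weights(impedance_binary(15), d)
#' @export
impedance_weights <- function(spec, costs) {
  if (!inherits(spec, "fca_impedance"))
    stop("`spec` must be an fca_impedance object")
  if (inherits(costs, "fca_scenario")) costs <- costs$costs
  if (!is.matrix(costs) || !is.numeric(costs))
    stop("`costs` must be a numeric matrix")
  if (any(costs < 0, na.rm = TRUE)) stop("costs must be non-negative")
  w <- switch(spec$kind,
    binary = (costs <= spec$d0) * 1,
    stepwise = {
      v <- matrix(0, nrow(costs), ncol(costs))
      # assign from widest bracket down so the smallest break wins ties
      for (r in rev(seq_along(spec$breaks)))
        v[costs <= spec$breaks[r]] <- spec$weights[r]
      v
    },
    gaussian = {
      v <- exp(-costs^2 / (2 * spec$sigma^2))
      v[!is.finite(costs)] <- 0
      if (!is.null(spec$cutoff)) v[costs > spec$cutoff] <- 0
      v
    },
    stop("unknown impedance kind: ", spec$kind)
  )
  dimnames(w) <- dimnames(costs)
  w
}

#' Parse a compact impedance description
#'
#' Accepts the command-line shorthand used throughout the package:
#' `"binary:15"` (threshold minutes), `"stepwise:5=0.946,10=0.801,..."`
#' (break=weight pairs), `"gaussian:15"` or `"gaussian:15@45"`
#' (sigma, optionally `@cutoff`).
#'
#' @param text a single character string.
#' @return An `fca_impedance` object.
#' @examples
#' parse_impedance("binary:15")
#' parse_impedance("stepwise:10=0.945,20=0.600,30=0.242")
#' @export
parse_impedance <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("impedance description must be a single non-empty string")
  parts <- strsplit(text, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop("impedance description must look like kind:params, got '", text, "'")
  kind <- trimws(parts[1L])
  body <- trimws(parts[2L])
  switch(kind,
    binary = impedance_binary(as.numeric(body)),
    gaussian = {
      at <- strsplit(body, "@", fixed = TRUE)[[1L]]
      impedance_gaussian(as.numeric(at[1L]),
                         cutoff = if (length(at) > 1L) as.numeric(at[2L]))
    },
    stepwise = {
      pairs <- strsplit(strsplit(body, ",", fixed = TRUE)[[1L]], "=",
                        fixed = TRUE)
      if (any(lengths(pairs) != 2L))
        stop("stepwise description must be break=weight pairs")
      impedance_stepwise(vapply(pairs, function(p) as.numeric(p[1L]), 0),
                         vapply(pairs, function(p) as.numeric(p[2L]), 0))
    },
    stop("unknown impedance kind '", kind,
         "'; valid kinds: binary, stepwise, gaussian")
  )
}

#' Short human-readable label for an impedance specification
#' @param spec an `fca_impedance` object.
#' @return a character string such as `"binary:15"`.
#' @keywords internal
#' @export
format.fca_impedance <- function(x, ...) {
  switch(x$kind,
    binary = paste0("binary:", x$d0),
    stepwise = paste0("stepwise:", paste0(x$breaks, "=",
                                          signif(x$weights, 4),
                                          collapse = ",")),
    gaussian = paste0("gaussian:", x$sigma,
                      if (!is.null(x$cutoff)) paste0("@", x$cutoff))
  )
}

#' @export
print.fca_impedance <- function(x, ...) {
  cat("<fca_impedance> ", format(x), "\n", sep = "")
  invisible(x)
}
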