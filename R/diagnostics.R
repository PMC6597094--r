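#' Conservation report: does the arithmetic preserve people and service?
#'
#' Summarizes the mass balance of a run. Nominal demand (the sum of the
#' facility demands) is compared against the actual population: under raw
#' binary weights overlapping catchments double-count people and nominal
#' demand exceeds population (demand inflation); under steep stepwise
#' weights it can fall short (deflation); under the balanced method it
#' equals the covered population exactly. Total accessibility is likewise
#' compared against the total level of service. The per-center coverage
#' count `K_i` — the number of facilities whose catchment includes center
#' `i` (strictly positive weights in row `i`) — is the multiplicity with
#' which that center is counted under raw binary weights.
#'
#' @param result an [fca_result][fca_run] object.
#' @return An `fca_conservation` object (list) with `total_population`,
#'   `total_nominal_demand`, `total_supply`, `total_los`,
#'   `total_accessibility` (both at the result's reporting scale),
#'   `regional_ppr` (supply per `scale` persons), `implied_ppr` (supply per
#'   `scale` units of nominal demand, `NA` if demand is 0), and
#'   `coverage_counts`.
#' @examples
#' fx <- simulated_nine_centers()
#' r <- fca_run_weights(fx$centers$size, fx$facilities$size,
#'                      fx$weights$binary, method = "2sfca")
#' conservation_report(r)$total_nominal_demand  # 9750, vs population 4500
#' @export
conservation_report <- function(result) {
  stopifnot(inherits(result, "fca_result"))
  sc <- result$scale
  pop <- sum(result$centers$size)
  dem <- sum(result$demand$facility_demand)
  sup <- sum(result$facilities$size)
  K <- rowSums(result$W > 0)
  structure(list(
    total_population = pop,
    total_nominal_demand = dem,
    total_supply = sup,
    total_los = sum(result$los$los) * sc,
    total_accessibility = sum(result$accessibility) * sc,
    regional_ppr = sup / pop * sc,
    implied_ppr = if (dem > 0) sup / dem * sc else NA_real_,
    coverage_counts = K,
    scale = sc, method = result$method), class = "fca_conservation")
}

#' @export
print.fca_conservation <- function(x, ...) {
  cat("<fca_conservation> method = ", x$method, "\n", sep = "")
  cat(sprintf("  population %s vs nominal demand %s (ratio %.3f)\n",
              format(x$total_population, big.mark = ","),
              format(round(x$total_nominal_demand, 1), big.mark = ","),
              x$total_nominal_demand / x$total_population))
  cat(sprintf("  regional PPR %.3f, implied PPR %.3f (per %s)\n",
              x$regional_ppr, x$implied_ppr, format(x$scale, big.mark = ",")))
  cat(sprintf("  total LOS %.3f vs total accessibility %.3f (per %s)\n",
              x$total_los, x$total_accessibility,
              format(x$scale, big.mark = ",")))
  invisible(x)
}

#' Inflation factors: unadjusted vs adjusted runs
#'
#' Ratios quantifying how much an unadjusted FCA run inflates demand and
#' accessibility relative to a balanced (proportionally allocated) run on
#' the same scenario and impedance: per facility,
#' `D_j(unadjusted) / D*_j(adjusted)`; per center,
#' `A_i(unadjusted) / A*_i(adjusted)`. Ratios with a zero denominator are
#' reported as `NA`, never infinity. When catchments do not overlap at all
#' (each center reaches exactly one facility and vice versa) every factor
#' is 1.
#'
#' @param unadjusted,adjusted two [fca_result][fca_run] objects computed on
#'   the same scenario (ids and sizes must match).
#' @return list of two data frames: `facilities` (id, demand_unadjusted,
#'   demand_adjusted, demand_ratio) and `centers` (id, access_unadjusted,
#'   access_adjusted, access_ratio, coverage_count).
#' @export
inflation_factors <- function(unadjusted, adjusted) {
  stopifnot(inherits(unadjusted, "fca_result"),
            inherits(adjusted, "fca_result"))
  if (!identical(unadjusted$centers$id, adjusted$centers$id) ||
      !identical(unadjusted$facilities$id, adjusted$facilities$id) ||
      !isTRUE(all.equal(unadjusted$centers$size, adjusted$centers$size)) ||
      !isTRUE(all.equal(unadjusted$facilities$size, adjusted$facilities$size)))
    stop("the two runs are not on the same scenario")
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  du <- unadjusted$demand$facility_demand
  da <- adjusted$demand$facility_demand
  au <- unadjusted$accessibility
  aa <- adjusted$accessibility
  list(
    facilities = data.frame(id = unadjusted$facilities$id,
                            demand_unadjusted = du, demand_adjusted = da,
                            demand_ratio = ratio(du, da),
                            stringsAsFactors = FALSE),
    centers = data.frame(id = unadjusted$centers$id,
                         access_unadjusted = au * unadjusted$scale,
                         access_adjusted = aa * adjusted$scale,
                         access_ratio = ratio(au, aa),
                         coverage_count = rowSums(unadjusted$W > 0),
                         stringsAsFactors = FALSE))
}

#' Accessibility disparity indices
#'
#' Two equity measures over a set of per-center accessibilities:
#' \describe{
#'   \item{`equitable_share`}{the total level of service divided by the
#'     number of population centers is each center's "equitable" share
#'     `L-bar`; the disparity index is `A_i - L-bar`. Positive values mean
#'     a center's accessibility exceeds its equitable share. Most
#'     interpretable on balanced results, where total accessibility equals
#'     total LOS and so the mean disparity is exactly 0.}
#'   \item{`spar`}{the spatial access ratio `A_i / mean(A)`, a
#'     dimensionless relative measure robust to the impedance scale.}
#' }
#'
#' @param result an [fca_result][fca_run] object.
#' @param mode `"equitable_share"` (default) or `"spar"`.
#' @return data frame with columns `id`, `accessibility` (per-person) and
#'   `disparity` or `spar`; the equitable share is attached as attribute
#'   `equitable_share`.
#' @examples
#' fx <- simulated_nine_centers()
#' r <- fca_run_weights(fx$centers$size, fx$facilities$size,
#'                      fx$weights$binary, method = "balanced")
#' d <- disparity(r)
#' round(attr(d, "equitable_share") * 1000, 3)  # about 0.448 per 1,000
#' @export
disparity <- function(result, mode = c("equitable_share", "spar")) {
  stopifnot(inherits(result, "fca_result"))
  mode <- match.arg(mode)
  A <- result$accessibility
  n <- length(A)
  if (n == 0L) stop("no population centers")
  out <- data.frame(id = result$centers$id, accessibility = A,
                    stringsAsFactors = FALSE)
  if (mode == "equitable_share") {
    lbar <- sum(result$los$los) / n
    out$disparity <- A - lbar
    attr(out, "equitable_share") <- lbar
  } else {
    out$spar <- if (mean(A) > 0) A / mean(A) else NA_real_
  }
  attr(out, "mode") <- mode
  out
}
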