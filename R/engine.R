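#' Step 1: allocate population demand to facilities
#'
#' Disaggregated demand is `D[i, j] = P[i] * W[i, j]`: the population of
#' center `i` weighted by the (raw, standardized, or selection-weighted)
#' weight binding it to facility `j`. Facility demand `D_j` is the column
#' sum. With raw impedance weights this is the classic first FCA step, and
#' overlapping catchments double-count population (demand inflation); with
#' row-standardized weights each covered center contributes exactly its
#' population.
#'
#' @param P numeric vector of center populations (length N).
#' @param W numeric N x J weight matrix.
#' @return An `fca_demand` object: list with `pair_demand` (N x J matrix)
#'   and `facility_demand` (length-J column totals).
#' @examples
#' W <- matrix(c(1, 1, 0, 1), 2, 2)
#' fca_step1_demand(c(100, 200), W)$facility_demand
#' @export
fca_step1_demand <- function(P, W) {
  if (!is.matrix(W) || !is.numeric(W)) stop("`W` must be a numeric matrix")
  if (length(P) != nrow(W))
    stop("length(P) = ", length(P), " but W has ", nrow(W), " rows")
  pair <- unclass(W) * as.numeric(P)
  attributes(pair) <- attributes(pair)["dim"]
  dimnames(pair) <- dimnames(W)
  structure(list(pair_demand = pair, facility_demand = colSums(pair)),
            class = "fca_demand")
}

#' Step 1: level of service from supply and demand
#'
#' `L_j = S_j / D_j`, the facility's supply divided by the demand
#' aggregated over its catchment — a local provider-to-population ratio
#' when demand is conserved. Levels of service are stored per person;
#' reporting functions rescale (per 1,000 by default). Facilities with
#' zero demand have no defined ratio: their LOS is set to 0, they are
#' recorded in `undefined`, and a warning is raised so they can be
#' excluded from aggregation rather than propagate infinities.
#'
#' @param S numeric vector of facility supplies (length J).
#' @param demand an [fca_demand][fca_step1_demand] object (or a numeric
#'   vector of facility demands).
#' @return An `fca_los` object: list with `los` (per-person, length J) and
#'   `undefined` (ids/indices of zero-demand facilities).
#' @export
fca_step1_los <- function(S, demand) {
  D <- if (inherits(demand, "fca_demand")) demand$facility_demand
       else as.numeric(demand)
  if (length(S) != length(D))
    stop("length(S) = ", length(S), " but there are ", length(D),
         " facility demands")
  zero <- D == 0
  los <- ifelse(zero, 0, S / D)
  names(los) <- names(D)
  ids <- if (is.null(names(D))) which(zero) else names(D)[zero]
  if (any(zero))
    warning("facility with zero demand, level of service undefined: ",
            paste(ids, collapse = ", "))
  structure(list(los = los, undefined = ids), class = "fca_los")
}

#' Step 2: aggregate levels of service into accessibility
#'
#' `allocation[i, j] = L_j * W2[i, j]` and accessibility `A_i` is the row
#' sum — the service center `i` receives from every facility whose
#' catchment reaches it. `W2` is the raw weight matrix for the classic
#' methods, the elementwise square for M2SFCA, or the column-standardized
#' matrix for the balanced method. Facilities with undefined LOS carry
#' LOS 0 and so contribute nothing.
#'
#' @param los an [fca_los][fca_step1_los] object (or per-person numeric
#'   vector).
#' @param W2 numeric N x J allocation weight matrix.
#' @return An `fca_access` object: list with `accessibility` (length N,
#'   per-person) and `allocation` (N x J matrix).
#' @export
fca_step2_accessibility <- function(los, W2) {
  L <- if (inherits(los, "fca_los")) los$los else as.numeric(los)
  if (!is.matrix(W2) || !is.numeric(W2)) stop("`W2` must be a numeric matrix")
  if (length(L) != ncol(W2))
    stop("length(los) = ", length(L), " but W2 has ", ncol(W2), " columns")
  alloc <- sweep(unclass(W2), 2L, L, "*")
  dimnames(alloc) <- dimnames(W2)
  structure(list(accessibility = rowSums(alloc), allocation = alloc),
            class = "fca_access")
}

#' Selection weights (3SFCA)
#'
#' Row-normalized shares `G[i, j] = T[i, j] / sum_j T[i, j]`: the
#' propensity of center `i` to choose facility `j` among the facilities it
#' can reach. Numerically identical to [row_standardize()] with unit
#' slack; kept as a named operation because 3SFCA composes it with the raw
#' weights rather than substituting it for them. Zero rows stay zero.
#'
#' @param TW numeric N x J matrix of selection impedance values (often the
#'   same impedance weights used for `W`).
#' @return numeric matrix of shares; every covered row sums to 1.
#' @export
fca_selection_weights <- function(TW) {
  G <- row_standardize(TW)
  attributes(G) <- attributes(G)[c("dim", "dimnames")]
  G
}

#' Run a complete FCA computation
#'
#' Executes one of the five method variants end to end from a scenario (or
#' from a prebuilt weight matrix via `fca_run_weights()`):
#'
#' \describe{
#'   \item{`2sfca`, `e2sfca`}{the unadjusted two-step method; the two tags
#'     run the same engine and differ only in the impedance supplied
#'     (binary vs stepwise).}
#'   \item{`3sfca`}{three-step: selection weights `G` (row-normalized from
#'     `selection_impedance`, defaulting to the same weights as `W`)
#'     multiply the demand weights elementwise in step 1; step 2 allocates
#'     with the column-wise analogue of `G` times `W`.}
#'   \item{`m2sfca`}{step 1 as the unadjusted method; step 2 discounts by
#'     the elementwise *square* of the weights.}
#'   \item{`balanced`}{proportional allocation: step 1 uses the
#'     row-standardized weights (each covered center contributes exactly
#'     its population), step 2 the column-standardized weights (each
#'     patronized facility allocates exactly its level of service). Slack
#'     factors relax the exact allocation.}
#' }
#'
#' @param scenario an [fca_scenario()] object.
#' @param impedance an [fca_impedance][impedance_binary] object or a
#'   compact string accepted by [parse_impedance()].
#' @param method one of `"2sfca"`, `"e2sfca"`, `"3sfca"`, `"m2sfca"`,
#'   `"balanced"`.
#' @param slack_demand,slack_supply optional positive slack factors (scalar
#'   or per-center / per-facility vectors), used by the balanced method.
#' @param selection_impedance optional separate impedance (object or
#'   string) for the 3SFCA selection weights `T`; defaults to `impedance`.
#' @param scale reporting multiplier for per-person quantities (default
#'   1000: physicians per 1,000 population).
#' @return An `fca_result` object: list with `method`, `impedance` (label),
#'   `centers`, `facilities`, `W` (raw weights), `demand` (`fca_demand`),
#'   `los` (`fca_los`), `accessibility` (per-person vector), `allocation`
#'   (N x J service allocation), `scale`.
#' @examples
#' fx <- simulated_nine_centers()
#' r <- fca_run_weights(fx$centers$size, fx$facilities$size,
#'                      fx$weights$binary, method = "balanced")
#' round(r$los$los * 1000, 3)  # local PPR per 1,000
#' @export
fca_run <- function(scenario, impedance,
                    method = c("2sfca", "e2sfca", "3sfca", "m2sfca",
                               "balanced"),
                    slack_demand = NULL, slack_supply = NULL,
                    selection_impedance = NULL, scale = 1000) {
  stopifnot(inherits(scenario, "fca_scenario"))
  method <- match.arg(method)
  if (is.character(impedance)) impedance <- parse_impedance(impedance)
  W <- impedance_weights(impedance, scenario$costs)
  TW <- NULL
  if (!is.null(selection_impedance)) {
    if (is.character(selection_impedance))
      selection_impedance <- parse_impedance(selection_impedance)
    TW <- impedance_weights(selection_impedance, scenario$costs)
  }
  fca_run_weights(scenario$centers$size, scenario$facilities$size, W,
                  method = method, slack_demand = slack_demand,
                  slack_supply = slack_supply, selection_weights_input = TW,
                  scale = scale,
                  centers = scenario$centers, facilities = scenario$facilities,
                  impedance_label = format(impedance))
}

#' @rdname fca_run
#' @param P,S population and supply vectors.
#' @param W raw impedance weight matrix (N x J), e.g. from
#'   [impedance_weights()] or a built-in fixture.
#' @param selection_weights_input optional matrix of selection impedance
#'   values `T` for 3SFCA; defaults to `W`.
#' @param centers,facilities optional entity data frames carried into the
#'   result (ids default to rownames/colnames of `W`).
#' @param impedance_label label stored in the result.
#' @export
fca_run_weights <- function(P, S, W,
                            method = c("2sfca", "e2sfca", "3sfca", "m2sfca",
                                       "balanced"),
                            slack_demand = NULL, slack_supply = NULL,
                            selection_weights_input = NULL, scale = 1000,
                            centers = NULL, facilities = NULL,
                            impedance_label = "custom") {
  method <- match.arg(method)
  W <- check_weights(W)
  if (length(P) != nrow(W) || length(S) != ncol(W))
    stop("dimension mismatch: W is ", nrow(W), " x ", ncol(W),
         " but length(P) = ", length(P), ", length(S) = ", length(S))
  if (is.null(centers))
    centers <- data.frame(id = margin_ids(W, 1L), size = as.numeric(P),
                          stringsAsFactors = FALSE)
  if (is.null(facilities))
    facilities <- data.frame(id = margin_ids(W, 2L), size = as.numeric(S),
                             stringsAsFactors = FALSE)

  if (method %in% c("2sfca", "e2sfca")) {
    W1 <- W
    W2 <- W
  } else if (method == "m2sfca") {
    W1 <- W
    W2 <- W * W
  } else if (method == "3sfca") {
    TW <- if (is.null(selection_weights_input)) W
          else check_weights(selection_weights_input)
    G <- fca_selection_weights(TW)
    Gj <- column_standardize(TW)
    attributes(Gj) <- attributes(Gj)[c("dim", "dimnames")]
    W1 <- G * W
    W2 <- Gj * W
  } else { # balanced
    Wi <- row_standardize(W, slack_demand)
    Wj <- column_standardize(W, slack_supply)
    W1 <- structure(unclass(Wi), uncovered = NULL)
    attributes(W1) <- attributes(W1)[c("dim", "dimnames")]
    W2 <- unclass(Wj)
    attributes(W2) <- attributes(W2)[c("dim", "dimnames")]
  }

  demand <- fca_step1_demand(P, W1)
  los <- fca_step1_los(S, demand)
  acc <- fca_step2_accessibility(los, W2)

  structure(list(method = method, impedance = impedance_label,
                 centers = centers, facilities = facilities, W = W,
                 demand = demand, los = los,
                 accessibility = acc$accessibility,
                 allocation = acc$allocation, scale = scale),
            class = "fca_result")
}

#' @export
print.fca_result <- function(x, ...) {
  sc <- x$scale
  cat("<fca_result> method = ", x$method, ", impedance = ", x$impedance,
      "\n", sep = "")
  cat(sprintf(
    "  population %s | total demand %s | supply %s | total LOS %.3f | total accessibility %.3f (per %s)\n",
    format(sum(x$centers$size), big.mark = ","),
    format(round(sum(x$demand$facility_demand), 3), big.mark = ","),
    sum(x$facilities$size), sum(x$los$los) * sc,
    sum(x$accessibility) * sc, format(sc, big.mark = ",")))
  invisible(x)
}

#' Per-center and per-facility summaries of a result
#'
#' @param object an `fca_result`.
#' @param ... unused.
#' @return list of two data frames, `centers` (id, population,
#'   accessibility at reporting scale) and `facilities` (id, supply,
#'   demand, level_of_service at reporting scale).
#' @export
summary.fca_result <- function(object, ...) {
  sc <- object$scale
  list(centers = data.frame(id = object$centers$id,
                            population = object$centers$size,
                            accessibility = object$accessibility * sc,
                            stringsAsFactors = FALSE),
       facilities = data.frame(id = object$facilities$id,
                               supply = object$facilities$size,
                               demand = object$demand$facility_demand,
                               level_of_service = object$los$los * sc,
                               stringsAsFactors = FALSE))
}
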