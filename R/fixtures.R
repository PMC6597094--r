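#' Built-in worked example: three centers, two clinics
#'
#' A hand-sized system used throughout the package documentation: three
#' population centers of 100 people each and two clinics of 10 physicians
#' each, all mutually reachable. Two weight matrices are supplied directly
#' (no cost matrix): an all-ones binary matrix, and a stepwise matrix
#' `rbind(c(0.8, 0.8), c(0.8, 0.4), c(0.4, 0.8))` in which the peripheral
#' centers are nearer to one clinic than the other. Under the balanced
#' method both impedances allocate exactly 150 people to each clinic, and
#' binary accessibility is 0.044 physicians per person at every center.
#'
#' @return list with `centers`, `facilities` (entity data frames) and
#'   `weights` (list of `binary` and `stepwise` matrices).
#' @examples
#' fx <- toy_two_clinics()
#' r <- fca_run_weights(fx$centers$size, fx$facilities$size,
#'                      fx$weights$binary, method = "balanced")
#' r$demand$facility_demand  # 150 150
#' @export
toy_two_clinics <- function() {
  centers <- data.frame(id = paste0("c", 1:3), size = rep(100, 3),
                        stringsAsFactors = FALSE)
  facilities <- data.frame(id = paste0("f", 1:2), size = rep(10, 2),
                           stringsAsFactors = FALSE)
  dn <- list(centers$id, facilities$id)
  list(centers = centers, facilities = facilities,
       weights = list(
         binary = matrix(1, 3, 2, dimnames = dn),
         stepwise = matrix(c(0.8, 0.8, 0.4,
                             0.8, 0.4, 0.8), 3, 2, dimnames = dn)))
}

#' Built-in worked example: nine centers, three clinics
#'
#' The package's reference system for comparing method variants: nine
#' population centers (populations 250, 250, 500, 500, 1000, 500, 1000,
#' 250, 250; total 4,500) and three clinics supplying 1, 3 and 2
#' physicians (regional PPR 1.333 per 1,000). Binary and stepwise
#' (weights 0.945 / 0.600 / 0.242) impedance matrices are supplied
#' directly. Under raw binary weights nominal demand sums to 9,750 —
#' more than double the population — while the stepwise weights imply
#' 4,315.5; the balanced method restores exactly 4,500 under either.
#'
#' @return list with `centers`, `facilities` and `weights` (list of
#'   `binary` and `stepwise` matrices).
#' @examples
#' fx <- simulated_nine_centers()
#' colSums(fx$centers$size * fx$weights$binary)  # 1500 4250 4000
#' @export
simulated_nine_centers <- function() {
  centers <- data.frame(
    id = paste0("c", 1:9),
    size = c(250, 250, 500, 500, 1000, 500, 1000, 250, 250),
    stringsAsFactors = FALSE)
  facilities <- data.frame(id = paste0("f", 1:3), size = c(1, 3, 2),
                           stringsAsFactors = FALSE)
  dn <- list(centers$id, facilities$id)
  binary <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0,
                     0, 1, 1, 1, 1, 1, 1, 1, 1,
                     0, 0, 1, 1, 1, 1, 1, 1, 1),
                   9, 3, dimnames = dn)
  stepwise <- matrix(
    c(0.242, 0.600, 0.242, 0.600, 0.000, 0.000, 0.000, 0.000, 0.000,
      0.000, 0.242, 0.600, 0.600, 0.600, 0.242, 0.242, 0.600, 0.242,
      0.000, 0.000, 0.242, 0.242, 0.945, 0.600, 0.242, 0.242, 0.242),
    9, 3, dimnames = dn)
  list(centers = centers, facilities = facilities,
       weights = list(binary = binary, stepwise = stepwise))
}

#' Generate a random synthetic scenario
#'
#' Places centers and facilities uniformly at random on a square region
#' and binds them with a planar Euclidean cost matrix. Populations are
#' log-uniform (heavy-tailed, echoing the mix of small and large centers
#' in realistic systems) and supplies are small integers. Reproducible:
#' the same seed yields an identical scenario.
#'
#' @param n_centers,n_facilities counts (>= 1).
#' @param region_size side length of the square region; costs are in the
#'   same units.
#' @param pop_range population range for the log-uniform law (default
#'   100 to 2000).
#' @param supply_range integer supply range (default 1 to 5).
#' @param seed integer seed.
#' @return an [fca_scenario()] with coordinates and Euclidean costs.
#' @examples
#' sc <- random_scenario(6, 4, seed = 42)
#' dim(sc$costs)
#' @export
random_scenario <- function(n_centers, n_facilities, region_size = 60,
                            pop_range = c(100, 2000),
                            supply_range = c(1L, 5L), seed = 1L) {
  stopifnot(n_centers >= 1, n_facilities >= 1, region_size > 0,
            all(pop_range > 0), all(supply_range >= 1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  centers <- data.frame(
    id = sprintf("c%03d", seq_len(n_centers)),
    size = round(exp(stats::runif(n_centers, log(pop_range[1L]),
                                  log(pop_range[2L])))),
    x = stats::runif(n_centers, 0, region_size),
    y = stats::runif(n_centers, 0, region_size),
    stringsAsFactors = FALSE)
  facilities <- data.frame(
    id = sprintf("f%03d", seq_len(n_facilities)),
    size = sample(seq(supply_range[1L], supply_range[2L]), n_facilities,
                  replace = TRUE),
    x = stats::runif(n_facilities, 0, region_size),
    y = stats::runif(n_facilities, 0, region_size),
    stringsAsFactors = FALSE)
  fca_scenario(centers, facilities)
}

#' Export a built-in fixture as CSV files
#'
#' Materializes a fixture (from [toy_two_clinics()] or
#' [simulated_nine_centers()]) as `centers.csv`, `facilities.csv`, the
#' weight matrices as wide CSVs (`weights_binary.csv`,
#' `weights_stepwise.csv`), and a synthetic wide cost matrix
#' `costs_binary.csv` whose entries are 10 minutes inside a binary
#' catchment and blank (unreachable) outside, so that running the command
#' line with `--impedance binary:15` on it reproduces the fixture's
#' binary weights exactly. The cost file is synthetic: the generating
#' distances of the fixtures are not part of the fixture definition.
#'
#' @param fixture list as returned by the fixture constructors.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(dir, "centers.csv")
  utils::write.csv(data.frame(id = fixture$centers$id,
                              population = fixture$centers$size),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "facilities.csv")
  utils::write.csv(data.frame(id = fixture$facilities$id,
                              supply = fixture$facilities$size),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  for (nm in names(fixture$weights)) {
    W <- fixture$weights[[nm]]
    df <- data.frame(origin = rownames(W), W, check.names = FALSE)
    p <- file.path(dir, paste0("weights_", nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  B <- fixture$weights$binary
  costs <- ifelse(B > 0, 10, NA)
  df <- data.frame(origin = rownames(B), costs, check.names = FALSE)
  p <- file.path(dir, "costs_binary.csv")
  utils::write.csv(df, p, row.names = FALSE, na = "")
  paths <- c(paths, p)
  invisible(paths)
}
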