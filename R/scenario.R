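#' Assemble an accessibility scenario
#'
#' A scenario binds together the three inputs every FCA computation needs:
#' a table of population centers (with population counts `P_i`), a table of
#' facilities (with supply counts `S_j`, e.g. physicians per clinic), and
#' the N x J origin-destination travel-cost matrix `d_ij` in minutes.
#' The cost matrix is aligned to the tables: its rows are reordered to the
#' center ids and its columns to the facility ids, and ids present in one
#' but not the other are an error. Unreachable pairs are stored as `Inf`.
#'
#' @param centers,facilities entity data frames as returned by
#'   [read_entities()]: columns `id`, `size`, optionally `x`, `y`.
#' @param costs numeric cost matrix with rownames = center ids and colnames
#'   = facility ids (any order; it is realigned), or `NULL` to compute
#'   planar Euclidean costs from coordinates.
#' @return An object of class `fca_scenario`: a list with elements
#'   `centers`, `facilities` and `costs` (aligned matrix).
#' @examples
#' ctr <- data.frame(id = c("c1", "c2"), size = c(100, 200),
#'                   x = c(0, 1), y = c(0, 0))
#' fac <- data.frame(id = "f1", size = 5, x = 0, y = 1)
#' sc <- fca_scenario(ctr, fac)
#' sc$costs
#' @export
fca_scenario <- function(centers, facilities, costs = NULL) {
  centers <- validate_entities(centers, "centers")
  facilities <- validate_entities(facilities, "facilities")
  if (is.null(costs)) costs <- euclidean_costs(centers, facilities)
  if (!is.matrix(costs) || !is.numeric(costs))
    stop("`costs` must be a numeric matrix")
  if (anyNA(costs) || any(costs < 0))
    stop("costs must be non-negative (use Inf for unreachable pairs)")
  rn <- rownames(costs)
  cn <- colnames(costs)
  if (is.null(rn) || is.null(cn)) {
    if (nrow(costs) != nrow(centers) || ncol(costs) != nrow(facilities))
      stop("unnamed cost matrix must be ", nrow(centers), " x ",
           nrow(facilities))
    dimnames(costs) <- list(centers$id, facilities$id)
  } else {
    rn <- trimws(rn); cn <- trimws(cn)
    if (!setequal(rn, centers$id))
      stop("cost matrix row ids do not match center ids (missing: ",
           paste(setdiff(centers$id, rn), collapse = ", "), ")")
    if (!setequal(cn, facilities$id))
      stop("cost matrix column ids do not match facility ids (missing: ",
           paste(setdiff(facilities$id, cn), collapse = ", "), ")")
    costs <- costs[match(centers$id, rn), match(facilities$id, cn),
                   drop = FALSE]
    dimnames(costs) <- list(centers$id, facilities$id)
  }
  structure(list(centers = centers, facilities = facilities, costs = costs),
            class = "fca_scenario")
}

validate_entities <- function(df, role) {
  if (!is.data.frame(df)) stop("`", role, "` must be a data frame")
  if (!all(c("id", "size") %in% names(df)))
    stop("`", role, "` needs columns `id` and `size`")
  if (nrow(df) == 0L) stop("no entities in `", role, "`")
  df$id <- trimws(as.character(df$id))
  if (any(!nzchar(df$id)))
    stop(role, ": empty id at row ",
         paste(which(!nzchar(df$id)), collapse = ", "))
  if (anyDuplicated(df$id))
    stop(role, ": duplicate id at row ",
         paste(which(duplicated(df$id)), collapse = ", "), " (",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), ")")
  df$size <- as.numeric(df$size)
  bad <- is.na(df$size) | !is.finite(df$size) | df$size < 0
  if (any(bad))
    stop(role, ": size must be a non-negative number; bad row ",
         paste(which(bad), collapse = ", "))
  if ("x" %in% names(df)) df$x <- as.numeric(df$x)
  if ("y" %in% names(df)) df$y <- as.numeric(df$y)
  rownames(df) <- NULL
  df
}

#' Planar Euclidean cost matrix from entity coordinates
#'
#' Convenience for synthetic scenarios; real studies normally supply
#' network travel times instead. Units are those of the coordinates.
#'
#' @param centers,facilities entity data frames carrying `x` and `y`.
#' @return numeric matrix with rownames = center ids, colnames = facility
#'   ids.
#' @examples
#' ctr <- data.frame(id = "c1", size = 1, x = 0, y = 0)
#' fac <- data.frame(id = "f1", size = 1, x = 3, y = 4)
#' euclidean_costs(ctr, fac)  # 5
#' @export
euclidean_costs <- function(centers, facilities) {
  centers <- validate_entities(centers, "centers")
  facilities <- validate_entities(facilities, "facilities")
  for (nm in list(list(centers, "centers"), list(facilities, "facilities"))) {
    df <- nm[[1L]]
    if (!all(c("x", "y") %in% names(df)) || anyNA(df$x) || anyNA(df$y))
      stop(nm[[2L]], " lack complete coordinates; cannot compute distances")
  }
  dx <- outer(centers$x, facilities$x, "-")
  dy <- outer(centers$y, facilities$y, "-")
  out <- sqrt(dx^2 + dy^2)
  dimnames(out) <- list(centers$id, facilities$id)
  out
}

#' @export
print.fca_scenario <- function(x, ...) {
  cat("<fca_scenario> ", nrow(x$centers), " centers (population ",
      format(sum(x$centers$size), big.mark = ","), "), ",
      nrow(x$facilities), " facilities (supply ",
      sum(x$facilities$size), ")\n", sep = "")
  unreach <- sum(!is.finite(x$costs))
  if (unreach > 0)
    cat("  ", unreach, " unreachable origin-destination pairs\n", sep = "")
  invisible(x)
}
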