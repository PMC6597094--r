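#' Read a population-center or facility table from CSV
#'
#' The file must be comma-separated UTF-8 with a header row. Column names
#' are configurable rather than guessed: by default the id column is `id`
#' and the size column is `population` for centers or `supply` for
#' facilities, falling back to `size` if the role-specific name is absent.
#' Optional `x`/`y` columns carry planar coordinates. Row order is
#' preserved; ids are trimmed of surrounding whitespace and must be unique
#' and non-empty; sizes must be finite and non-negative. Violations are
#' reported with the offending row index.
#'
#' @param path CSV file path.
#' @param role `"centers"` or `"facilities"`; picks the default size column.
#' @param id_col,size_col,x_col,y_col column names; `size_col = NULL` uses
#'   the role default.
#' @return data frame with columns `id`, `size` and, when present in the
#'   file, `x` and `y`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,population", "c1,100", "c2,250"), f)
#' read_entities(f, "centers")
#' @export
read_entities <- function(path, role = c("centers", "facilities"),
                          id_col = "id", size_col = NULL,
                          x_col = "x", y_col = "y") {
  role <- match.arg(role)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("no entities in ", path)
  if (is.null(size_col)) {
    cand <- c(if (role == "centers") "population" else "supply", "size")
    size_col <- cand[cand %in% names(df)][1L]
    if (is.na(size_col))
      stop(path, ": no size column; expected one of ",
           paste(cand, collapse = ", "))
  }
  for (col in c(id_col, size_col))
    if (!col %in% names(df))
      stop(path, ": missing required column '", col, "'")
  out <- data.frame(id = trimws(as.character(df[[id_col]])),
                    size = suppressWarnings(as.numeric(df[[size_col]])),
                    stringsAsFactors = FALSE)
  if (x_col %in% names(df) && y_col %in% names(df)) {
    out$x <- as.numeric(df[[x_col]])
    out$y <- as.numeric(df[[y_col]])
  }
  validate_entities(out, role)
}

#' Read an origin-destination cost matrix from CSV
#'
#' Two layouts are supported. `wide`: the first column holds the origin
#' (center) id and every remaining column is named for a facility id and
#' holds costs in minutes. `long`: three columns (origin, destination,
#' cost), one row per pair. In either layout the result is a dense N x J
#' matrix aligned to the supplied id orders. Pairs absent from a long file
#' are unreachable (`Inf`): they fall outside every catchment and get
#' weight 0 under any impedance — they are *not* cost 0, which would mean
#' maximal weight.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param origin_ids,dest_ids ordered center and facility ids the matrix
#'   must align to.
#' @param origin_col,dest_col,cost_col column names for the long layout.
#' @return numeric matrix (rownames = `origin_ids`, colnames = `dest_ids`)
#'   with `Inf` marking unreachable pairs.
#' @export
read_cost_matrix <- function(path, layout = c("wide", "long"),
                             origin_ids, dest_ids,
                             origin_col = "origin", dest_col = "destination",
                             cost_col = "cost") {
  layout <- match.arg(layout)
  origin_ids <- trimws(as.character(origin_ids))
  dest_ids <- trimws(as.character(dest_ids))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("no rows in cost file ", path)
  out <- matrix(Inf, length(origin_ids), length(dest_ids),
                dimnames = list(origin_ids, dest_ids))
  if (layout == "wide") {
    o <- trimws(as.character(df[[1L]]))
    dcols <- trimws(names(df)[-1L])
    check_known(o, origin_ids, path, "origin")
    check_known(dcols, dest_ids, path, "destination column")
    if (anyDuplicated(o))
      stop(path, ": duplicate origin rows: ",
           paste(unique(o[duplicated(o)]), collapse = ", "))
    raw <- as.matrix(df[, -1L, drop = FALSE])
    vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
    blank <- is.na(raw) | trimws(raw) == ""
    if (any(is.na(vals) & !blank))
      stop(path, ": non-numeric cost at row ",
           which(rowSums(is.na(vals) & !blank) > 0)[1L])
    vals[blank] <- Inf  # blank cells mean unreachable
    if (any(vals < 0)) stop(path, ": negative cost")
    out[match(o, origin_ids), match(dcols, dest_ids)] <- vals
  } else {
    for (col in c(origin_col, dest_col, cost_col))
      if (!col %in% names(df))
        stop(path, ": missing required column '", col, "'")
    o <- trimws(as.character(df[[origin_col]]))
    d <- trimws(as.character(df[[dest_col]]))
    check_known(o, origin_ids, path, "origin")
    check_known(d, dest_ids, path, "destination")
    key <- paste(o, d, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- which(duplicated(key))[1L]
      stop(path, ": duplicate pair (", o[dup], ", ", d[dup], ") at row ", dup)
    }
    cost <- suppressWarnings(as.numeric(df[[cost_col]]))
    bad <- which(is.na(cost) | cost < 0)
    if (length(bad))
      stop(path, ": non-numeric or negative cost at row ",
           paste(bad, collapse = ", "))
    out[cbind(match(o, origin_ids), match(d, dest_ids))] <- cost
  }
  out
}

check_known <- function(found, known, path, what) {
  unknown <- setdiff(found, known)
  if (length(unknown))
    stop(path, ": unknown ", what, " id(s): ",
         paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Write FCA results to CSV (and optionally GeoJSON)
#'
#' Writes up to four files into `dir`:
#' \describe{
#'   \item{`centers.csv`}{id, population, accessibility (reporting scale),
#'     and disparity/SPAR columns when a disparity table is supplied.}
#'   \item{`facilities.csv`}{id, supply, demand, level_of_service
#'     (reporting scale).}
#'   \item{`allocation.csv`}{long table (center, facility, demand,
#'     service) of the disaggregated allocations; only when
#'     `allocation = TRUE`.}
#'   \item{`centers.geojson`}{point features with the per-center results as
#'     properties; only when `geojson = TRUE` and coordinates exist (a
#'     warning is issued and the file skipped otherwise).}
#' }
#' Numbers are written with 6 significant digits by default; full precision
#' is always retained in the in-memory objects.
#'
#' @param result an [fca_result][fca_run] object.
#' @param dir output directory (created if needed).
#' @param disparity optional [disparity()] table to merge into the
#'   per-center file.
#' @param allocation write the long allocation table?
#' @param geojson write per-center GeoJSON points?
#' @param digits significant digits for file output.
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, dir, disparity = NULL,
                          allocation = FALSE, geojson = FALSE, digits = 6) {
  stopifnot(inherits(result, "fca_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) signif(x, digits)
  sc <- result$scale
  paths <- character()

  ctr <- data.frame(id = result$centers$id,
                    population = result$centers$size,
                    accessibility = fmt(result$accessibility * sc))
  if (!is.null(disparity)) {
    stopifnot(nrow(disparity) == nrow(ctr))
    if ("disparity" %in% names(disparity))
      ctr$disparity <- fmt(disparity$disparity * sc)
    if ("spar" %in% names(disparity))
      ctr$spar <- fmt(disparity$spar)
  }
  p <- file.path(dir, "centers.csv")
  utils::write.csv(ctr, p, row.names = FALSE)
  paths <- c(paths, p)

  fac <- data.frame(id = result$facilities$id,
                    supply = result$facilities$size,
                    demand = fmt(result$demand$facility_demand),
                    level_of_service = fmt(result$los$los * sc))
  p <- file.path(dir, "facilities.csv")
  utils::write.csv(fac, p, row.names = FALSE)
  paths <- c(paths, p)

  if (allocation) {
    al <- expand.grid(center = result$centers$id,
                      facility = result$facilities$id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    al$demand <- fmt(as.vector(result$demand$pair_demand))
    al$service <- fmt(as.vector(result$allocation * sc))
    p <- file.path(dir, "allocation.csv")
    utils::write.csv(al, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  if (geojson) {
    if (is.null(result$centers$x) || anyNA(result$centers$x)) {
      warning("scenario has no center coordinates; GeoJSON skipped")
    } else {
      feats <- lapply(seq_len(nrow(ctr)), function(i) {
        props <- as.list(ctr[i, , drop = FALSE])
        list(type = "Feature",
             geometry = list(type = "Point",
                             coordinates = c(result$centers$x[i],
                                             result$centers$y[i])),
             properties = props)
      })
      p <- file.path(dir, "centers.geojson")
      jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                           p, auto_unbox = TRUE, digits = NA)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
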