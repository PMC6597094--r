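#' Row- and column-standardize an impedance weight matrix
#'
#' Standardization is the core adjustment behind the balanced FCA method:
#' dividing each weight by its row sum (`row_standardize`) makes every
#' covered population center allocate exactly 100% of its population across
#' the facilities it can reach, and dividing by column sums
#' (`column_standardize`) makes every patronized facility allocate exactly
#' 100% of its level of service across the centers it can serve. The same
#' operation is familiar from spatial statistics as row/column
#' standardization of a spatial weights matrix.
#'
#' Rows (or columns) whose weights are all zero — centers outside every
#' catchment, or facilities with no population in reach — are returned as
#' zero and recorded in the `"uncovered"` attribute; this is a legitimate
#' state of a suboptimally configured system, not an error.
#'
#' Slack factors deliberately break the exact 100% allocation: a demand
#' slack of 1.10 on a center inflates its allocated demand by 10%, a supply
#' slack of 0.9 on a facility deflates its allocated service by 10%. Slack
#' is applied multiplicatively after normalization, so row `i` of a
#' row-standardized matrix sums to its slack factor.
#'
#' @param W numeric weight matrix (N centers x J facilities), entries >= 0.
#' @param slack optional positive slack factors: a single number recycled to
#'   every row (column), or a vector of length N (J). Default 1 (exact
#'   proportional allocation).
#' @return The standardized matrix, of class `fca_std_weights`, with
#'   attributes `orientation` (`"row"` or `"column"`), `slack_applied`
#'   (logical) and `uncovered` (ids or indices of all-zero rows/columns).
#' @examples
#' W <- matrix(c(0.8, 0.8, 0.4, 0.8, 0.4, 0.8), nrow = 3)
#' row_standardize(W)     # rows sum to 1
#' column_standardize(W)  # columns sum to 1
#' @export
row_standardize <- function(W, slack = NULL) {
  W <- check_weights(W)
  slack <- check_slack(slack, nrow(W), "demand")
  s <- rowSums(W)
  covered <- s > 0
  out <- W
  out[covered, ] <- (slack[covered] / s[covered]) * W[covered, , drop = FALSE]
  structure(out,
            orientation = "row",
            slack_applied = !is.null(attr(slack, "explicit")),
            uncovered = margin_ids(W, 1L)[!covered],
            class = c("fca_std_weights", class(out)))
}

#' @rdname row_standardize
#' @export
column_standardize <- function(W, slack = NULL) {
  W <- check_weights(W)
  slack <- check_slack(slack, ncol(W), "supply")
  s <- colSums(W)
  covered <- s > 0
  out <- W
  out[, covered] <- sweep(W[, covered, drop = FALSE], 2L,
                          slack[covered] / s[covered], "*")
  structure(out,
            orientation = "column",
            slack_applied = !is.null(attr(slack, "explicit")),
            uncovered = margin_ids(W, 2L)[!covered],
            class = c("fca_std_weights", class(out)))
}

check_weights <- function(W) {
  if (inherits(W, "fca_std_weights")) {
    # standardization is idempotent, so accepting one is harmless; method
    # pipelines nevertheless always standardize the raw impedance weights
    attributes(W) <- attributes(W)[c("dim", "dimnames")]
  }
  if (!is.matrix(W) || !is.numeric(W))
    stop("`W` must be a numeric matrix")
  if (anyNA(W) || any(W < 0) || any(!is.finite(W)))
    stop("weights must be finite and non-negative")
  W
}

check_slack <- function(slack, n, what) {
  if (is.null(slack)) return(rep(1, n))
  if (!is.numeric(slack) || anyNA(slack) || any(slack <= 0))
    stop(what, " slack factors must be positive numbers")
  if (length(slack) == 1L) slack <- rep(slack, n)
  if (length(slack) != n)
    stop(what, " slack must have length 1 or ", n, ", got ", length(slack))
  structure(as.numeric(slack), explicit = TRUE)
}

margin_ids <- function(W, margin) {
  nm <- dimnames(W)[[margin]]
  if (is.null(nm)) seq_len(dim(W)[margin]) else nm
}

#' Read slack factors from a CSV file of (id, factor) pairs
#'
#' @param path CSV with columns `id` and `factor` (names configurable).
#' @param ids ordered ids of the rows (centers) or columns (facilities) the
#'   factors apply to; ids absent from the file default to 1.
#' @param id_col,factor_col column names in the file.
#' @return numeric vector of slack factors aligned to `ids`.
#' @export
read_slack <- function(path, ids, id_col = "id", factor_col = "factor") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c(id_col, factor_col) %in% names(df)))
    stop("slack file must have columns '", id_col, "' and '", factor_col, "'")
  key <- trimws(as.character(df[[id_col]]))
  if (anyDuplicated(key))
    stop("duplicate ids in slack file: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  unknown <- setdiff(key, ids)
  if (length(unknown))
    stop("slack file mentions unknown ids: ", paste(unknown, collapse = ", "))
  out <- rep(1, length(ids))
  out[match(key, ids)] <- as.numeric(df[[factor_col]])
  if (anyNA(out) || any(out <= 0)) stop("slack factors must be positive")
  out
}
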