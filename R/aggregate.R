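# Marginal-mean aggregation of cross-validation score grids.
#
# A score grid has one row per feature and one column per classifier (or per
# metric, or per metric x line-speed). Reports add row means, column means,
# per-block column subtotals (e.g. sideview image features vs instrumental
# features) and a grand mean; every marginal is the plain arithmetic mean of
# its constituent cells. Values are kept unrounded internally and rendered
# to 3 decimals (ties rounded half up).

#' Aggregate a grid of cross-validation scores into a report
#'
#' @param cells a data frame in long form with columns `row` (feature),
#'   `col` (classifier/metric), `value`, and optionally `block` (a grouping
#'   of rows used for subtotal rows). Every `row` x `col` combination must
#'   appear exactly once.
#' @return an object of class `aggregate_report`: `cells` (the value
#'   matrix), `row_means`, `col_means`, `block_col_means` (matrix, one row
#'   per block; `NULL` without blocks), `grand_mean`, `blocks`. Values are
#'   unrounded; `print()` renders them to 3 decimals.
#' @examples
#' cells <- expand.grid(row = c("f1", "f2"), col = c("A", "B"))
#' cells$value <- c(0.9, 0.8, 0.7, 0.6)
#' aggregate_report(cells)
#' @export
aggregate_report <- function(cells) {
  if (!is.data.frame(cells) ||
      !all(c("row", "col", "value") %in% names(cells))) {
    stop_invalid("`cells` must be a data frame with row, col, value columns")
  }
  rows <- unique(as.character(cells$row))
  colsv <- unique(as.character(cells$col))
  tabcount <- table(factor(as.character(cells$row), rows),
                    factor(as.character(cells$col), colsv))
  if (any(tabcount != 1L)) {
    stop_incomplete("every row x col combination must appear exactly once")
  }
  m <- matrix(NA_real_, length(rows), length(colsv),
              dimnames = list(rows, colsv))
  m[cbind(as.character(cells$row), as.character(cells$col))] <- cells$value
  blocks <- NULL
  block_col_means <- NULL
  if ("block" %in% names(cells)) {
    bl <- unique(cells[, c("row", "block")])
    if (nrow(bl) != length(rows)) {
      stop_incomplete("each row must belong to exactly one block")
    }
    blocks <- stats::setNames(as.character(bl$block), as.character(bl$row))
    ub <- unique(blocks)
    block_col_means <- matrix(NA_real_, length(ub), length(colsv),
                              dimnames = list(ub, colsv))
    for (b in ub) {
      block_col_means[b, ] <- colMeans(m[blocks == b, , drop = FALSE])
    }
  }
  structure(list(
    cells = m,
    row_means = rowMeans(m),
    col_means = colMeans(m),
    block_col_means = block_col_means,
    grand_mean = mean(m),
    blocks = blocks
  ), class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, digits = 3, ...) {
  fmt <- function(v) sprintf(paste0("%.", digits, "f"), round_half_up(v, digits))
  m <- cbind(x$cells, MEAN = x$row_means)
  body <- apply(m, c(1, 2), fmt)
  if (!is.null(x$block_col_means)) {
    out <- NULL
    for (b in rownames(x$block_col_means)) {
      rows_b <- names(x$blocks)[x$blocks == b]
      out <- rbind(out, body[rows_b, , drop = FALSE],
                   `Avg. subtotal` = c(fmt(x$block_col_means[b, ]), ""))
      rownames(out)[nrow(out)] <- paste0("Avg. subtotal (", b, ")")
    }
    body <- out
  }
  body <- rbind(body,
                `Average total` = c(fmt(x$col_means), fmt(x$grand_mean)))
  print(noquote(body))
  invisible(x)
}

#' Render report marginals rounded for publication-style tables
#'
#' @param report an [aggregate_report()].
#' @param digits decimals (default 3, ties half up).
#' @return a list with rounded `row_means`, `col_means`, `block_col_means`
#'   and `grand_mean`.
#' @export
report_marginals <- function(report, digits = 3) {
  stopifnot(inherits(report, "aggregate_report"))
  list(
    row_means = round_half_up(report$row_means, digits),
    col_means = round_half_up(report$col_means, digits),
    block_col_means = if (!is.null(report$block_col_means))
      round_half_up(report$block_col_means, digits),
    grand_mean = round_half_up(report$grand_mean, digits)
  )
}
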