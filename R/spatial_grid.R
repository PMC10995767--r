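#' Construct a spatial grid of spots
#'
#' Builds the neighbor graph over array coordinates. For `hex` layouts
#' (Visium-style interleaved columns) two spots are neighbors iff
#' `|drow| <= 1` with `|dcol| == 2` on the same row and `|dcol| == 1` on
#' adjacent rows, which yields the standard 6-neighbor hexagonal topology.
#' For `square` layouts neighbors are the 4 rook-adjacent spots.
#'
#' @param spots data.frame with columns `spot_id`, `array_row`, `array_col`
#'   and optionally `in_tissue` (defaults to 1).
#' @param layout `"hex"` or `"square"`.
#' @return object of class `SpatialGrid`: list with `spots` (data.frame),
#'   `layout`, and `adjacency` (list of integer neighbor indices, symmetric
#'   and irreflexive).
#' @export
spatial_grid <- function(spots, layout = c("hex", "square")) {
  layout <- match.arg(layout)
  need <- c("spot_id", "array_row", "array_col")
  miss <- setdiff(need, names(spots))
  if (length(miss)) stop("spots table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(spots$spot_id))
    stop("duplicated spot ids: ",
         paste(unique(spots$spot_id[duplicated(spots$spot_id)]),
               collapse = ", "))
  if (is.null(spots$in_tissue)) spots$in_tissue <- 1L
  n <- nrow(spots)
  key <- paste(spots$array_row, spots$array_col, sep = ",")
  if (anyDuplicated(key)) stop("duplicated array coordinates")
  idx <- stats::setNames(seq_len(n), key)

  offsets <- if (layout == "hex") {
    rbind(c(0, -2), c(0, 2), c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    rbind(c(0, -1), c(0, 1), c(-1, 0), c(1, 0))
  }
  adjacency <- vector("list", n)
  for (i in seq_len(n)) {
    nb_key <- paste(spots$array_row[i] + offsets[, 1],
                    spots$array_col[i] + offsets[, 2], sep = ",")
    hits <- idx[nb_key]
    adjacency[[i]] <- sort(unname(hits[!is.na(hits)]))
  }
  structure(list(spots = spots, layout = layout, adjacency = adjacency),
            class = "SpatialGrid")
}

#' @export
print.SpatialGrid <- function(x, ...) {
  cat(sprintf("SpatialGrid (%s): %d spots, %d edges\n", x$layout,
              nrow(x$spots), sum(lengths(x$adjacency)) / 2))
  invisible(x)
}

#' Build a full rectangular grid of spots
#'
#' Convenience constructor used by the simulators: a `nrow x ncol` array of
#' spots. For hex layouts, columns follow the Visium convention where the
#' column parity matches the row parity, so each row holds `ncol` spots at
#' array columns `row%%2, row%%2 + 2, ...`.
#'
#' @param n_rows,n_cols grid dimensions in spots.
#' @param layout `"hex"` or `"square"`.
#' @return a `SpatialGrid`.
#' @export
make_grid <- function(n_rows, n_cols, layout = c("hex", "square")) {
  layout <- match.arg(layout)
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)
  cols <- if (layout == "hex") {
    as.integer(2L * (rep(seq_len(n_cols), n_rows) - 1L) + rows %% 2L)
  } else {
    rep(seq_len(n_cols) - 1L, n_rows)
  }
  spots <- data.frame(spot_id = sprintf("spot_%04d", seq_along(rows)),
                      array_row = rows, array_col = cols,
                      in_tissue = 1L, stringsAsFactors = FALSE)
  spatial_grid(spots, layout)
}
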