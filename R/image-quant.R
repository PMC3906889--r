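# Quantification of arrayed spot cultures from time-lapse plate images.
# Each spot is measured as the summed pixel intensity in a square window
# (side 0.9 x pitch) centered on its nominal grid position, minus a local
# background estimate (median of inter-spot pixels) times the window area.

# integer pixel window of a grid cell; clipped to frame bounds
.cellWindow <- function(stack, row, col, dims) {
  half <- (0.9 * stack@pitch) / 2
  cr <- stack@originRow + row * stack@pitch
  cc <- stack@originCol + col * stack@pitch
  list(
    rows = max(1L, ceiling(cr - half)):min(dims[1L], floor(cr + half)),
    cols = max(1L, ceiling(cc - half)):min(dims[2L], floor(cc + half))
  )
}

#' Quantify every spot of a plate image stack
#'
#' For each frame and each grid cell, measures the background-subtracted
#' density: the sum of pixel intensities inside the cell's window minus the
#' frame's background level (median intensity of all pixels outside every
#' cell window) times the window area. Deterministic; densities can be
#' slightly negative only through background noise.
#'
#' @param stack a [PlateStack].
#' @return data.frame with columns `row`, `col` (0-based grid coordinates),
#'   `time` (hours) and `density`.
#' @export
quantifyStack <- function(stack) {
  stopifnot(is(stack, "PlateStack"))
  validObject(stack)
  dims <- dim(stack@frames[[1L]])

  inWindow <- matrix(FALSE, dims[1L], dims[2L])
  cells <- vector("list", stack@gridRows * stack@gridCols)
  i <- 0L
  for (row in seq_len(stack@gridRows) - 1L) {
    for (col in seq_len(stack@gridCols) - 1L) {
      w <- .cellWindow(stack, row, col, dims)
      inWindow[w$rows, w$cols] <- TRUE
      i <- i + 1L
      cells[[i]] <- list(row = row, col = col, w = w)
    }
  }
  if (all(inWindow))
    stop("grid windows cover the whole frame; no inter-spot background region")

  out <- vector("list", length(stack@frames))
  for (f in seq_along(stack@frames)) {
    frame <- stack@frames[[f]]
    bg <- stats::median(frame[!inWindow])
    dens <- vapply(cells, function(cell) {
      sub <- frame[cell$w$rows, cell$w$cols]
      sum(sub) - bg * length(sub)
    }, numeric(1))
    out[[f]] <- data.frame(
      row = vapply(cells, `[[`, integer(1), "row"),
      col = vapply(cells, `[[`, integer(1), "col"),
      time = stack@frameTimes[f],
      density = dens
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract one spot's growth time series
#'
#' Pulls a single grid cell's density trajectory out of a [quantifyStack]
#' measurement table, ready for [fitLogistic].
#'
#' @param measurements data.frame from [quantifyStack].
#' @param row,col 0-based grid coordinates of the spot.
#' @param cultureId identifier for the resulting series; defaults to
#'   `"r<row>c<col>"`.
#' @return a [CultureSeries].
#' @export
toTimeSeries <- function(measurements, row, col,
                         cultureId = sprintf("r%dc%d", row, col)) {
  sel <- measurements$row == row & measurements$col == col
  if (!any(sel))
    stop("no measurements for grid cell (", row, ", ", col, ")")
  sub <- measurements[sel, , drop = FALSE]
  sub <- sub[order(sub$time), , drop = FALSE]
  allTimes <- sort(unique(measurements$time))
  missing <- setdiff(allTimes, sub$time)
  if (length(missing))
    stop("cell (", row, ", ", col, ") is missing frames at t = ",
         paste(signif(missing, 6), collapse = ", "))
  CultureSeries(cultureId, sub$time, sub$density)
}
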