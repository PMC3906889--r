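# Per-strain interaction plots: the raw L-vs-dose response against the
# reference band (left), and the same data with the reference dose effect
# removed so only the interaction remains (right).

#' Plot a strain's dose response against the reference
#'
#' Two panels: the raw fitted `L` per dose over the reference central-95%
#' band, and the dose-effect-removed view (`Y_i - RD_i`, shifted so the
#' zero-dose point sits at the knockout effect `K0`) with the fitted
#' quadratic.
#'
#' @param dr a [DoseResponse].
#' @param ref a [ReferenceModel].
#' @param res optional scored [InteractionResult] for the quadratic overlay.
#' @param file optional PNG path; when given the plot is written there
#'   (requires the `png`-capable `grDevices`).
#' @return invisibly, `NULL`.
#' @export
plotInteraction <- function(dr, ref, res = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 450)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)

  D <- doses(ref)
  band <- referenceBand(ref)
  ylim <- range(c(band, lValues(dr)), na.rm = TRUE)
  plot(D, centralL(ref), type = "l", lwd = 2, col = "gray40", ylim = ylim,
       xlab = "oligomycin (ug/mL)", ylab = "L (h)", main = "raw response")
  graphics::polygon(c(D, rev(D)), c(band["low", ], rev(band["high", ])),
                    col = grDevices::adjustcolor("gray", 0.4), border = NA)
  graphics::points(doses(dr), lValues(dr), pch = 19, col = "steelblue")

  Ki <- lValues(dr) - centralL(ref)
  plot(doses(dr), Ki, pch = 19, col = "steelblue",
       xlab = "oligomycin (ug/mL)", ylab = "L - reference (h)",
       main = "dose effect removed")
  graphics::abline(h = 0, col = "gray60", lty = 2)
  if (!is.null(res) && !anyNA(quadCoef(res))) {
    cf <- quadCoef(res)
    dd <- seq(0, max(D), length.out = 100)
    graphics::lines(dd, orfEffect(res) + cf["A"] + cf["B"] * dd +
                      cf["C"] * dd^2, col = "firebrick", lwd = 2)
  }
  invisible(NULL)
}

#' Write plate frames as grayscale PNG images
#'
#' @param stack a [PlateStack].
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
writePlateFrames <- function(stack, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing plate frames requires the 'png' package")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  top <- max(vapply(frames(stack), max, numeric(1)), 1)
  paths <- character(length(frames(stack)))
  for (i in seq_along(frames(stack))) {
    paths[i] <- file.path(dir, sprintf("frame_%03d.png", i))
    png::writePNG(pmin(frames(stack)[[i]] / top, 1), paths[i])
  }
  invisible(paths)
}
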