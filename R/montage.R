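# Electrode montages. Two deterministic layouts:
#  - "ten-ten-subset": an idealised spherical 10-10 layout with standard
#    nomenclature, rows Fp..O on anterior-posterior arcs, columns z,1..8
#    laterally; suits label-aware work and the CSD spline.
#  - "fibonacci-sphere": golden-angle spiral over the upper hemisphere-ish
#    cap; suits montage-agnostic numerical tests.

# Ordered 10-10 rows: anterior-posterior angle from vertex (deg, + = front)
.tenTenRows <- list(
  Fp = list(angle = 72, cols = c("1", "z", "2")),
  AF = list(angle = 54, cols = c("7", "3", "z", "4", "8")),
  F  = list(angle = 36, cols = c("7", "5", "3", "1", "z", "2", "4", "6", "8")),
  FC = list(angle = 18, cols = c("T7", "5", "3", "1", "z", "2", "4", "6", "T8")),
  C  = list(angle = 0,  cols = c("T7", "5", "3", "1", "z", "2", "4", "6", "T8")),
  CP = list(angle = -18, cols = c("T7", "5", "3", "1", "z", "2", "4", "6", "T8")),
  P  = list(angle = -36, cols = c("7", "5", "3", "1", "z", "2", "4", "6", "8")),
  PO = list(angle = -54, cols = c("7", "3", "z", "4", "8")),
  O  = list(angle = -72, cols = c("1", "z", "2"))
)

.lateralFraction <- c(z = 0, "1" = 0.2, "2" = 0.2, "3" = 0.4, "4" = 0.4,
                      "5" = 0.6, "6" = 0.6, "7" = 0.8, "8" = 0.8)

.tenTenTable <- function() {
  rows <- lapply(names(.tenTenRows), function(rn) {
    r <- .tenTenRows[[rn]]
    cols <- r$cols
    out <- data.frame(label = character(length(cols)), ap = r$angle,
                      lat = 0, stringsAsFactors = FALSE)
    for (i in seq_along(cols)) {
      cc <- cols[i]
      if (cc %in% c("T7", "T8")) {
        # temporal line labels replace row prefix in the 7/8 columns
        base <- switch(rn, FC = "FT", C = "T", CP = "TP", rn)
        out$label[i] <- paste0(base, substring(cc, 2))
        side <- if (cc == "T7") -1 else 1
        out$lat[i] <- side * 0.8
      } else if (cc == "z") {
        out$label[i] <- paste0(rn, "z")
        out$lat[i] <- 0
      } else {
        out$label[i] <- paste0(rn, cc)
        side <- if (as.integer(cc) %% 2 == 1) -1 else 1
        out$lat[i] <- side * .lateralFraction[[cc]]
      }
    }
    out
  })
  do.call(rbind, rows)
}

.tenTenPositions <- function(tab) {
  ap <- tab$ap * pi / 180
  lam <- tab$lat * 112.5 * pi / 180   # column 8 at C row reaches the rim
  # midline point at AP angle, rotated about the anterior-posterior (y) axis
  x <- cos(ap) * sin(lam)
  y <- sin(ap)
  z <- cos(ap) * cos(lam)
  p <- cbind(x, y, z)
  p / sqrt(rowSums(p^2))
}

#' Build a deterministic electrode montage
#'
#' `"ten-ten-subset"` lays out electrodes on an idealised sphere with
#' standard 10-10 labels (midline and lateral chains Fp through O, 61
#' positions available); `"fibonacci-sphere"` distributes points by the
#' golden-angle spiral over the superior two thirds of the sphere and labels
#' them `E1..En`. Both layouts are deterministic functions of their
#' arguments.
#'
#' @param nChannels number of electrodes (>= 16).
#' @param scheme `"ten-ten-subset"` or `"fibonacci-sphere"`.
#' @return a [Montage-class].
#' @examples
#' m <- makeMontage(60)
#' channelLabels(m)[1:6]
#' @export
makeMontage <- function(nChannels = 60,
                        scheme = c("ten-ten-subset", "fibonacci-sphere")) {
  scheme <- match.arg(scheme)
  if (nChannels < 16)
    stop("montages below 16 channels are not supported")
  if (scheme == "ten-ten-subset") {
    tab <- .tenTenTable()
    if (nChannels > nrow(tab))
      stop("ten-ten-subset supports at most ", nrow(tab), " channels")
    # shed outer-ring/midline extras first so 60 keeps the main chains
    dropFirst <- c("AFz", "POz", "AF7", "AF8", "PO7", "PO8", "AF3", "AF4",
                   "PO3", "PO4", "Fpz", "Oz", "F5", "F6", "C5", "C6",
                   "P5", "P6", "CP5", "CP6", "FC5", "FC6", "F1", "F2",
                   "C1", "C2", "P1", "P2", "CP1", "CP2", "FC1", "FC2",
                   "FT7", "FT8", "TP7", "TP8", "Fp1", "Fp2", "O1", "O2",
                   "F3", "F4", "CP3", "CP4", "FC3", "FC4")
    rank <- match(tab$label, rev(dropFirst))
    rank[is.na(rank)] <- 0L
    keep <- sort(utils::head(order(rank, seq_len(nrow(tab))), nChannels))
    tab <- tab[keep, , drop = FALSE]
    new("Montage", labels = tab$label, positions = .tenTenPositions(tab))
  } else {
    i <- seq_len(nChannels)
    # cap: z from 1 down to -0.35, golden-angle azimuth
    zc <- 1 - (i - 0.5) / nChannels * 1.35
    phi <- (i - 1) * pi * (3 - sqrt(5))
    r <- sqrt(pmax(0, 1 - zc^2))
    p <- cbind(r * cos(phi), r * sin(phi), zc)
    p <- p / sqrt(rowSums(p^2))
    new("Montage", labels = paste0("E", i), positions = p)
  }
}
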