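#' Extended 10-20 montage on a spherical head model
#'
#' Builds the default 16-site extended 10-20 scalp montage used by the
#' mobile recording setup, plus the two mastoid sites (M1/M2, below the
#' equatorial plane of the spherical head model), the left infra-orbital EOG
#' channel (LVEOG) and the vertex reference position (CZ).  Positions are
#' unit vectors on a spherical head model with the x axis through the nasion,
#' y to the left pre-auricular point and z through the vertex.
#'
#' @param labels Optional character vector restricting the scalp sites kept
#'   (M1, M2, LVEOG and CZ are always retained; FZ and OZ, the analysis
#'   electrodes, must be present).
#' @return A data frame of class `qeeg_montage` with columns `label`, `x`,
#'   `y`, `z` and `type` (`"eeg"`, `"mastoid"`, `"eog"` or `"reference"`).
#' @examples
#' mon <- qeeg_montage()
#' subset(mon, label %in% c("FZ", "OZ"))
#' @export
qeeg_montage <- function(labels = NULL) {
  # (inclination from vertex, azimuth from nasion, +ve to the left), degrees
  ang <- rbind(
    FP1   = c( 92,   18), FP2 = c( 92,  -18),
    F7    = c( 92,   54), F8  = c( 92,  -54),
    F3    = c( 60,   39), F4  = c( 60,  -39),
    FZ    = c( 46,    0),
    T7    = c( 92,   90), T8  = c( 92,  -90),
    C3    = c( 46,   90), C4  = c( 46,  -90),
    P3    = c( 60,  141), P4  = c( 60, -141),
    PZ    = c( 46,  180),
    O1    = c( 92,  162),
    OZ    = c( 92,  180),
    M1    = c(115,  108), M2  = c(115, -108),
    LVEOG = c(115,   18),
    CZ    = c(  0,    0))
  incl <- ang[, 1] * pi / 180
  az   <- ang[, 2] * pi / 180
  mon <- data.frame(
    label = rownames(ang),
    x = sin(incl) * cos(az),
    y = sin(incl) * sin(az),
    z = cos(incl),
    type = "eeg",
    stringsAsFactors = FALSE)
  mon$type[mon$label %in% c("M1", "M2")] <- "mastoid"
  mon$type[mon$label == "LVEOG"] <- "eog"
  mon$type[mon$label == "CZ"] <- "reference"
  if (!is.null(labels)) {
    keep <- mon$type != "eeg" | mon$label %in% labels
    miss <- setdiff(labels, mon$label)
    if (length(miss))
      stop("unknown montage labels: ", paste(miss, collapse = ", "))
    mon <- mon[keep, , drop = FALSE]
  }
  rownames(mon) <- NULL
  class(mon) <- c("qeeg_montage", "data.frame")
  validate_montage(mon)
  mon
}

validate_montage <- function(mon) {
  stopifnot(is.data.frame(mon),
            all(c("label", "x", "y", "z", "type") %in% names(mon)))
  if (anyDuplicated(mon$label))
    stop("montage labels must be unique")
  nrm <- sqrt(mon$x^2 + mon$y^2 + mon$z^2)
  if (any(abs(nrm - 1) > 1e-9))
    stop("montage positions must lie on the unit sphere")
  for (need in c("FZ", "OZ"))
    if (!need %in% mon$label)
      stop("analysis electrode ", need, " missing from montage")
  invisible(mon)
}

montage_positions <- function(mon, labels) {
  idx <- match(labels, mon$label)
  if (anyNA(idx))
    stop("channels absent from montage: ",
         paste(labels[is.na(idx)], collapse = ", "))
  as.matrix(mon[idx, c("x", "y", "z")])
}

#' Default frequency band definitions
#'
#' Theta 4-7 Hz, alpha 8-13 Hz and low beta 14-20 Hz, with inclusive edges at
#' the 1 Hz bin resolution implied by 1-second epochs.
#'
#' @return Named list of `c(lo, hi)` Hz pairs.
#' @export
default_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 13), beta = c(14, 20))
}

validate_bands <- function(bands) {
  stopifnot(is.list(bands), length(bands) >= 1, !is.null(names(bands)))
  for (b in bands)
    if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2])
      stop("each band must be c(lo, hi) with lo < hi")
  edges <- t(vapply(bands, identity, numeric(2)))
  o <- order(edges[, 1])
  if (any(edges[o, 1][-1] <= edges[o, 2][-length(bands)]))
    stop("bands must be non-overlapping")
  invisible(bands)
}
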