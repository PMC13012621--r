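#' Integer label mask of flat clathrin lattices
#'
#' A 2-D grid of non-negative integers: 0 is background, each positive
#' label one pre-segmented lattice region (labels are authoritative; no
#' re-segmentation is performed).
#'
#' @param grid integer matrix.
#' @param pixel_size pixel edge in um.
#' @return an object of class `fcl_mask`.
#' @export
label_mask <- function(grid, pixel_size) {
  if (!is.matrix(grid)) stop("grid must be a matrix")
  if (any(!is.finite(grid)) || any(grid < 0) ||
      any(grid != round(grid))) {
    stop("mask labels must be non-negative integers")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be positive (um/pixel)")
  }
  structure(list(grid = matrix(as.integer(grid), nrow(grid), ncol(grid)),
                 pixel_size = pixel_size),
            class = "fcl_mask")
}

#' Read a label mask from a headerless CSV integer grid
#'
#' @param file path to a CSV file of integers (rows = image rows).
#' @param pixel_size pixel edge in um (never inferred from the file).
#' @return an [label_mask()].
#' @export
read_mask_csv <- function(file, pixel_size) {
  g <- as.matrix(utils::read.csv(file, header = FALSE))
  dimnames(g) <- NULL
  label_mask(g, pixel_size)
}

#' Read an integer-labeled TIFF mask
#'
#' @inheritParams read_mask_csv
#' @return an [label_mask()].
#' @export
read_mask_tiff <- function(file, pixel_size) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF masks requires the 'tiff' package")
  }
  g <- tiff::readTIFF(file, as.is = TRUE)
  if (length(dim(g)) == 3) g <- g[, , 1]
  label_mask(round(g), pixel_size)
}

#' Per-lattice records of a label mask
#'
#' One record per distinct non-zero label: pixel-count area and the
#' centroid of the pixel centers. Pixel (i, j) (row, column) has center
#' `x = (j - 0.5) px`, `y = (i - 0.5) px`.
#'
#' @param mask an [label_mask()].
#' @return data.frame with `label`, `x`, `y` (um) and `area` (um^2).
#' @export
fcl_records <- function(mask) {
  stopifnot(inherits(mask, "fcl_mask"))
  g <- mask$grid
  px <- mask$pixel_size
  idx <- which(g > 0)
  if (length(idx) == 0) {
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0)))
  }
  lab <- g[idx]
  ri <- ((idx - 1) %% nrow(g)) + 1
  ci <- ((idx - 1) %/% nrow(g)) + 1
  xs <- (ci - 0.5) * px
  ys <- (ri - 0.5) * px
  labs <- sort(unique(lab))
  out <- data.frame(
    label = labs,
    x = as.numeric(tapply(xs, lab, mean)[as.character(labs)]),
    y = as.numeric(tapply(ys, lab, mean)[as.character(labs)]),
    area = as.numeric(table(lab)[as.character(labs)]) * px^2)
  rownames(out) <- NULL
  out
}

#' Neighbor counts in a square window
#'
#' For each lattice, the number of other lattices whose centroid lies in
#' the closed `window` x `window` axis-aligned square centered on its own
#' centroid. The focal lattice is excluded by default; boundary centroids
#' count (closed square).
#'
#' @param records a [fcl_records()] table.
#' @param window square edge in um (default 1).
#' @param include_self count the focal lattice itself.
#' @return integer vector, one count per record row.
#' @export
neighbor_counts <- function(records, window = 1, include_self = FALSE) {
  if (window <= 0) stop("window must be positive")
  half <- window / 2
  n <- nrow(records)
  if (n == 0) return(integer(0))
  vapply(seq_len(n), function(i) {
    dx <- abs(records$x - records$x[i])
    dy <- abs(records$y - records$y[i])
    inside <- dx <= half & dy <= half
    if (!include_self) inside[i] <- FALSE
    sum(inside)
  }, integer(1))
}

#' Generate a synthetic lattice label mask
#'
#' Places non-overlapping elliptical regions with log-normal areas and
#' uniform random centers and orientations on a square field, emulating
#' platinum-replica-EM-derived lattice masks for testing. Returns the mask
#' together with exact ground truth (as painted, plus the continuous
#' target parameters).
#'
#' @param n_fcl requested number of regions.
#' @param field_size field edge, um.
#' @param pixel_size pixel edge, um.
#' @param area_meanlog,area_sdlog log-normal parameters of the region
#'   areas (um^2); defaults give a mean area of about 0.05 um^2.
#' @param max_aspect maximum ellipse aspect ratio.
#' @param seed RNG seed.
#' @param max_tries placement retries per region before giving up (the
#'   achieved count may then fall short of `n_fcl`).
#' @return list with `mask` (an [label_mask()]), `truth` (data.frame:
#'   `label`, `x`, `y`, `area` as painted, `area_target` continuous) and
#'   `n_placed`.
#' @export
synthetic_mask <- function(n_fcl, field_size = 10, pixel_size = 0.02,
                           area_meanlog = log(0.05) - 0.125,
                           area_sdlog = 0.5, max_aspect = 2, seed = 1,
                           max_tries = 200) {
  stopifnot(n_fcl >= 0, field_size > 0, pixel_size > 0)
  set.seed(seed)
  npx <- max(1L, round(field_size / pixel_size))
  g <- matrix(0L, npx, npx)
  truth <- list()
  placed <- 0L
  for (k in seq_len(n_fcl)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      area <- stats::rlnorm(1, area_meanlog, area_sdlog)
      aspect <- stats::runif(1, 1, max_aspect)
      b <- sqrt(area / (pi * aspect))  # semi-minor
      a <- aspect * b                  # semi-major
      th <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, a, field_size - a)
      cy <- stats::runif(1, a, field_size - a)
      # rasterize only inside the bounding box of the ellipse
      ci <- max(1L, floor((cx - a) / pixel_size)):
        min(npx, ceiling((cx + a) / pixel_size))
      ri <- max(1L, floor((cy - a) / pixel_size)):
        min(npx, ceiling((cy + a) / pixel_size))
      dx <- outer(rep(1, length(ri)), (ci - 0.5) * pixel_size - cx)
      dy <- outer((ri - 0.5) * pixel_size - cy, rep(1, length(ci)))
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      if (!any(inside)) next
      sub <- g[ri, ci, drop = FALSE]
      if (any(sub[inside] != 0)) next
      sub[inside] <- placed + 1L
      g[ri, ci] <- sub
      placed <- placed + 1L
      xs <- outer(rep(1, length(ri)), (ci - 0.5) * pixel_size)
      ys <- outer((ri - 0.5) * pixel_size, rep(1, length(ci)))
      truth[[placed]] <- data.frame(
        label = placed,
        x = mean(xs[inside]), y = mean(ys[inside]),
        area = sum(inside) * pixel_size^2, area_target = area)
      ok <- TRUE
      break
    }
    if (!ok) break
  }
  truth <- if (placed > 0) do.call(rbind, truth) else
    data.frame(label = integer(0), x = numeric(0), y = numeric(0),
               area = numeric(0), area_target = numeric(0))
  list(mask = label_mask(g, pixel_size), truth = truth, n_placed = placed)
}
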