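#' Density map container
#'
#' A 2-D histogram normalized as percentage of the densest bin, the
#' convention used for relative neighbour-position and speed-polarization
#' heat maps. Raw counts are retained so the normalization is invertible.
#'
#' @param counts integer matrix of bin counts (rows = x bins).
#' @param x_edges,y_edges bin boundary vectors (length `nrow+1`, `ncol+1`).
#' @param units character of length 2 naming the axis units.
#' @param overflow number of samples that fell outside the extent.
#' @return an object of class `"density_map"` with `values` in `[0, 100]`.
#' @export
density_map <- function(counts, x_edges, y_edges,
                        units = c("", ""), overflow = 0L) {
  stopifnot(nrow(counts) == length(x_edges) - 1L,
            ncol(counts) == length(y_edges) - 1L)
  n <- sum(counts)
  peak <- max(counts)
  values <- if (n > 0) counts / peak * 100 else counts * 0
  structure(list(values = values, counts = counts, x_edges = x_edges,
                 y_edges = y_edges, n_samples = n, peak_count = peak,
                 overflow = as.integer(overflow), units = units),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map> %d x %d bins (%s x %s), %d samples, %d outside extent\n",
    nrow(x$values), ncol(x$values), x$units[1], x$units[2],
    x$n_samples, x$overflow))
  invisible(x)
}

#' @export
plot.density_map <- function(x, main = "", ...) {
  graphics::image(x = x$x_edges, y = x$y_edges, z = x$values,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = x$units[1], ylab = x$units[2], main = main,
                  useRaster = TRUE, ...)
  invisible(x)
}

bin2d <- function(x, y, x_edges, y_edges) {
  ix <- findInterval(x, x_edges, rightmost.closed = TRUE)
  iy <- findInterval(y, y_edges, rightmost.closed = TRUE)
  nbx <- length(x_edges) - 1L
  nby <- length(y_edges) - 1L
  keep <- ix >= 1L & ix <= nbx & iy >= 1L & iy <= nby & !is.na(ix) & !is.na(iy)
  counts <- matrix(0L, nbx, nby)
  if (any(keep)) {
    tab <- table(factor(ix[keep], levels = seq_len(nbx)),
                 factor(iy[keep], levels = seq_len(nby)))
    counts <- matrix(as.integer(tab), nbx, nby)
  }
  list(counts = counts, overflow = sum(!keep))
}

#' Relative neighbour-position density map
#'
#' For every frame with a defined focal heading and every ordered
#' (focal, neighbour) pair, the neighbour position is expressed in the
#' focal fish's frame of reference: origin at the focal fish, heading
#' rotated to point up (+y), distances in body lengths. Samples are
#' accumulated into a 2-D histogram and normalized as percent of the
#' densest bin; samples outside the extent are dropped and tallied in
#' `overflow`.
#'
#' @param traj a smoothed, gap-free [trajectory()] with at least 2 fish.
#' @param meta the trial's [trial_metadata()] (supplies `body_length_mm`).
#' @param bin_width bin width in body lengths; default 0.25.
#' @param extent_BL half-extent of the map in body lengths; default 5.
#' @param min_step passed to [compute_headings()].
#' @return a [density_map()] in BL units (x: left-right, y: back-front).
#' @export
neighbour_density <- function(traj, meta, bin_width = 0.25, extent_BL = 5,
                              min_step = 0.2) {
  stopifnot(inherits(traj, "trajectory"))
  ni <- n_individuals(traj)
  if (ni < 2L) stop("neighbour density needs at least 2 individuals")
  bl <- meta$body_length_mm
  hd <- compute_headings(traj, min_step = min_step)
  p <- traj$positions
  xs <- ys <- list(); k <- 0L
  for (i in seq_len(ni)) {
    def <- !is.na(hd[, i, 1])
    if (!any(def)) next
    ux <- hd[def, i, 1]; uy <- hd[def, i, 2]
    for (j in seq_len(ni)[-i]) {
      rx <- p[def, j, 1] - p[def, i, 1]
      ry <- p[def, j, 2] - p[def, i, 2]
      # rotate so the focal heading maps to +y; +x is the focal's right
      k <- k + 1L
      xs[[k]] <- (rx * uy - ry * ux) / bl
      ys[[k]] <- (rx * ux + ry * uy) / bl
    }
  }
  if (k == 0L) stop("no frames with a defined focal heading")
  edges <- seq(-extent_BL, extent_BL, by = bin_width)
  b <- bin2d(unlist(xs), unlist(ys), edges, edges)
  if (sum(b$counts) == 0L) stop("no neighbour samples inside the extent")
  density_map(b$counts, edges, edges, units = c("BL", "BL"),
              overflow = b$overflow)
}

#' Group speed vs polarization density map
#'
#' Joint 2-D histogram, frame by frame, of group speed (mean individual
#' speed at the frame, cm/s) and polarization, normalized as percent of
#' the densest bin. Frames with undefined polarization are skipped.
#'
#' @param traj a smoothed, gap-free [trajectory()], or `NULL` when
#'   `speed` and `polarization` are given directly.
#' @param speed,polarization optional per-frame vectors, used instead of
#'   `traj` (e.g. pooled across trials).
#' @param speed_bin speed bin width, cm/s; default 0.25.
#' @param pol_bin polarization bin width; default 0.05.
#' @param max_speed upper speed extent, cm/s; default 12.
#' @param min_step passed to [compute_headings()] when `traj` is used.
#' @return a [density_map()] (x: speed cm/s, y: polarization).
#' @export
speed_polarization_density <- function(traj = NULL, speed = NULL,
                                       polarization = NULL,
                                       speed_bin = 0.25, pol_bin = 0.05,
                                       max_speed = 12, min_step = 0.2) {
  if (!is.null(traj)) {
    stopifnot(inherits(traj, "trajectory"))
    speed <- rowMeans(compute_speeds(traj))
    polarization <- compute_polarization(compute_headings(traj, min_step))
  }
  if (is.null(speed) || is.null(polarization)) {
    stop("supply either `traj` or both `speed` and `polarization`")
  }
  def <- !is.na(polarization) & !is.na(speed)
  if (!any(def)) stop("no frames with defined polarization")
  s_edges <- seq(0, max_speed, by = speed_bin)
  p_edges <- seq(0, 1, by = pol_bin)
  b <- bin2d(speed[def], polarization[def], s_edges, p_edges)
  density_map(b$counts, s_edges, p_edges, units = c("cm/s", "polarization"),
              overflow = b$overflow)
}

#' Write a density map as CSV
#'
#' The bin-count matrix is written as a CSV matrix with `#`-comment header
#' lines carrying the bin edges, units and sample counts, so the map can
#' be reconstructed exactly.
#'
#' @param map a [density_map()].
#' @param path output path.
#' @export
write_density_map <- function(map, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste0("# x_edges: ", paste(map$x_edges, collapse = " ")),
    paste0("# y_edges: ", paste(map$y_edges, collapse = " ")),
    paste0("# units: ", paste(map$units, collapse = " ")),
    paste0("# n_samples: ", map$n_samples),
    paste0("# overflow: ", map$overflow)), con)
  utils::write.table(map$counts, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a density map written by [write_density_map()]
#' @param path CSV path.
#' @return a [density_map()].
#' @export
read_density_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, ": "), "", grep(
    paste0("^# ", key, ":"), hdr, value = TRUE))
  x_edges <- as.numeric(strsplit(get("x_edges"), " ")[[1]])
  y_edges <- as.numeric(strsplit(get("y_edges"), " ")[[1]])
  units <- strsplit(get("units"), " ")[[1]]
  if (length(units) < 2L) units <- c(units, "")
  counts <- as.matrix(utils::read.csv(textConnection(
    lines[!startsWith(lines, "#")]), header = FALSE))
  dimnames(counts) <- NULL
  density_map(counts, x_edges, y_edges, units = units,
              overflow = as.integer(get("overflow")))
}
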