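# Topographic mapping: exact thin-plate spline interpolation of
# per-electrode statistics over flattened skull coordinates, and pointwise
# group statistics on the interpolated grid.

.tpsKernel <- function(r) ifelse(r > 0, r^2 * log(r), 0)

# linear operator mapping 12 electrode values to grid values: exact TPS
# interpolation is linear in the data, so the (nGrid x nElectrode) basis
# matrix is precomputed once per layout/grid
.tpsBasis <- function(coords, grid) {
  n <- nrow(coords)
  if (anyDuplicated(paste(coords[, 1], coords[, 2])))
    stop("duplicate electrode coordinates")
  D <- as.matrix(stats::dist(coords))
  K <- .tpsKernel(D)
  P <- cbind(1, coords)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Minv <- solve(M)
  rg <- sqrt(outer(grid[, 1], coords[, 1], "-")^2 +
             outer(grid[, 2], coords[, 2], "-")^2)
  cbind(.tpsKernel(rg), 1, grid) %*% Minv[, seq_len(n)]
}

# convex hull polygon of the electrode positions, and a mask of grid points
# inside the hull or within `margin` mm of it
.hullMask <- function(coords, grid, margin) {
  hull <- coords[grDevices::chull(coords), , drop = FALSE]
  nh <- nrow(hull)
  inside <- rep(FALSE, nrow(grid))
  px <- grid[, 1]; py <- grid[, 2]
  j <- nh
  for (i in seq_len(nh)) {
    xi <- hull[i, 1]; yi <- hull[i, 2]
    xj <- hull[j, 1]; yj <- hull[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mind <- rep(Inf, nrow(grid))
  j <- nh
  for (i in seq_len(nh)) {
    ax <- hull[j, 1]; ay <- hull[j, 2]
    bx <- hull[i, 1]; by <- hull[i, 2]
    vx <- bx - ax; vy <- by - ay
    tt <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) /
                            (vx^2 + vy^2)))
    d <- sqrt((px - (ax + tt * vx))^2 + (py - (ay + tt * vy))^2)
    mind <- pmin(mind, d)
    j <- i
  }
  inside | mind <= margin
}

#' Grid specification for topographic maps
#'
#' @param resolution grid step, mm
#' @param margin extension beyond the electrode bounding box / hull, mm
#' @return list(resolution, margin)
#' @export
gridSpec <- function(resolution = 0.25, margin = 1) {
  stopifnot(resolution > 0, margin >= 0)
  list(resolution = resolution, margin = margin)
}

.makeGrid <- function(layout, spec) {
  coords <- cbind(layout$anterior, layout$lateral)
  # cover [lo, hi] with symmetric overshoot so a left-right symmetric
  # layout yields a left-right symmetric grid
  axisGrid <- function(lo, hi) {
    n <- ceiling((hi - lo) / spec$resolution)
    over <- (n * spec$resolution - (hi - lo)) / 2
    (lo - over) + (0:n) * spec$resolution
  }
  x <- axisGrid(min(coords[, 1]) - spec$margin,
                max(coords[, 1]) + spec$margin)
  y <- axisGrid(min(coords[, 2]) - spec$margin,
                max(coords[, 2]) + spec$margin)
  grid <- cbind(rep(x, times = length(y)), rep(y, each = length(x)))
  list(x = x, y = y, grid = grid, coords = coords,
       mask = .hullMask(coords, grid, spec$margin))
}

#' Thin-plate spline interpolation of electrode values onto a skull grid
#'
#' Exact (non-penalized) thin-plate spline over the flattened
#' (anterior, lateral) electrode coordinates: the interpolant reproduces the
#' electrode values exactly and reproduces affine fields exactly. The grid
#' covers the electrode bounding box plus a margin; points outside the
#' convex hull + margin are masked.
#'
#' @param values 12 finite per-electrode values, in layout order
#' @param layout electrode layout
#' @param spec a [gridSpec()]
#' @return object of class \code{qeegTopoMap}: list(x, y, values
#'   (length(x) x length(y) matrix, NA outside the mask), layout, spec)
#' @export
splineInterpolate <- function(values, layout = defaultLayout(),
                              spec = gridSpec()) {
  if (length(values) != nrow(layout) || !all(is.finite(values)))
    stop("need one finite value per electrode")
  g <- .makeGrid(layout, spec)
  B <- .tpsBasis(g$coords, g$grid)
  v <- as.numeric(B %*% values)
  v[!g$mask] <- NA_real_
  out <- list(x = g$x, y = g$y,
              values = matrix(v, length(g$x), length(g$y)),
              significance = NULL, layout = layout, spec = spec)
  class(out) <- "qeegTopoMap"
  out
}

#' Pointwise group statistics on the interpolated grid
#'
#' Each subject's per-electrode values are interpolated to the common grid;
#' at every unmasked grid point the group contrast is then tested with the
#' same mixed RM-ANOVA machinery used for the channel-level statistics
#' (treatment x time when several within-levels are present, one-way ANOVA
#' on a single level), and the p value is binned into the three-level scale
#' none / p<0.05 / p<0.01 / p<0.001. No correction is applied across grid
#' points (configurable; the published convention corrects across
#' comparisons, not across map pixels).
#'
#' @param data data.frame(subject, group, time, channel, value); channels
#'   must cover the layout
#' @param layout electrode layout
#' @param spec a [gridSpec()]
#' @param effect which ANOVA effect drives the significance overlay
#' @param alphaLevels the three significance levels
#' @return a \code{qeegTopoMap} whose \code{values} hold the group-mean
#'   difference (second group minus first, averaged over time) when exactly
#'   two groups are present (the F statistic otherwise) and whose
#'   \code{significance} matrix holds codes 0-3
#' @export
pointwiseSignificance <- function(data, layout = defaultLayout(),
                                  spec = gridSpec(),
                                  effect = "treatment:time",
                                  alphaLevels = c(0.05, 0.01, 0.001)) {
  stopifnot(all(c("subject", "group", "time", "channel", "value") %in%
                  names(data)))
  if (!all(layout$label %in% data$channel))
    stop("data must cover every layout channel")
  groups <- unique(data$group)
  if (min(table(unique(data[, c("subject", "group")])$group)) < 2)
    stop("need at least 2 subjects per group")
  g <- .makeGrid(layout, spec)
  B <- .tpsBasis(g$coords, g$grid[g$mask, , drop = FALSE])

  cells <- unique(data[, c("subject", "group", "time")])
  gv <- matrix(NA_real_, sum(g$mask), nrow(cells))
  for (i in seq_len(nrow(cells))) {
    d <- data[data$subject == cells$subject[i] & data$time == cells$time[i], ]
    v <- d$value[match(layout$label, d$channel)]
    if (anyNA(v)) stop("missing channel value for subject ",
                       cells$subject[i])
    gv[, i] <- B %*% v
  }

  times <- unique(cells$time)
  pvals <- numeric(sum(g$mask))
  stat <- numeric(sum(g$mask))
  for (p in seq_len(sum(g$mask))) {
    design <- data.frame(subject = cells$subject, group = cells$group,
                         time = cells$time, value = gv[p, ],
                         stringsAsFactors = FALSE)
    if (length(times) >= 2) {
      an <- rmAnova(design, runPosthoc = FALSE)
      pvals[p] <- effectP(an, effect)
    } else {
      fit <- stats::oneway.test(value ~ group, design, var.equal = TRUE)
      pvals[p] <- fit$p.value
    }
    if (length(groups) == 2) {
      m <- tapply(gv[p, ], cells$group, mean)
      stat[p] <- m[as.character(groups[2])] - m[as.character(groups[1])]
    } else {
      m <- tapply(gv[p, ], cells$group, mean)
      stat[p] <- max(m) - min(m)
    }
  }
  sig <- as.integer(pvals < alphaLevels[1]) +
    as.integer(pvals < alphaLevels[2]) + as.integer(pvals < alphaLevels[3])

  full <- function(vm) {
    out <- rep(NA_real_, nrow(g$grid)); out[g$mask] <- vm
    matrix(out, length(g$x), length(g$y))
  }
  out <- list(x = g$x, y = g$y, values = full(stat),
              significance = full(sig), pvalues = full(pvals),
              layout = layout, spec = spec,
              contrast = if (length(groups) == 2)
                paste(groups[2], "-", groups[1]) else "max group spread")
  class(out) <- "qeegTopoMap"
  out
}

#' Evaluate a topographic map at arbitrary coordinates
#'
#' @param map a \code{qeegTopoMap}
#' @param anterior,lateral coordinates, mm (must lie on grid nodes within
#'   the resolution/2)
#' @return map values at the nearest grid nodes
#' @export
mapValueAt <- function(map, anterior, lateral) {
  ix <- vapply(anterior, function(a) which.min(abs(map$x - a)), integer(1))
  iy <- vapply(lateral, function(l) which.min(abs(map$y - l)), integer(1))
  map$values[cbind(ix, iy)]
}

#' Write a topographic map as PNG
#'
#' Simple raster rendering with electrode positions overlaid; significance
#' (when present) is drawn as three-level contour shading.
#'
#' @param map a \code{qeegTopoMap}
#' @param path output PNG path
#' @param main plot title
#' @return the path, invisibly
#' @export
plotTopoMap <- function(map, path, main = "") {
  grDevices::png(path, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(map$x, map$y, map$values, col = pal,
                  xlab = "anterior (mm)", ylab = "lateral (mm)",
                  main = main, useRaster = FALSE)
  if (!is.null(map$significance)) {
    for (lv in 1:3) {
      idx <- which(map$significance >= lv, arr.ind = TRUE)
      if (nrow(idx))
        graphics::points(map$x[idx[, 1]], map$y[idx[, 2]], pch = ".",
                         cex = lv)
    }
  }
  graphics::points(map$layout$anterior, map$layout$lateral, pch = 21,
                   bg = "white")
  graphics::text(map$layout$anterior, map$layout$lateral,
                 map$layout$label, pos = 3, cex = 0.8)
  invisible(path)
}
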