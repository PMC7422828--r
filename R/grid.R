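#' Build the modified 24-2 test grid
#'
#' Constructs the test grid: the standard 54-point 24-2 perimetric lattice
#' (locations at odd multiples of 3 degrees, 6-degree spacing, with the nasal
#' extension pair at 27 degrees eccentricity on the +/-3 degree rows) with the
#' four-point top and bottom rows (y = +/-21) omitted, because remote eye
#' trackers have limited vertical range. That leaves 46 locations: 44 test
#' points plus the two blind-spot points at 15 degrees temporal, which are
#' flagged with role `"blind_spot"` and serve as an internal validity check.
#'
#' Coordinates are visual-field degrees (x positive rightward, y positive
#' upward). In right-eye format the temporal field is positive x (blind spot
#' at (15, +/-3)) and the nasal extension sits at (-27, +/-3); a left-eye grid
#' is the x-mirror.
#'
#' @param eye `"right"` or `"left"`.
#' @return A `test_grid`: a data frame with columns `x_deg`, `y_deg`, `role`
#'   (`"test"` or `"blind_spot"`), `group` (growth-pattern stage, 0 for
#'   blind-spot points) and attribute `eye`.
#' @examples
#' g <- build_grid("right")
#' nrow(g)                      # 46
#' sum(g$role == "blind_spot")  # 2
#' @export
build_grid <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  rows <- list(`15` = seq(-15, 15, by = 6),
               `9`  = seq(-21, 21, by = 6),
               `3`  = c(seq(-21, 21, by = 6), -27),
               `-3` = c(seq(-21, 21, by = 6), -27),
               `-9` = seq(-21, 21, by = 6),
               `-15` = seq(-15, 15, by = 6))
  g <- do.call(rbind, lapply(names(rows), function(y)
    data.frame(x_deg = sort(rows[[y]]), y_deg = as.numeric(y))))
  g$role <- ifelse(g$x_deg == 15 & abs(g$y_deg) == 3, "blind_spot", "test")
  if (eye == "left") g$x_deg <- -g$x_deg
  g <- g[order(-g$y_deg, g$x_deg), ]
  rownames(g) <- NULL
  g$group <- growth_stages(g)
  structure(g, eye = eye, class = c("test_grid", "data.frame"))
}

# Assign growth-pattern stages: the four quadrant seeds at (+/-9, +/-9) form
# stage 1; each later stage is the set of untested points within one lattice
# step (6 deg Chebyshev) of an earlier stage. Blind-spot points get stage 0
# (tested throughout, outside the growth pattern).
growth_stages <- function(grid) {
  stage <- integer(nrow(grid))
  test <- grid$role == "test"
  seeds <- test & abs(grid$x_deg) == 9 & abs(grid$y_deg) == 9
  if (!any(seeds)) stop("grid has no quadrant seed points at (+/-9, +/-9)")
  stage[seeds] <- 1L
  k <- 1L
  while (any(test & stage == 0L)) {
    frontier <- which(test & stage == 0L)
    done <- which(stage > 0L & stage <= k)
    reach <- vapply(frontier, function(i) {
      any(pmax(abs(grid$x_deg[i] - grid$x_deg[done]),
               abs(grid$y_deg[i] - grid$y_deg[done])) <= 6)
    }, logical(1))
    if (!any(reach))
      stop("disconnected grid location(s): no 6-degree path to a seed")
    stage[frontier[reach]] <- k + 1L
    k <- k + 1L
  }
  stage
}

#' Growth-pattern stages of a grid
#'
#' Returns the ordered partition of the 44 test locations into growth-pattern
#' stages. Stage 1 holds the four quadrant seeds at (+/-9, +/-9); each later
#' stage contains locations adjacent (within 6 degrees Chebyshev) to an
#' already-staged location, so completed neighbours can seed their priors.
#' Blind-spot points are excluded: they are tested throughout the session.
#'
#' @param grid A [build_grid()] result.
#' @return A list of data frames, one per stage, in testing order.
#' @export
growth_pattern <- function(grid) {
  stopifnot(inherits(grid, "test_grid"))
  stages <- sort(unique(grid$group[grid$group > 0]))
  lapply(stages, function(k) grid[grid$group == k, , drop = FALSE])
}

#' Convert locations and pointwise values to right-eye format
#'
#' Left-eye fields are x-mirrored so that grids and normative tables from both
#' eyes can be pooled; right-eye input is returned unchanged. Only coordinates
#' flip, values never do.
#'
#' @param x A `test_grid`, or any data frame with `x_deg` and an `eye`
#'   attribute or `eye` argument.
#' @param eye Eye of the input, if `x` carries no `eye` attribute.
#' @return The same object in right-eye format.
#' @export
to_right_eye_format <- function(x, eye = attr(x, "eye")) {
  if (is.null(eye)) stop("eye not specified and not an attribute of x")
  eye <- match.arg(eye, c("right", "left"))
  if (eye == "left") {
    x$x_deg <- -x$x_deg
    x <- x[order(-x$y_deg, x$x_deg), , drop = FALSE]
    rownames(x) <- NULL
    attr(x, "eye") <- "right"
  }
  x
}

#' Aggregate pointwise values over named visual-field subregions
#'
#' Generic region aggregation (e.g. for published visual-field cluster maps):
#' each region is a set of grid locations, and the region statistic is the
#' mean of its member values. Locations absent from every region are ignored.
#'
#' @param values Data frame with `x_deg`, `y_deg` and a `value` column.
#' @param region_map Named list; each element a data frame (or 2-column
#'   matrix) of `x_deg`, `y_deg` member locations.
#' @return Named numeric vector of per-region means.
#' @export
aggregate_regions <- function(values, region_map) {
  stopifnot(is.data.frame(values), all(c("x_deg", "y_deg", "value") %in% names(values)))
  key <- paste(values$x_deg, values$y_deg)
  out <- vapply(region_map, function(reg) {
    reg <- as.data.frame(reg)
    names(reg)[1:2] <- c("x_deg", "y_deg")
    idx <- match(paste(reg$x_deg, reg$y_deg), key)
    if (anyNA(idx))
      stop("region map refers to location(s) not present in the grid")
    mean(values$value[idx])
  }, numeric(1))
  out
}
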