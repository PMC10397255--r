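#' Stimulus field geometry
#'
#' Describes the circular stimulus field used for dot-array generation: a
#' virtual circle of `field_diameter` degrees of visual angle centred on
#' fixation, with a central rectangular exclusion zone reserved for the
#' distractor stimulus, a dot diameter, and a minimum edge-to-edge separation
#' between dots.
#'
#' The minimum separation is interpreted edge-to-edge, so two dot centres must
#' be at least `dot_diameter + min_separation` degrees apart.  Dots are fully
#' contained in the field (centre within `field_diameter / 2 - dot_diameter / 2`
#' of fixation) and the exclusion rectangle is inflated by the dot radius so
#' that no dot overlaps it.
#'
#' @param field_diameter Diameter of the circular field, degrees.
#' @param dot_diameter Dot diameter, degrees.
#' @param min_separation Minimum edge-to-edge separation between dots, degrees.
#' @param exclusion_width,exclusion_height Size of the central exclusion
#'   rectangle, degrees.
#'
#' @return An object of class `field_geometry`.
#' @examples
#' geom <- field_geometry()
#' geom$field_diameter
#' @export
field_geometry <- function(field_diameter = 10, dot_diameter = 0.3,
                           min_separation = 0.3, exclusion_width = 1.6,
                           exclusion_height = 1.6) {
  vals <- c(field_diameter = field_diameter, dot_diameter = dot_diameter,
            min_separation = min_separation, exclusion_width = exclusion_width,
            exclusion_height = exclusion_height)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry fields must be finite and strictly positive")
  }
  # the exclusion rectangle must fit inside the field circle
  half_diag <- sqrt((exclusion_width / 2)^2 + (exclusion_height / 2)^2)
  if (half_diag >= field_diameter / 2) {
    stop("exclusion rectangle does not fit inside the field circle")
  }
  if (min_separation + dot_diameter >= field_diameter) {
    stop("min_separation + dot_diameter must be smaller than field_diameter")
  }
  structure(as.list(vals), class = "field_geometry")
}

# derived quantities used by the samplers and the validator
.geom_limits <- function(geom) {
  list(
    r_max = geom$field_diameter / 2 - geom$dot_diameter / 2,
    # exclusion half-extents inflated by the dot radius
    ex_x = geom$exclusion_width / 2 + geom$dot_diameter / 2,
    ex_y = geom$exclusion_height / 2 + geom$dot_diameter / 2,
    min_cc = geom$dot_diameter + geom$min_separation
  )
}

.new_dot_array <- function(x, y, arrangement) {
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 arrangement = arrangement, n = length(x)),
            class = "dot_array")
}

#' @export
print.dot_array <- function(x, ...) {
  cat(sprintf("<dot_array: %d %s dots>\n", x$n, x$arrangement))
  invisible(x)
}

# one uniform draw from the admissible annulus-minus-rectangle region
.draw_admissible <- function(lim) {
  repeat {
    r <- lim$r_max * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    px <- r * cos(th)
    py <- r * sin(th)
    if (abs(px) > lim$ex_x || abs(py) > lim$ex_y) {
      return(c(px, py))
    }
  }
}

#' Sample a random dot array
#'
#' Places `n` dots uniformly (by rejection sampling) in the admissible region
#' of the stimulus field: inside the virtual circle, outside the central
#' exclusion rectangle, and at least `dot_diameter + min_separation` degrees
#' centre-to-centre from every other dot.
#'
#' @param n Number of dots (positive integer).
#' @param geom A [field_geometry()].
#' @param max_attempts Attempt budget per dot before the sampler gives up and
#'   signals an infeasible packing density.
#'
#' @return A `dot_array` with `arrangement = "random"`.  Uses R's global
#'   random number stream; seed with [set.seed()] for reproducibility.
#' @seealso [sample_symmetric_array()], [validate_array()]
#' @examples
#' set.seed(1)
#' arr <- sample_random_array(12)
#' validate_array(arr)
#' @export
sample_random_array <- function(n, geom = field_geometry(),
                                max_attempts = 10000L) {
  stopifnot(length(n) == 1, n >= 1, n == round(n))
  lim <- .geom_limits(geom)
  xs <- numeric(n)
  ys <- numeric(n)
  min_cc2 <- lim$min_cc^2
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- .draw_admissible(lim)
      if (i == 1L ||
          all((xs[seq_len(i - 1L)] - p[1])^2 +
              (ys[seq_len(i - 1L)] - p[2])^2 >= min_cc2)) {
        xs[i] <- p[1]
        ys[i] <- p[2]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement failure: could not place dot ", i, " of ", n,
           " within ", max_attempts, " attempts (density infeasible)",
           call. = FALSE)
    }
  }
  .new_dot_array(xs, ys, "random")
}

#' Sample a vertically mirror-symmetric dot array
#'
#' Draws `floor(n / 2)` dots in the left half-field and reflects them about
#' the vertical axis, producing a point set invariant under `x -> -x`.  Each
#' drawn dot must respect the pairwise separation against all previously
#' placed dots *and* their mirror images; drawn dots are kept at
#' `|x| >= (dot_diameter + min_separation) / 2` so that a dot and its own
#' mirror never collide.  For odd `n` one unpaired dot is placed on the
#' symmetry axis (`x = 0`), above or below the central exclusion zone.
#'
#' @inheritParams sample_random_array
#' @return A `dot_array` with `arrangement = "symmetric"`.
#' @examples
#' set.seed(7)
#' arr <- sample_symmetric_array(8)
#' sort(arr$x + rev(sort(arr$x))) # mirror pairs cancel
#' @export
sample_symmetric_array <- function(n, geom = field_geometry(),
                                   max_attempts = 10000L) {
  stopifnot(length(n) == 1, n >= 1, n == round(n))
  lim <- .geom_limits(geom)
  min_cc2 <- lim$min_cc^2
  half_margin <- lim$min_cc / 2
  n_pairs <- n %/% 2L
  xs <- numeric(0)
  ys <- numeric(0)

  ok_against_all <- function(px, py) {
    length(xs) == 0L ||
      (all((xs - px)^2 + (ys - py)^2 >= min_cc2) &&
       all((-xs - px)^2 + (ys - py)^2 >= min_cc2))
  }

  if (n %% 2L == 1L) {
    # unpaired on-axis dot; x = 0 is inside the exclusion x-range, so it must
    # sit above or below the exclusion rectangle, inside the circle
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      py <- stats::runif(1, -lim$r_max, lim$r_max)
      if (abs(py) > lim$ex_y && abs(py) <= lim$r_max) {
        xs <- 0
        ys <- py
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement failure: no admissible on-axis position", call. = FALSE)
    }
  }

  for (i in seq_len(n_pairs)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- .draw_admissible(lim)
      px <- -abs(p[1])                    # fold into the left half-plane
      if (px > -half_margin) next         # too close to the axis
      if (ok_against_all(px, p[2])) {
        xs <- c(xs, px)
        ys <- c(ys, p[2])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement failure: could not place mirror pair ", i, " of ",
           n_pairs, " within ", max_attempts, " attempts", call. = FALSE)
    }
  }

  off <- xs != 0
  .new_dot_array(c(xs[!off], xs[off], -xs[off]),
                 c(ys[!off], ys[off], ys[off]),
                 "symmetric")
}

#' Convex-hull area of a dot array
#'
#' Area (squared degrees) of the two-dimensional convex hull of the dot
#' centres, computed from the hull polygon ([grDevices::chull()]) by the
#' shoelace formula.  Degenerate inputs (fewer than three dots, or all dots
#' collinear) have zero area.
#'
#' @param array A `dot_array`, or any list with numeric `x` and `y`.
#' @return Hull area in deg^2.
#' @examples
#' sq <- list(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' convex_hull_area(sq) # 1
#' @export
convex_hull_area <- function(array) {
  x <- array$x
  y <- array$y
  if (length(x) < 3L) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) return(0)
  hx <- x[h]
  hy <- y[h]
  j <- c(seq_along(h)[-1], 1L)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

#' Validate a dot array against the field constraints
#'
#' Checks every structural invariant of a dot array and returns a character
#' vector of violation descriptors (empty when the array is valid):
#' `"out-of-field"`, `"in-exclusion"`, `"pair-too-close"` and, for arrays
#' labelled symmetric, `"asymmetric"` when the point set is not invariant
#' under reflection about the vertical axis.
#'
#' @param array A `dot_array`.
#' @param geom A [field_geometry()].
#' @param tol Coordinate tolerance for the mirror-match test, degrees.
#' @return Character vector of violations; `character(0)` if valid.
#' @export
validate_array <- function(array, geom = field_geometry(), tol = 1e-9) {
  lim <- .geom_limits(geom)
  x <- array$x
  y <- array$y
  out <- character(0)
  eps <- 1e-12                            # guard against round-off at bounds
  if (any(x^2 + y^2 > (lim$r_max + eps)^2)) out <- c(out, "out-of-field")
  if (any(abs(x) < lim$ex_x - eps & abs(y) < lim$ex_y - eps)) {
    out <- c(out, "in-exclusion")
  }
  if (length(x) > 1L) {
    d2 <- stats::dist(cbind(x, y))
    if (any(d2 < lim$min_cc - 1e-9)) out <- c(out, "pair-too-close")
  }
  if (identical(array$arrangement, "symmetric")) {
    if (!.is_mirror_symmetric(x, y, tol)) out <- c(out, "asymmetric")
  }
  if (!is.null(array$n) && array$n != length(x)) out <- c(out, "bad-count")
  out
}

# set-wise invariance under x -> -x: each point must have a mirror partner
.is_mirror_symmetric <- function(x, y, tol = 1e-9) {
  used <- rep(FALSE, length(x))
  for (i in seq_along(x)) {
    j <- which(!used & abs(x + x[i]) <= tol & abs(y - y[i]) <= tol)
    if (length(j) == 0L) return(FALSE)
    used[j[1]] <- TRUE
  }
  TRUE
}

#' Export dot arrays as a long-format data frame
#'
#' One row per dot, suitable for writing to CSV: `trial_id`, `dot_index`,
#' `x_deg`, `y_deg`, `arrangement`, `n`.
#'
#' @param arrays A list of `dot_array` objects.
#' @param trial_ids Optional vector of identifiers (default sequential).
#' @return A [tibble::tibble()].
#' @export
dot_array_table <- function(arrays, trial_ids = seq_along(arrays)) {
  stopifnot(length(arrays) == length(trial_ids))
  dfs <- lapply(seq_along(arrays), function(i) {
    a <- arrays[[i]]
    tibble::tibble(trial_id = trial_ids[i], dot_index = seq_len(a$n),
                   x_deg = a$x, y_deg = a$y, arrangement = a$arrangement,
                   n = a$n)
  })
  dplyr::bind_rows(dfs)
}
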