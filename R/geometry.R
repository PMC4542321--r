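#' Build the layer geometry
#'
#' Places `n_e` excitatory and `n_i` inhibitory neurons on square grids inside
#' an `m` x `m` patch. Neuron `i` of a population with `n` cells sits at
#' `x = ((i-1) %% sqrt(n)) * m / sqrt(n)`,
#' `y = floor((i-1) / sqrt(n)) * m / sqrt(n)`, so both populations tile the
#' patch uniformly with periodic boundary conditions. Deterministic.
#'
#' @param n_e,n_i Population sizes; each must be a perfect square.
#' @param m Linear patch size (length units, nominal 1 mm).
#' @return A tibble of class `layer_geometry` with columns `population`
#'   ("E"/"I"), `neuron` (1-based index within population), `x`, `y`;
#'   attributes `m`, `n_e`, `n_i`.
#' @export
build_geometry <- function(n_e = 8100, n_i = 2025, m = 1) {
  stopifnot(m > 0)
  check_square <- function(n, label) {
    r <- sqrt(n)
    if (abs(r - round(r)) > 1e-9) {
      abort(sprintf("population %s: size %d is not a perfect square", label, n))
    }
    as.integer(round(r))
  }
  grid_pop <- function(n, label) {
    r <- check_square(n, label)
    i <- seq_len(n) - 1L
    tibble(
      population = label,
      neuron = seq_len(n),
      x = (i %% r) * m / r,
      y = (i %/% r) * m / r
    )
  }
  geom <- bind_rows(grid_pop(n_e, "E"), grid_pop(n_i, "I"))
  structure(geom, m = m, n_e = as.integer(n_e), n_i = as.integer(n_i),
            class = c("layer_geometry", class(geom)))
}

#' Pinwheel orientation map
#'
#' Evaluates the continuous orientation-preference map at positions `(x, y)`
#' in a patch of linear size `m` with periodic boundary conditions:
#' `arctan(sin(2*pi*y/m) / sin(2*pi*x/m)) / 2 + pi/2 +
#'  pi * (1 + sign(x/m - 1/2)) / 4`, reduced to `\[0, pi)` and returned in
#' degrees. The map is continuous (as an orientation) everywhere except at the
#' pinwheel singularities where both sine factors vanish.
#'
#' @param x,y Numeric vectors of coordinates.
#' @param m Patch size.
#' @return Orientations in degrees, in \[0, 180).
#' @export
orientation_map <- function(x, y, m = 1) {
  sx <- sin(2 * pi * x / m)
  sy <- sin(2 * pi * y / m)
  ratio <- sy / sx
  base <- atan(ratio) / 2
  base[sx == 0 & sy == 0] <- 0    # formula singular exactly at the pinwheels
  base[sx == 0 & sy != 0] <- sign(ratio[sx == 0 & sy != 0]) * pi / 4
  # the pi/2 correction undoes the sign flip of the arctan argument where
  # sin(2 pi x / m) < 0 (equivalently x/m > 1/2); keying it to the sine keeps
  # the map continuous (mod pi) on the boundary columns themselves
  theta <- base + pi / 2 + (pi / 2) * (sx < 0)
  wrap_orientation(theta * 180 / pi)
}

#' Assign feed-forward preferred orientations
#'
#' Gives every neuron its feed-forward preferred orientation, either from the
#' continuous pinwheel map evaluated at the neuron's grid position
#' (`mode = "map"`, deterministic) or i.i.d. uniform on \[0, 180)
#' (`mode = "random"`, the salt-and-pepper layout, reproducible from `seed`).
#'
#' @param geom A `layer_geometry` tibble from [build_geometry()].
#' @param mode `"map"` or `"random"`.
#' @param seed Integer seed (used only for `mode = "random"`).
#' @return The geometry tibble with an added `theta_deg` column; class
#'   `orientation_layout`, attribute `layout_mode`.
#' @export
assign_orientations <- function(geom, mode = c("map", "random"), seed = NULL) {
  mode <- match.arg(mode)
  m <- attr(geom, "m")
  if (mode == "map") {
    theta <- orientation_map(geom$x, geom$y, m)
  } else {
    if (!is.null(seed)) set.seed(seed)
    theta <- runif(nrow(geom), 0, 180)
  }
  out <- mutate(geom, theta_deg = theta)
  structure(out, m = m, n_e = attr(geom, "n_e"), n_i = attr(geom, "n_i"),
            layout_mode = mode,
            class = c("orientation_layout", "layer_geometry", class(tibble())))
}
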