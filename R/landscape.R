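# Payoff landscapes and skill grids.
#
# A problem instance pairs a payoff surface over a W x H lattice of solution
# cells with an integer skill label per cell. Complex landscapes are a narrow
# bivariate Gaussian "signal" summed with fractal Perlin noise, which yields
# many local optima; simple landscapes are a single broad Gaussian bump with
# exactly one optimum. All payoffs are min-max normalized to [0, 1] so that
# outcomes are comparable across independently generated instances.

#' Fractal Perlin noise parameters
#'
#' Parameters of the summed-octave (fractal) Perlin noise field added to the
#' Gaussian signal of a complex landscape. Octave `o` (0-based) has spatial
#' period `base_period / lacunarity^o` cells and relative amplitude
#' `persistence^o`. The summed field is rescaled to `[0, 1]` and multiplied by
#' `amplitude`, so `amplitude = 1` makes noise and signal peak contributions
#' comparable; `amplitude = 0` disables the noise entirely.
#'
#' @param octaves Number of noise octaves summed (default 4).
#' @param persistence Per-octave amplitude decay in (0, 1] (default 0.5).
#' @param base_period Spatial period of the coarsest octave, in cells
#'   (default 10, so the dominant noise features span several cells and four
#'   octaves carry the detail down to just over a cell).
#' @param lacunarity Per-octave frequency multiplier (default 2).
#' @param amplitude Overall noise amplitude relative to the unit-height
#'   Gaussian signal (default 1; must be >= 0).
#' @return An object of class `noise_spec`.
#' @export
#' @examples
#' noise_spec(octaves = 2, amplitude = 0.5)
noise_spec <- function(octaves = 4L, persistence = 0.5, base_period = 10,
                       lacunarity = 2, amplitude = 1) {
  octaves <- check_count(octaves, "octaves", min = 1L)
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop_param("`amplitude` must be >= 0")
  }
  if (persistence <= 0 || base_period <= 0 || lacunarity <= 0) {
    stop_param("`persistence`, `base_period` and `lacunarity` must be > 0")
  }
  structure(
    list(octaves = octaves, persistence = persistence,
         base_period = base_period, lacunarity = lacunarity,
         amplitude = amplitude),
    class = "noise_spec"
  )
}

quintic_fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)

#' Single-octave Perlin gradient noise on a cell grid
#'
#' Classic two-dimensional Perlin noise evaluated at the cell centers of a
#' `height` x `width` grid, with random unit gradient vectors on an integer
#' lattice of spacing `period` cells and quintic-fade interpolation.
#' Consumes the current RNG stream (one draw per lattice gradient).
#'
#' @param width,height Grid dimensions in cells.
#' @param period Lattice spacing in cells (> 0); features span ~`period` cells.
#' @param seed Optional integer seed; when given the global RNG is untouched.
#' @return A `height` x `width` numeric matrix, values roughly in (-0.71, 0.71).
#' @export
perlin_noise <- function(width, height, period, seed = NULL) {
  width <- check_count(width, "width")
  height <- check_count(height, "height")
  stopifnot(period > 0)
  local_seed_if(seed)

  X <- matrix((seq_len(width) - 1) / period, height, width, byrow = TRUE)
  Y <- matrix((seq_len(height) - 1) / period, height, width)
  xi <- floor(X); yi <- floor(Y)
  xf <- as.vector(X - xi); yf <- as.vector(Y - yi)

  nx <- max(xi) + 2L
  ny <- max(yi) + 2L
  theta <- matrix(stats::runif(nx * ny, 0, 2 * pi), ny, nx)
  gx <- cos(theta); gy <- sin(theta)

  i00 <- cbind(as.vector(yi) + 1L, as.vector(xi) + 1L)
  i10 <- cbind(i00[, 1L], i00[, 2L] + 1L)
  i01 <- cbind(i00[, 1L] + 1L, i00[, 2L])
  i11 <- cbind(i00[, 1L] + 1L, i00[, 2L] + 1L)

  n00 <- gx[i00] * xf + gy[i00] * yf
  n10 <- gx[i10] * (xf - 1) + gy[i10] * yf
  n01 <- gx[i01] * xf + gy[i01] * (yf - 1)
  n11 <- gx[i11] * (xf - 1) + gy[i11] * (yf - 1)

  u <- quintic_fade(xf)
  v <- quintic_fade(yf)
  nx0 <- n00 + u * (n10 - n00)
  nx1 <- n01 + u * (n11 - n01)
  matrix(nx0 + v * (nx1 - nx0), height, width)
}

# Summed-octave noise field, rescaled to [0, 1] * amplitude.
fractal_noise <- function(width, height, spec) {
  if (spec$amplitude == 0) {
    return(matrix(0, height, width))
  }
  field <- matrix(0, height, width)
  for (o in seq_len(spec$octaves) - 1L) {
    field <- field +
      spec$persistence^o *
      perlin_noise(width, height, spec$base_period / spec$lacunarity^o)
  }
  rng <- range(field)
  if (rng[2] > rng[1]) {
    field <- (field - rng[1]) / (rng[2] - rng[1])
  }
  field * spec$amplitude
}

new_payoff_grid <- function(payoff, kind, seed) {
  structure(
    list(payoff = payoff, width = ncol(payoff), height = nrow(payoff),
         kind = kind, seed = seed),
    class = "payoff_grid"
  )
}

normalize_payoffs <- function(m) {
  rng <- range(m)
  if (!all(is.finite(rng))) stop_param("non-finite payoffs in generated surface")
  if (rng[2] == rng[1]) {
    stop_param("degenerate (constant) payoff surface; unusable problem instance")
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

# Unit-height isotropic Gaussian bump centered on a uniformly drawn cell.
gaussian_signal <- function(width, height, variance) {
  mu_row <- sample.int(height, 1L)
  mu_col <- sample.int(width, 1L)
  d2 <- outer((seq_len(height) - mu_row)^2, (seq_len(width) - mu_col)^2, `+`)
  list(signal = exp(-d2 / (2 * variance)), peak = c(mu_row, mu_col))
}

#' Generate a rugged (complex) payoff landscape
#'
#' Builds the payoff surface as a unimodal bivariate Gaussian signal with a
#' uniformly random mean cell and the given variance, summed with fractal
#' Perlin noise, then min-max normalized to `[0, 1]`. With non-zero noise the
#' surface typically has many local optima, which is what makes the search
#' problem hard for hill-climbing agents.
#'
#' @param width,height Grid dimensions in cells (>= 3; default 100 x 100).
#' @param signal_variance Variance of the Gaussian signal in squared cells
#'   (default 3).
#' @param noise A [noise_spec()].
#' @param seed Optional integer seed for reproducible generation.
#' @return A `payoff_grid`: a list with `payoff` (height x width matrix in
#'   `[0, 1]`), `width`, `height`, `kind = "complex"`, and `seed`.
#' @seealso [generate_simple_landscape()], [count_local_optima()]
#' @export
#' @examples
#' g <- generate_complex_landscape(seed = 1)
#' range(g$payoff)
#' count_local_optima(g) > 1
generate_complex_landscape <- function(width = 100L, height = 100L,
                                       signal_variance = 3,
                                       noise = noise_spec(), seed = NULL) {
  width <- check_count(width, "width", min = 3L)
  height <- check_count(height, "height", min = 3L)
  if (!is.numeric(signal_variance) || signal_variance <= 0) {
    stop_param("`signal_variance` must be > 0")
  }
  stopifnot(inherits(noise, "noise_spec"))
  local_seed_if(seed)

  surface <- gaussian_signal(width, height, signal_variance)$signal +
    fractal_noise(width, height, noise)
  new_payoff_grid(normalize_payoffs(surface), "complex", seed)
}

#' Generate a simple unimodal payoff landscape
#'
#' A single isotropic Gaussian bump with a uniformly random peak cell and no
#' noise, normalized to `[0, 1]`. Payoff is strictly decreasing in Euclidean
#' distance from the peak, so the landscape has exactly one (global) optimum.
#'
#' The bump's standard deviation defaults to a quarter of the shorter grid
#' side. A much narrower bump (e.g. the complex landscape's variance of 3 on
#' a 100 x 100 grid) would underflow to an exactly flat far field, creating
#' spurious weak local optima and stranding distant agents.
#'
#' @param width,height Grid dimensions in cells (>= 3; default 100 x 100).
#' @param signal_sd Standard deviation of the bump in cells
#'   (default `min(width, height) / 4`).
#' @param seed Optional integer seed.
#' @return A `payoff_grid` with `kind = "simple"`.
#' @export
#' @examples
#' g <- generate_simple_landscape(20, 20, seed = 7)
#' count_local_optima(g)  # always 1
generate_simple_landscape <- function(width = 100L, height = 100L,
                                      signal_sd = min(width, height) / 4,
                                      seed = NULL) {
  width <- check_count(width, "width", min = 3L)
  height <- check_count(height, "height", min = 3L)
  stopifnot(signal_sd > 0)
  local_seed_if(seed)

  surface <- gaussian_signal(width, height, signal_sd^2)$signal
  new_payoff_grid(normalize_payoffs(surface), "simple", seed)
}

#' Randomly assign a skill type to every solution cell
#'
#' Each cell independently receives one of `s` skill labels, uniformly at
#' random. Labels are the integers `1..s` (R's 1-based convention).
#'
#' @param width,height Grid dimensions in cells.
#' @param s Number of skill types (>= 1; default 100).
#' @param seed Optional integer seed.
#' @return A `skill_grid`: list with `skill` (height x width integer matrix),
#'   `width`, `height`, `s`, `seed`.
#' @export
assign_skills <- function(width = 100L, height = 100L, s = 100L, seed = NULL) {
  width <- check_count(width, "width")
  height <- check_count(height, "height")
  s <- check_count(s, "s", min = 1L)
  local_seed_if(seed)
  skill <- matrix(sample.int(s, width * height, replace = TRUE), height, width)
  structure(
    list(skill = skill, width = width, height = height, s = s, seed = seed),
    class = "skill_grid"
  )
}

#' Pair a payoff grid with a skill grid into a problem instance
#'
#' @param payoffs A `payoff_grid`.
#' @param skills A `skill_grid` with matching dimensions.
#' @return A `problem_instance` holding both grids.
#' @export
problem_instance <- function(payoffs, skills) {
  stopifnot(inherits(payoffs, "payoff_grid"), inherits(skills, "skill_grid"))
  if (payoffs$width != skills$width || payoffs$height != skills$height) {
    stop_param("payoff and skill grids must share dimensions")
  }
  structure(
    list(payoffs = payoffs, skills = skills,
         width = payoffs$width, height = payoffs$height, s = skills$s),
    class = "problem_instance"
  )
}

#' Count weak local optima of a payoff surface
#'
#' A cell is a (weak) local optimum when none of its up-to-8 Moore neighbors
#' has a strictly greater payoff; neighborhoods are clipped at the grid
#' boundary. This matches the hill-climbing stopping rule: an agent on such a
#' cell sees no strict improvement among adjacent cells.
#'
#' @param grid A `payoff_grid` or a numeric matrix.
#' @return Integer count of local optima.
#' @export
#' @examples
#' count_local_optima(matrix(c(1, 2, 1, 2, 3, 2, 1, 2, 1), 3, byrow = TRUE))
count_local_optima <- function(grid) {
  m <- if (inherits(grid, "payoff_grid")) grid$payoff else grid
  stopifnot(is.matrix(m), is.numeric(m), all(is.finite(m)))
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  best_nb <- matrix(-Inf, h, w)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      best_nb <- pmax(best_nb, pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc])
    }
  }
  sum(m >= best_nb)
}

#' @export
print.payoff_grid <- function(x, ...) {
  cat(sprintf("<payoff_grid> %d x %d, kind = %s, payoff in [%.3g, %.3g]\n",
              x$width, x$height, x$kind, min(x$payoff), max(x$payoff)))
  invisible(x)
}

#' @export
print.skill_grid <- function(x, ...) {
  cat(sprintf("<skill_grid> %d x %d, s = %d skill types\n",
              x$width, x$height, x$s))
  invisible(x)
}

#' @export
print.problem_instance <- function(x, ...) {
  cat(sprintf("<problem_instance> %d x %d grid, %s payoffs, s = %d skill types\n",
              x$width, x$height, x$payoffs$kind, x$s))
  invisible(x)
}
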