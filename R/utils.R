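# Internal numerical helpers shared by the measurement and alignment code.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded simulations do not perturb the global stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Indices and types of strict local extrema of y (plateaus break toward the
# left sample).
.local_extrema <- function(y) {
  d <- diff(y)
  s <- sign(d)
  s[s == 0] <- 1
  turn <- which(diff(s) != 0) + 1L
  if (length(turn) == 0L) {
    return(data.frame(i = integer(), type = character(),
                      stringsAsFactors = FALSE))
  }
  type <- ifelse(y[turn - 1L] < y[turn], "max", "min")
  data.frame(i = turn, type = type, stringsAsFactors = FALSE)
}

# Prominence pruning: repeatedly drop the adjacent (max, min) pair whose
# amplitude difference is smallest, while that difference is below `prom`.
# Removing an adjacent opposite-type pair preserves the max/min alternation,
# so small noise wiggles riding on a lobe collapse into the lobe itself.
.prune_extrema <- function(ext, y, prom) {
  if (nrow(ext) < 2L) {
    return(ext)
  }
  repeat {
    if (nrow(ext) < 2L) break
    v <- y[ext$i]
    d <- abs(diff(v))
    j <- which.min(d)
    if (d[j] >= prom) break
    ext <- ext[-c(j, j + 1L), , drop = FALSE]
  }
  ext
}

# Local-polynomial refinement of an extremum at index i. A cubic over +/- 3
# samples is used because a parabola ignores the odd (cubic) term of a
# Lorentzian derivative around its extremum, which biases peak-to-peak widths
# outward by about (window / width)^2 — over 1% for a 1 G line on a 0.05 G
# grid. The cubic's extremum nearest the grid sample removes that
# leading-order bias; a parabola is the fallback for degenerate fits.
.refine_extremum <- function(x, y, i, half = 3L) {
  idx <- max(1L, i - half):min(length(x), i + half)
  x0 <- x[idx] - x[i]
  span <- max(abs(x0))
  if (length(idx) >= 5L) {
    b <- unname(stats::lm.fit(cbind(1, x0, x0^2, x0^3),
                              y[idx])$coefficients)
    if (all(is.finite(b)) && b[4L] != 0) {
      disc <- 4 * b[3L]^2 - 12 * b[4L] * b[2L]
      if (disc >= 0) {
        r <- (-2 * b[3L] + c(1, -1) * sqrt(disc)) / (6 * b[4L])
        dx <- r[which.min(abs(r))]
        if (is.finite(dx) && abs(dx) <= span) {
          return(c(x[i] + dx,
                   b[1L] + b[2L] * dx + b[3L] * dx^2 + b[4L] * dx^3))
        }
      }
    }
  }
  b <- unname(stats::lm.fit(cbind(1, x0, x0^2), y[idx])$coefficients)
  if (!all(is.finite(b)) || b[3L] == 0) {
    return(c(x[i], y[i]))
  }
  dx <- -b[2L] / (2 * b[3L])
  if (!is.finite(dx) || abs(dx) > span) {
    dx <- 0
  }
  c(x[i] + dx, b[1L] + b[2L] * dx + b[3L] * dx^2)
}

# First downward zero crossing of y between indices i1 < i2, by linear
# interpolation between the bracketing samples; NA if none.
.zero_crossing <- function(x, y, i1, i2) {
  seg <- i1:(i2 - 1L)
  k <- seg[y[seg] > 0 & y[seg + 1L] <= 0]
  if (length(k) == 0L) {
    return(NA_real_)
  }
  k <- k[1L]
  x[k] + (0 - y[k]) * (x[k + 1L] - x[k]) / (y[k + 1L] - y[k])
}

# Noise scale estimated from the outer edges of the sweep, where a
# well-recorded first-derivative spectrum has decayed to baseline.
.edge_sigma <- function(y, frac = 0.05) {
  n <- length(y)
  k <- max(4L, floor(frac * n))
  edges <- c(y[seq_len(k)], y[(n - k + 1L):n])
  stats::sd(edges)
}

.mean_step <- function(field) {
  mean(diff(field))
}

.is_uniform <- function(field, tol = 1e-6) {
  d <- diff(field)
  h <- mean(d)
  all(abs(d - h) <= tol * abs(h))
}

.require_uniform <- function(s, what = "this operation") {
  if (!.is_uniform(s$field_G)) {
    stop("non-uniform field grid: resample (see resample_align()) before ",
         what, call. = FALSE)
  }
  invisible(TRUE)
}

.same_grid <- function(a, b, tol = 1e-9) {
  length(a$field_G) == length(b$field_G) &&
    max(abs(a$field_G - b$field_G)) <= tol
}
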