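# Quasi-random Sobol sequences for swarm initialization.
#
# Gray-code (Antonov-Saleev) construction. Dimensions 1-8 use the published
# Joe-Kuo direction numbers; higher dimensions use primitive polynomials over
# GF(2) enumerated algorithmically, with deterministically generated odd
# initial direction integers (Sobol's validity conditions: m_i odd, m_i < 2^i).

.SOBOL_BITS <- 30L
.sobol_cache <- new.env(parent = emptyenv())

# Published (s, a, m...) rows for dimensions 2..8; dimension 1 is the base-2
# van der Corput sequence (all m_i = 1).
.sobol_builtin <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L))
)

# ---- GF(2) polynomial helpers (bitmask representation) ----------------------

gf2_deg <- function(p) {
  d <- -1L
  while (p > 0) {
    p <- p %/% 2
    d <- d + 1L
  }
  d
}

gf2_mulmod <- function(a, b, mod) {
  res <- 0
  dm <- gf2_deg(mod)
  while (b > 0) {
    if (b %% 2 == 1) res <- bitwXor(res, a)
    b <- b %/% 2
    a <- a * 2
    if (gf2_deg(a) == dm) a <- bitwXor(a, mod)
  }
  res
}

gf2_powmod <- function(a, e, mod) {
  res <- 1
  while (e > 0) {
    if (e %% 2 == 1) res <- gf2_mulmod(res, a, mod)
    a <- gf2_mulmod(a, a, mod)
    e <- e %/% 2
  }
  res
}

prime_factors <- function(n) {
  out <- integer(0)
  d <- 2
  while (d * d <= n) {
    if (n %% d == 0) {
      out <- c(out, d)
      while (n %% d == 0) n <- n %/% d
    }
    d <- d + 1
  }
  if (n > 1) out <- c(out, n)
  out
}

# x generates the multiplicative group of GF(2^s) modulo p  <=>  p primitive.
gf2_primitive <- function(p) {
  s <- gf2_deg(p)
  ord <- 2^s - 1
  if (gf2_powmod(2, ord, p) != 1) return(FALSE)
  for (q in prime_factors(ord)) {
    if (gf2_powmod(2, ord / q, p) == 1) return(FALSE)
  }
  TRUE
}

# Enumerate primitive polynomials (s, a) beyond the built-in table, in order
# of increasing degree then increasing a, skipping the built-in ones.
.extra_polys <- function(count) {
  used <- vapply(.sobol_builtin, function(e) paste(e$s, e$a), "")
  out <- vector("list", count)
  got <- 0L
  s <- 5L
  while (got < count) {
    if (s > 13L) stop("Sobol dimension beyond supported direction-number table")
    for (a in 1:(2^(s - 1L) - 1L)) {
      if (paste(s, a) %in% used) next
      p <- 2^s + 2 * a + 1   # x^s + (middle bits a) + 1
      if (gf2_primitive(p)) {
        got <- got + 1L
        out[[got]] <- list(s = s, a = a)
        if (got == count) break
      }
    }
    s <- s + 1L
  }
  out
}

# Deterministic odd initial direction integers for generated dimensions.
.generated_m <- function(dim, s) {
  z <- (as.double(dim) * 2654435761) %% 2147483647
  m <- integer(s)
  for (i in seq_len(s)) {
    z <- (z * 48271) %% 2147483647
    m[i] <- if (i == 1L) 1L else as.integer(2 * (floor(z) %% 2^(i - 1L)) + 1)
  }
  m
}

# Direction integers v_{j,i} (scaled by 2^(BITS - i)) for `dims` dimensions.
.direction_numbers <- function(dims) {
  key <- as.character(dims)
  if (!is.null(.sobol_cache[[key]])) return(.sobol_cache[[key]])
  B <- .SOBOL_BITS
  V <- matrix(0, nrow = dims, ncol = B)
  extra <- if (dims > 8L) .extra_polys(dims - 8L) else list()
  for (j in seq_len(dims)) {
    if (j == 1L) {
      m <- rep(1L, B)
      s <- B
      a <- 0L
    } else {
      ent <- if (j <= 8L) .sobol_builtin[[j - 1L]] else extra[[j - 8L]]
      s <- ent$s
      a <- ent$a
      m0 <- if (j <= 8L) ent$m else .generated_m(j, s)
      m <- double(B)
      m[seq_len(s)] <- m0
      # a encodes coefficients a_1..a_{s-1} of x^s + a_1 x^{s-1} + ... + 1,
      # a_1 being the most significant bit
      ab <- rev(as.integer(intToBits(a))[seq_len(max(s - 1L, 1L))])
      for (i in (s + 1L):B) {
        val <- bitwXor(as.integer(m[i - s] * 2^s), as.integer(m[i - s]))
        if (s > 1L) for (t in seq_len(s - 1L)) {
          if (ab[t] == 1L) val <- bitwXor(val, as.integer(m[i - t] * 2^t))
        }
        m[i] <- val
      }
    }
    V[j, ] <- m[seq_len(B)] * 2^(B - seq_len(B))
  }
  .sobol_cache[[key]] <- V
  V
}

#' Generate Sobol quasi-random points
#'
#' Deterministic low-discrepancy points in `[0, 1)^dims`, built with the
#' Gray-code Sobol construction. The first point is the origin unless
#' `skip_zero` is set. An optional seeded digital shift (`scramble = TRUE`)
#' decorrelates repeated experiments while preserving the net structure.
#'
#' @param n number of points (>= 1).
#' @param dims number of dimensions (>= 1).
#' @param scramble apply a random digital shift (requires `seed`).
#' @param seed integer seed for the digital shift; ignored when
#'   `scramble = FALSE`.
#' @param skip_zero drop the initial all-zeros point and return the next `n`
#'   points instead.
#' @return an `n x dims` matrix with entries in `[0, 1)`.
#' @examples
#' sobol_points(4, 1)        # 0, 0.5, 0.75, 0.25
#' @export
sobol_points <- function(n, dims, scramble = FALSE, seed = NULL,
                         skip_zero = FALSE) {
  stopifnot(n >= 1, dims >= 1)
  if (dims > 1500L) stop("Sobol dimension beyond supported direction-number table")
  B <- .SOBOL_BITS
  V <- .direction_numbers(dims)
  total <- n + if (skip_zero) 1L else 0L
  X <- matrix(0, nrow = total, ncol = dims)
  state <- rep(0L, dims)
  if (total > 1L) {
    for (i in 2:total) {
      j <- i - 2L                      # previous index, Gray-code increment
      c <- 1L
      while (j %% 2 == 1) {
        j <- j %/% 2
        c <- c + 1L
      }
      state <- bitwXor(state, as.integer(V[, c]))
      X[i, ] <- state
    }
  }
  if (skip_zero) X <- X[-1L, , drop = FALSE]
  if (scramble) {
    if (is.null(seed)) stop("scramble = TRUE requires a seed")
    shift <- with_seed(as.integer(seed), {
      as.integer(floor(stats::runif(dims) * 2^B))
    })
    for (j in seq_len(dims)) {
      X[, j] <- bitwXor(as.integer(X[, j]), shift[j])
    }
  }
  X / 2^B
}

#' Scale unit-cube points to decision-space bounds
#'
#' Affine map `X = x_min + s * (x_max - x_min)` applied per dimension.
#'
#' @param points matrix of points in `[0, 1]`.
#' @param x_min,x_max per-dimension bounds (recycled if scalar);
#'   `x_min < x_max` elementwise.
#' @return matrix of positions within the bounds.
#' @export
scale_population <- function(points, x_min, x_max) {
  points <- as.matrix(points)
  d <- ncol(points)
  x_min <- rep_len(x_min, d)
  x_max <- rep_len(x_max, d)
  if (any(x_min >= x_max)) stop("x_min must be < x_max elementwise")
  if (any(points < 0) || any(points > 1)) {
    stop("points must lie in [0, 1]")
  }
  sweep(sweep(points, 2L, x_max - x_min, "*"), 2L, x_min, "+")
}
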