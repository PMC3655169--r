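#' Configuration for the three-scale curvelet-style decomposition
#'
#' The decomposition splits the 2-D frequency plane into one low-pass band
#' (the coarse layer), a ring of oriented parabolic wedges at the middle
#' scale (the detail layer), and one high-pass band (the fine layer).
#' With the default 32 detail wedges this yields 1 + 32 + 1 = 34 sub-bands.
#'
#' @param n_scales Number of radial scales; fixed at 3 (coarse/detail/fine).
#' @param n_detail_wedges Number of angular wedges in the detail layer.
#'   Wedges are indexed counter-clockwise from angle 0 and defined on
#'   orientation modulo pi, so coefficients stay real-valued.
#' @param pad_to Square side (power of 2) images are zero-padded to before
#'   the FFT. Must be at least 32 so that all three scales are resolvable.
#' @return An object of class `curvelet_config`.
#' @export
#' @examples
#' cfg <- curvelet_config()
#' subband_count(cfg)  # 34
curvelet_config <- function(n_scales = 3L, n_detail_wedges = 32L, pad_to = 64L) {
  n_scales <- as.integer(n_scales)
  n_detail_wedges <- as.integer(n_detail_wedges)
  pad_to <- as.integer(pad_to)
  if (n_scales != 3L) {
    stop_invalid("only the 3-scale (coarse/detail/fine) configuration is supported")
  }
  if (n_detail_wedges < 1L) {
    stop_invalid("n_detail_wedges must be >= 1 (the detail layer cannot be empty)")
  }
  if (pad_to < 32L || bitwAnd(pad_to, pad_to - 1L) != 0L) {
    stop_invalid("pad_to must be a power of 2 and >= 32, got %d", pad_to)
  }
  structure(
    list(n_scales = n_scales, n_detail_wedges = n_detail_wedges, pad_to = pad_to),
    class = "curvelet_config"
  )
}

#' Number of sub-bands a configuration produces
#'
#' One coarse band, `n_detail_wedges` oriented detail bands, one fine band.
#'
#' @param cfg A [curvelet_config()].
#' @return Integer sub-band count (34 under the default configuration).
#' @export
subband_count <- function(cfg) {
  stopifnot(inherits(cfg, "curvelet_config"))
  1L + cfg$n_detail_wedges + 1L
}

# C1 smoothstep: 0 below 0, 1 above 1, 3t^2 - 2t^3 between.
# Satisfies S(t) + S(1 - t) = 1, which makes adjacent window ramps
# complementary so squared windows sum to exactly 1.
smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# Frequency-domain squared windows for one configuration. Returns a list of
# n x n matrices U2[[j]] with sum_j U2[[j]] == 1 at every frequency (a tight
# frame / Parseval partition). Windows depend only on |omega| and on the
# orientation modulo pi, hence are symmetric under omega -> -omega and the
# sub-band coefficients of a real image are real.
#
# Radial layout (rho = |omega| / Nyquist, in [0, sqrt(2)]):
#   coarse^2 = 1 - u1,  detail^2 = u1 (1 - u2),  fine^2 = u1 u2
# with u1 rising over rho in [0.15, 0.25] and u2 over [0.35, 0.50].
# Angular layout: n_w wedges of width pi/n_w, cross-faded with smoothstep
# ramps of half-width a quarter wedge, periodic in pi.
curvelet_windows <- function(cfg) {
  key <- sprintf("w_%d_%d", cfg$n_detail_wedges, cfg$pad_to)
  cached <- .curvelet_cache[[key]]
  if (!is.null(cached)) return(cached)

  n <- cfg$pad_to
  k <- 0:(n - 1L)
  f <- ifelse(k <= n / 2, k, k - n) / (n / 2)   # normalized frequency in (-1, 1]
  FX <- matrix(f, n, n, byrow = TRUE)           # column frequency
  FY <- matrix(f, n, n)                         # row frequency
  rho <- sqrt(FX^2 + FY^2)
  theta <- atan2(FY, FX) %% pi

  u1 <- smoothstep((rho - 0.15) / 0.10)
  u2 <- smoothstep((rho - 0.35) / 0.15)
  W2 <- vector("list", subband_count(cfg))
  W2[[1L]] <- 1 - u1                            # coarse
  Wd2 <- u1 * (1 - u2)                          # detail ring (to be split)
  W2[[subband_count(cfg)]] <- u1 * u2           # fine

  n_w <- cfg$n_detail_wedges
  tpos <- theta / (pi / n_w)                    # wedge coordinate in [0, n_w)
  for (j in seq_len(n_w)) {
    cj <- j - 0.5                               # wedge centre, CCW from angle 0
    d <- abs(((tpos - cj + n_w / 2) %% n_w) - n_w / 2)   # periodic distance
    # bump: 1 in the wedge core, smoothstep cross-fade to the neighbours
    A2 <- 1 - smoothstep((d - 0.25) / 0.5)
    W2[[1L + j]] <- Wd2 * A2
  }

  scales <- c("coarse", rep("detail", n_w), "fine")
  wedges <- c(1L, seq_len(n_w), 1L)
  out <- list(W2 = W2, scale = scales, wedge = wedges, n = n)
  assign(key, out, envir = .curvelet_cache)
  out
}

.curvelet_cache <- new.env(parent = emptyenv())

pad_image <- function(image, n) {
  nr <- nrow(image); nc <- ncol(image)
  if (nr > n || nc > n) {
    stop_invalid("image (%d x %d) larger than pad_to = %d", nr, nc, n)
  }
  if (nr == n && nc == n) return(image)
  out <- matrix(0, n, n)
  r0 <- floor((n - nr) / 2); c0 <- floor((n - nc) / 2)
  out[r0 + seq_len(nr), c0 + seq_len(nc)] <- image
  out
}

#' Forward three-scale curvelet-style decomposition
#'
#' Decomposes a real 2-D image into 34 sub-bands (under the default
#' configuration): one coarse low-pass band, 32 oriented detail wedges
#' ordered counter-clockwise from angle 0, and one fine high-pass band.
#' The squared frequency windows form a partition of unity, so the
#' decomposition is a tight frame: energy is conserved exactly
#' (Parseval) and [fdct_inverse()] reconstructs the input to machine
#' precision. Sub-band coefficient grids are kept at full `pad_to`
#' resolution (undecimated) and are real-valued.
#'
#' @param image Real matrix, at least 32 x 32; zero-padded (centred) to
#'   `cfg$pad_to` if smaller.
#' @param cfg A [curvelet_config()].
#' @return An object of class `curvelet_decomposition`: a list with
#'   `subbands` (list of 34 entries, each `scale_id`, `wedge_id`, `coeff`),
#'   `source_shape`, and the configuration.
#' @export
#' @examples
#' x <- matrix(rnorm(64 * 64), 64, 64)
#' d <- fdct_forward(x)
#' length(d$subbands)                       # 34
#' e <- sum(vapply(d$subbands, function(s) sum(s$coeff^2), 0))
#' e / sum(x^2)                             # 1 (tight frame)
fdct_forward <- function(image, cfg = curvelet_config()) {
  stopifnot(inherits(cfg, "curvelet_config"))
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L) {
    stop_invalid("image must be a non-empty numeric matrix")
  }
  if (nrow(image) < 32L || ncol(image) < 32L) {
    stop_invalid("image must be at least 32 x 32 for a 3-scale decomposition, got %d x %d",
                 nrow(image), ncol(image))
  }
  src <- dim(image)
  w <- curvelet_windows(cfg)
  n <- w$n
  X <- stats::fft(pad_image(image, n))
  subbands <- vector("list", length(w$W2))
  for (j in seq_along(w$W2)) {
    cj <- Re(stats::fft(X * sqrt(w$W2[[j]]), inverse = TRUE)) / (n * n)
    subbands[[j]] <- list(scale_id = w$scale[j], wedge_id = w$wedge[j], coeff = cj)
  }
  structure(
    list(subbands = subbands, source_shape = src, config = cfg),
    class = "curvelet_decomposition"
  )
}

#' Inverse curvelet-style reconstruction
#'
#' Adjoint of [fdct_forward()]. Because the squared windows sum to 1,
#' the adjoint is an exact inverse: the round-trip relative error is at
#' machine precision.
#'
#' @param d A `curvelet_decomposition` from [fdct_forward()].
#' @param cfg The same configuration used for the forward transform.
#' @return The reconstructed image, cropped back to the original shape.
#' @export
fdct_inverse <- function(d, cfg = d$config) {
  stopifnot(inherits(d, "curvelet_decomposition"), inherits(cfg, "curvelet_config"))
  w <- curvelet_windows(cfg)
  n <- w$n
  if (length(d$subbands) != length(w$W2)) {
    stop_invalid("decomposition has %d sub-bands but config expects %d",
                 length(d$subbands), length(w$W2))
  }
  acc <- matrix(0 + 0i, n, n)
  for (j in seq_along(w$W2)) {
    cj <- d$subbands[[j]]$coeff
    if (!all(dim(cj) == n)) {
      stop_invalid("sub-band %d has shape %d x %d, expected %d x %d",
                   j, nrow(cj), ncol(cj), n, n)
    }
    acc <- acc + stats::fft(cj) * sqrt(w$W2[[j]])
  }
  xh <- Re(stats::fft(acc, inverse = TRUE)) / (n * n)
  src <- d$source_shape
  r0 <- floor((n - src[1]) / 2); c0 <- floor((n - src[2]) / 2)
  xh[r0 + seq_len(src[1]), c0 + seq_len(src[2]), drop = FALSE]
}

# Wedge index (1..n_w, CCW from angle 0) whose core contains a given
# orientation in radians; used by tests to predict where an oriented
# edge concentrates its energy.
wedge_for_angle <- function(angle, cfg = curvelet_config()) {
  n_w <- cfg$n_detail_wedges
  1L + (floor((angle %% pi) / (pi / n_w)) %% n_w)
}
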