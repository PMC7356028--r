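# Decayed-weight kernels and same-size 2-D convolution: each residue
# pair's "environment" value averages its neighborhood in the pair grid.

#' Build a decayed-weight square kernel
#'
#' Weights depend only on the Chebyshev ring distance `r` from the center:
#' `w(r) = 1 - r * decay`. With `normalized = TRUE` (default) the weights
#' are divided by their sum, so convolution is a weighted neighborhood
#' average.
#'
#' @param size odd kernel size, one of 3, 5, 7.
#' @param decay per-ring weight decrease, in `[0, 0.25]`.
#' @param normalized divide weights by their sum (default `TRUE`).
#' @return A `ppi_kernel`: list with `size`, `decay`, `normalized`,
#'   `weights` (size x size matrix).
#' @export
make_kernel <- function(size = 5L, decay = 0.10, normalized = TRUE) {
  if (!is_count(size) || !(size %in% c(3L, 5L, 7L)))
    stop_ppiface("kernel size must be 3, 5 or 7 (got %s)", format(size))
  if (!is.numeric(decay) || decay < 0 || decay > 0.25)
    stop_ppiface("decay must lie in [0, 0.25] (got %s)", format(decay))
  half <- (size - 1L) / 2L
  off <- seq(-half, half)
  r <- outer(abs(off), abs(off), pmax)       # Chebyshev distance to center
  w <- 1 - r * decay
  if (any(w <= 0)) stop_ppiface("decay %s makes kernel weights non-positive",
                                format(decay))
  if (normalized) w <- w / sum(w)
  structure(list(size = as.integer(size), decay = decay,
                 normalized = normalized, weights = w),
            class = "ppi_kernel")
}

#' @export
print.ppi_kernel <- function(x, ...) {
  cat(sprintf("<ppi_kernel> %dx%d, decay %.2f, %s\n", x$size, x$size,
              x$decay, if (x$normalized) "normalized" else "unnormalized"))
  invisible(x)
}

kernel_spec <- function(kernel) {
  list(size = kernel$size, decay = kernel$decay,
       normalized = kernel$normalized)
}

#' Same-size 2-D convolution with zero padding
#'
#' Cross-correlation of `m` with the kernel weights, zero-padded outside
#' the matrix so the output has the input's shape. The kernels built by
#' [make_kernel()] are centro-symmetric, so cross-correlation and flipped
#' convolution coincide.
#'
#' @param m numeric matrix.
#' @param kernel a `ppi_kernel`, or a plain square weight matrix of odd
#'   size.
#' @return Matrix of the same shape as `m`.
#' @export
convolve_same <- function(m, kernel) {
  w <- if (inherits(kernel, "ppi_kernel")) kernel$weights else kernel
  k <- nrow(w)
  stopifnot(is.matrix(w), k == ncol(w), k %% 2L == 1L)
  half <- (k - 1L) / 2L
  M <- nrow(m); N <- ncol(m)
  out <- matrix(0, M, N)
  for (di in seq(-half, half)) {
    rlo <- max(1L, 1L - di); rhi <- min(M, M - di)
    if (rlo > rhi) next
    ri <- rlo:rhi                           # output rows receiving m[ri+di, ]
    for (dj in seq(-half, half)) {
      clo <- max(1L, 1L - dj); chi <- min(N, N - dj)
      if (clo > chi) next
      cj <- clo:chi
      wij <- w[di + half + 1L, dj + half + 1L]
      out[ri, cj] <- out[ri, cj] + wij * m[ri + di, cj + dj, drop = FALSE]
    }
  }
  out
}

#' Derive environment features for a base stack
#'
#' Convolves each of the nine base matrices with the kernel and appends the
#' results, min-max rescaled, under "E"-prefixed names (ECMI, ECCM, ...).
#'
#' @param stack a 9-matrix base `feature_stack`.
#' @param kernel a `ppi_kernel`.
#' @return An 18-matrix `feature_stack` carrying the kernel spec as
#'   attribute `kernel`.
#' @export
derive_env_stack <- function(stack, kernel = make_kernel()) {
  stopifnot(inherits(stack, "feature_stack"), inherits(kernel, "ppi_kernel"))
  if (!identical(names(stack), feature_names()))
    stop_ppiface("base stack must have exactly the 9 canonical features")
  env <- lapply(stack, function(m) minmax_scale(convolve_same(m, kernel)))
  names(env) <- paste0("E", names(stack))
  out <- c(unclass(stack), env)
  structure(out, M = attr(stack, "M"), N = attr(stack, "N"),
            kernel = kernel_spec(kernel), class = "feature_stack")
}
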