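#' Masked 3-D Gaussian smoothing
#'
#' Convolves a volume with a truncated, separable Gaussian kernel
#' (default 5 x 5 x 5 voxels, sigma = 1). Undefined voxels (NA, or outside
#' `mask`) are excluded and the kernel weights are renormalized over the
#' defined neighbours, so a constant map is reproduced exactly everywhere,
#' including at edges. Output voxels that were undefined stay undefined.
#'
#' @param x numeric 3-D array (may contain NA) or a `temperature_map`.
#' @param kernel_size odd kernel width in voxels (applied per axis).
#' @param sigma Gaussian SD in voxels.
#' @param mask optional logical array of defined voxels; defaults to
#'   `!is.na(x)`.
#' @param ... passed to methods.
#' @return object of the same class with smoothed values.
#' @export
gaussian_smooth <- function(x, kernel_size = 5L, sigma = 1, ...) {
  UseMethod("gaussian_smooth")
}

#' @rdname gaussian_smooth
#' @export
gaussian_smooth.default <- function(x, kernel_size = 5L, sigma = 1,
                                    mask = NULL, ...) {
  stopifnot(length(dim(x)) == 3L)
  if (kernel_size %% 2L != 1L) stop("`kernel_size` must be odd")
  if (is.null(mask)) mask <- !is.na(x)
  half <- (kernel_size - 1L) / 2L
  g <- stats::dnorm(-half:half, sd = sigma)
  xm <- x
  xm[!mask] <- 0
  num <- separable_conv3(xm, g)
  den <- separable_conv3(array(as.numeric(mask), dim(x)), g)
  out <- array(NA_real_, dim(x))
  ok <- mask & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' @rdname gaussian_smooth
#' @export
gaussian_smooth.temperature_map <- function(x, kernel_size = 5L, sigma = 1, ...) {
  x$values <- gaussian_smooth.default(x$values, kernel_size, sigma,
                                      mask = x$qc_mask)
  x
}

# zero-padded separable 3-D convolution with the same 1-D kernel per axis
separable_conv3 <- function(x, g) {
  d <- dim(x)
  half <- (length(g) - 1L) / 2L
  conv_axis <- function(a, axis) {
    out <- array(0, dim(a))
    for (t in seq_along(g)) {
      s <- t - 1L - half
      if (s == 0) { out <- out + g[t] * a; next }
      n <- d[axis]
      src <- if (s > 0) (1 + s):n else 1:(n + s)
      dst <- if (s > 0) 1:(n - s) else (1 - s):n
      idx_src <- switch(axis,
                        list(src, TRUE, TRUE), list(TRUE, src, TRUE), list(TRUE, TRUE, src))
      idx_dst <- switch(axis,
                        list(dst, TRUE, TRUE), list(TRUE, dst, TRUE), list(TRUE, TRUE, dst))
      slice <- do.call(`[`, c(list(a), idx_src, list(drop = FALSE)))
      tmp <- array(0, dim(a))
      tmp <- do.call(`[<-`, c(list(tmp), idx_dst, list(slice)))
      out <- out + g[t] * tmp
    }
    out
  }
  conv_axis(conv_axis(conv_axis(x, 1L), 2L), 3L)
}
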