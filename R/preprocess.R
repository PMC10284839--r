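#' Spillover compensation
#'
#' Inverts the linear channel mixing `observed = true %*% S` per pixel by
#' solving the shared linear system once (one matrix factorization for the
#' whole stack), then clamps negative solutions to zero, since intensities
#' are counts. With an identity spillover matrix the stack is returned
#' unchanged.
#'
#' @param x a [ChannelStack] or a pixels-by-channels (or cells-by-channels)
#'   numeric matrix.
#' @param S a [SpilloverMatrix] whose channels match `x` in order.
#' @return object of the same class as `x`, compensated.
#' @examples
#' S <- spilloverMatrix(matrix(c(1, 0, 0.1, 1), 2), channels = c("a", "b"))
#' compensate(matrix(c(1, 1.1), 1), S)   # recovers (1, 1)
#' @export
setGeneric("compensate", function(x, S) standardGeneric("compensate"))

.compensateMatrix <- function(m, S) {
  Smat <- as.matrix(S)
  if (ncol(m) != nrow(Smat))
    stop("spillover matrix has ", nrow(Smat), " channels (",
         paste(head(channelNames(S), 4), collapse = ", "),
         ", ...) but the input has ", ncol(m))
  # observed = true %*% S  =>  true' = solve(S', observed')
  out <- t(solve(t(Smat), t(m)))
  out[out < 0] <- 0
  dimnames(out) <- dimnames(m)
  out
}

#' @rdname compensate
#' @export
setMethod("compensate", "matrix", function(x, S) .compensateMatrix(x, S))

#' @rdname compensate
#' @export
setMethod("compensate", "ChannelStack", function(x, S) {
  if (!identical(channelNames(x), channelNames(S)))
    stop("channel names of the stack (", paste(head(channelNames(x), 4),
         collapse = ", "), ", ...) do not match the spillover matrix")
  d <- dim(x@pixels)
  m <- matrix(x@pixels, d[1] * d[2], d[3])
  x@pixels <- array(.compensateMatrix(m, S), d)
  x
})

#' Median denoising
#'
#' Replaces every pixel by the median of its `window x window`
#' neighborhood, each channel independently. Borders are zero-padded, which
#' darkens border pixels of bright constant regions (the window then
#' contains padding zeros); this matches the behaviour of the standard
#' fixed-window median filter the pipeline emulates and is documented
#' because it changes border values.
#'
#' @param x a [ChannelStack] or a single-channel numeric matrix.
#' @param window odd window side length (default 3).
#' @return same class as `x`, filtered.
#' @export
setGeneric("medianDenoise", function(x, window = 3L) standardGeneric("medianDenoise"))

.medianFilterMatrix <- function(m, window) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (window == 1L) return(m)
  r <- window %/% 2L
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2 * r, W + 2 * r)
  pad[(r + 1):(r + H), (r + 1):(r + W)] <- m
  # stack the window^2 shifted copies and take the row-wise median
  shifts <- matrix(0, H * W, window^2)
  k <- 1L
  for (dy in 0:(window - 1L)) for (dx in 0:(window - 1L)) {
    shifts[, k] <- pad[(1 + dy):(H + dy), (1 + dx):(W + dx)]
    k <- k + 1L
  }
  matrix(.rowMedianSorted(shifts), H, W)
}

# Exact row-wise median of a small fixed number of columns via a
# vectorized compare-exchange (bubble) sorting network: O(k^2) pmin/pmax
# passes over all rows at once, no per-pixel function calls.
.rowMedianSorted <- function(p) {
  k <- ncol(p)
  cols <- lapply(seq_len(k), function(j) p[, j])
  for (i in seq_len(k - 1)) for (j in seq_len(k - i)) {
    lo <- pmin(cols[[j]], cols[[j + 1]])
    cols[[j + 1]] <- pmax(cols[[j]], cols[[j + 1]])
    cols[[j]] <- lo
  }
  if (k %% 2L == 1L) cols[[(k + 1L) %/% 2L]]
  else (cols[[k %/% 2L]] + cols[[k %/% 2L + 1L]]) / 2
}

#' @rdname medianDenoise
#' @export
setMethod("medianDenoise", "matrix", function(x, window = 3L)
  .medianFilterMatrix(x, window))

#' @rdname medianDenoise
#' @export
setMethod("medianDenoise", "ChannelStack", function(x, window = 3L) {
  for (i in seq_len(dim(x@pixels)[3]))
    x@pixels[, , i] <- .medianFilterMatrix(x@pixels[, , i], window)
  x
})

#' Contrast enhancement to the 0-255 range
#'
#' Per channel, linearly maps the `saturation` and `1 - saturation`
#' intensity quantiles to 0 and 255 and clips outside that range, so each
#' channel uses the full 8-bit display range with a small saturated tail at
#' either end. A constant channel maps to all zeros.
#'
#' @param x a [ChannelStack] or numeric matrix (one channel).
#' @param saturation fraction saturated per tail, in `[0, 0.5)`;
#'   default 0.01.
#' @return same class as `x`, rescaled to `[0, 255]`.
#' @export
setGeneric("enhanceContrast", function(x, saturation = 0.01)
  standardGeneric("enhanceContrast"))

.enhanceMatrix <- function(m, saturation) {
  if (saturation < 0 || saturation >= 0.5)
    stop("saturation must be in [0, 0.5)")
  q <- quantile(m, c(saturation, 1 - saturation), names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(m), ncol(m)))
  out <- 255 * (m - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' @rdname enhanceContrast
#' @export
setMethod("enhanceContrast", "matrix", function(x, saturation = 0.01)
  .enhanceMatrix(x, saturation))

#' @rdname enhanceContrast
#' @export
setMethod("enhanceContrast", "ChannelStack", function(x, saturation = 0.01) {
  for (i in seq_len(dim(x@pixels)[3]))
    x@pixels[, , i] <- .enhanceMatrix(x@pixels[, , i], saturation)
  x
})

#' Run the full image preprocessing chain
#'
#' Compensation, then median denoising, then contrast enhancement, in that
#' order.
#'
#' @param stack a [ChannelStack].
#' @param S a [SpilloverMatrix] (skipped when `NULL`).
#' @param window median filter window (odd).
#' @param saturation contrast saturation fraction per tail.
#' @param enhance apply the contrast step (disable when absolute
#'   intensities must be preserved for quantification).
#' @return preprocessed [ChannelStack].
#' @export
preprocessStack <- function(stack, S = NULL, window = 3L, saturation = 0.01,
                            enhance = FALSE) {
  if (!is.null(S)) stack <- compensate(stack, S)
  stack <- medianDenoise(stack, window)
  if (enhance) stack <- enhanceContrast(stack, saturation)
  stack
}
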