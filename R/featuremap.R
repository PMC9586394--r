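#' Feature maps
#'
#' Feature maps are plain numeric arrays in channel-first layout:
#' `dim = c(C, H, W)` for a single map, `dim = c(C, H, W, N)` for a batch of
#' `N` maps. A bare `H x W` matrix is accepted anywhere a feature map is and
#' is treated as a single-channel map. All operator functions return a result
#' of the same rank as their input.
#'
#' @name featuremap
NULL

# Coerce to a 4D batch array, remembering the input rank so results can be
# returned at the caller's rank.
fm4d <- function(x) {
  if (is.null(dim(x))) stop_config("feature map must be a matrix or array")
  d <- dim(x)
  rank <- length(d)
  if (rank == 2L) {
    dim(x) <- c(1L, d[1], d[2], 1L)
  } else if (rank == 3L) {
    dim(x) <- c(d, 1L)
  } else if (rank != 4L) {
    stop_config("feature map must have 2, 3 or 4 dimensions, got ", rank)
  }
  if (any(dim(x) < 1L)) stop_config("feature map dimensions must be >= 1")
  if (!all(is.finite(x))) stop_config("feature map contains non-finite values")
  list(a = x, rank = rank)
}

fm_restore <- function(a, rank) {
  d <- dim(a)
  if (rank == 2L) {
    dim(a) <- d[2:3]
  } else if (rank == 3L) {
    dim(a) <- d[1:3]
  }
  a
}

#' Rectified linear activation
#'
#' Elementwise `max(x, 0)` on a feature map (or any numeric array).
#'
#' @param x numeric array.
#' @return array of the same shape with negative entries set to zero.
#' @examples
#' relu(matrix(c(-1, 2, 0, -3), 2))
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Elementwise sum of feature maps
#'
#' Sums a list of identically shaped feature maps cell by cell. A shape
#' mismatch is an error: inside the pooling blocks this is the guard that the
#' directional paths were shape-reconciled before combination.
#'
#' @param terms list of numeric arrays sharing one shape.
#' @return array of that shape containing the cellwise sum.
#' @examples
#' elementwise_sum(list(diag(2), diag(2)))
#' @export
elementwise_sum <- function(terms) {
  if (!is.list(terms) || length(terms) == 0L)
    stop_config("elementwise_sum needs a non-empty list of arrays")
  d0 <- dim(terms[[1]])
  out <- terms[[1]]
  for (t in terms[-1]) {
    if (!identical(dim(t), d0))
      stop_config("elementwise_sum shape mismatch: ",
                  paste(d0, collapse = "x"), " vs ",
                  paste(dim(t), collapse = "x"))
    out <- out + t
  }
  out
}
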