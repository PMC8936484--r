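#' Mean squared error over all points and channels
#'
#' @param predicted Numeric vector or matrix.
#' @param target Same shape as `predicted`.
#' @return Mean of the squared differences, pooled over every point and
#'   channel.
#' @export
#' @examples
#' mean_squared_error(c(0, 2), c(0, 0))  # 2
mean_squared_error <- function(predicted, target) {
  if (length(predicted) == 0L || length(predicted) != length(target)) {
    stop("predicted and target must have equal nonzero lengths",
         call. = FALSE)
  }
  mean((as.numeric(predicted) - as.numeric(target))^2)
}

#' Node-wise absolute-error curves between two trajectories
#'
#' Computes |surrogate - reference| per grid node and state channel, in
#' physical units. The two trajectories must share the same time grid.
#'
#' @param surrogate,reference `eco_trajectory` objects on identical grids.
#' @return A data frame with columns `t` and one absolute-error column per
#'   state channel (`S`, `I`, `P` for the model system).
#' @export
absolute_error_curves <- function(surrogate, reference) {
  if (length(surrogate$times) != length(reference$times) ||
      any(abs(surrogate$times - reference$times) >
            1e-10 * pmax(1, abs(reference$times)))) {
    stop("trajectories are on different time grids", call. = FALSE)
  }
  ae <- abs(surrogate$states - reference$states)
  df <- as.data.frame(ae)
  if (ncol(df) == 3L) names(df) <- c("S", "I", "P")
  cbind(t = reference$times, df)
}

#' Equal-width histogram of signed fitting errors
#'
#' Bins span `[min, max]` of the signed errors with `n_bins` equal widths;
#' counts always sum to the number of errors. A degenerate range (all
#' errors equal) collapses to a single occupied bin centered at that value.
#'
#' @param errors Nonempty numeric vector of signed residuals.
#' @param n_bins Number of bins (default 20, the fitting-tool convention).
#' @return A list with `centers` and `counts`.
#' @export
#' @examples
#' error_histogram(c(-1, 0, 1), n_bins = 4)
error_histogram <- function(errors, n_bins = 20L) {
  if (length(errors) == 0L) {
    stop("errors must be nonempty", call. = FALSE)
  }
  stopifnot(n_bins >= 1L)
  lo <- min(errors); hi <- max(errors)
  if (hi <= lo) {
    return(list(centers = lo, counts = length(errors)))
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  w <- (hi - lo) / n_bins
  u <- (errors - lo) / w
  j <- floor(u)
  idx <- pmin(pmax(j + 1L, 1L), n_bins)
  # values landing exactly on an interior edge are assigned toward the
  # center of the range, which keeps mirror-symmetric inputs
  # mirror-symmetric in the counts
  on_edge <- u == j & j >= 1L & j <= n_bins - 1L
  idx[on_edge & u >= n_bins / 2] <- j[on_edge & u >= n_bins / 2]
  counts <- tabulate(idx, nbins = n_bins)
  list(centers = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
       counts = counts)
}

#' Pearson correlation between fitted and target values
#'
#' The regression statistic R of the fitting-tool diagnostic plots:
#' plain Pearson correlation, invariant under positive affine transforms of
#' either argument.
#'
#' @param predicted,target Numeric vectors of equal length >= 2; the target
#'   must not be constant.
#' @return A value in `[-1, 1]`.
#' @export
regression_r <- function(predicted, target) {
  if (length(predicted) != length(target) || length(target) < 2L) {
    stop("predicted and target must have equal lengths of at least 2",
         call. = FALSE)
  }
  if (stats::sd(target) == 0) {
    stop("correlation undefined: target is constant", call. = FALSE)
  }
  stats::cor(as.numeric(predicted), as.numeric(target))
}
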