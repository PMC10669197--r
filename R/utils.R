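#' @useDynLib vesselmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef integrate lm median predict quantile rnorm
#'   runif sd setNames smooth.spline
#' @importFrom utils head read.csv tail write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

vm_stop <- function(..., class = "vm_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.check_num3 <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 3L || anyNA(x))
    vm_stop(name, " must be a numeric vector of length 3")
  if (positive && any(x <= 0))
    vm_stop(name, " must be positive")
  as.numeric(x)
}

# derive a child RNG seed from a base seed, kept inside 32-bit integer range
.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * i) %% 2147483647)
}

# linear-interpolation resampling of a polyline at uniform arc-length steps
.resample_polyline <- function(pts, n = NULL, step = NULL) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (is.null(n)) n <- max(3L, as.integer(round(total / step)) + 1L)
  tgt <- seq(0, total, length.out = n)
  out <- vapply(seq_len(3), function(j) approx(s, pts[, j], xout = tgt,
                                               ties = "ordered")$y,
                numeric(length(tgt)))
  out
}
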