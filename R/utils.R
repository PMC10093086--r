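#' @importFrom rlang .data abort warn
#' @importFrom stats fft rnorm runif rpois quantile sd var median prcomp
#'   p.adjust pnorm qnorm lm coef setNames predict
#' @importFrom utils head tail
#' @importFrom tools file_ext
NULL

# numerical guard used throughout for ratios with possibly-zero denominators
.EPS <- 1e-12

`%||%` <- function(x, y) if (is.null(x)) y else x

# pull the intensity matrix out of whatever image-ish object we are handed
as_intensity_matrix <- function(x) {
  if (is.matrix(x) && is.numeric(x)) return(x)
  if (inherits(x, "mt_roi") || inherits(x, "mt_image")) return(x$intensities)
  abort("expected a numeric matrix, `mt_image`, or `mt_roi`")
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < lower) {
    abort(sprintf("`%s` must be an integer >= %d", name, lower))
  }
  invisible(as.integer(x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# base-2 entropy with the 0 * log 0 == 0 convention
entropy2 <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}
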