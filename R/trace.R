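#' Time-series trace container
#'
#' A minimal container for uniformly or non-uniformly sampled traces of
#' sarcomere length (um), calcium (uM) or force (relative tension units).
#'
#' @param t time grid (ms), strictly increasing.
#' @param v values, same length as `t`.
#' @param kind one of `"SL"`, `"Ca"`, `"force"`.
#' @return An object of class `"trace"`.
#' @examples
#' tr <- trace(0:10, sin(0:10 / 3) + 2, "SL")
#' @export
trace <- function(t, v, kind = c("SL", "Ca", "force")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(t), is.numeric(v))
  if (length(t) != length(v)) stop("t and v must have the same length")
  if (length(t) > 1 && any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(!is.finite(t)) || any(!is.finite(v))) stop("t and v must be finite")
  structure(list(t = as.numeric(t), v = as.numeric(v), kind = kind),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace: %s, %d samples, t in [%.4g, %.4g] ms, v in [%.6g, %.6g]>\n",
              x$kind, length(x$t), min(x$t), max(x$t), min(x$v), max(x$v)))
  invisible(x)
}

#' @export
as.data.frame.trace <- function(x, ...) {
  data.frame(t_ms = x$t, value = x$v)
}

#' @export
plot.trace <- function(x, ...) {
  ylab <- switch(x$kind, SL = "Sarcomere length (um)", Ca = "Calcium (uM)",
                 force = "Tension (rel. units)")
  graphics::plot(x$t, x$v, type = "l", xlab = "Time (ms)", ylab = ylab, ...)
  invisible(x)
}
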