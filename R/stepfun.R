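#' Right-continuous step functions
#'
#' Estimated survival curves, cumulative hazards and cumulative incidence
#' functions are all right-continuous piecewise-constant functions of time.
#' `cr_stepfun()` builds such a function from its jump times and the value
#' taken immediately to the right of each jump; [sf_at()] evaluates it and
#' [sf_left()] returns left limits, which several estimators (Aalen-Johansen,
#' IPCW weights) need explicitly.
#'
#' @param times strictly increasing jump times (may be empty).
#' @param values value of the function on `[times[i], times[i+1])`.
#' @param initial_value value on `[0, times[1])`; defaults to 1, the natural
#'   start for survival-type curves.
#' @param extra optional named list of parallel vectors (standard errors,
#'   at-risk counts, event counts) carried alongside the curve.
#' @return An object of class `cr_stepfun`.
#' @export
cr_stepfun <- function(times, values, initial_value = 1, extra = list()) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  structure(
    c(list(times = times, values = values,
           initial_value = as.numeric(initial_value)), extra),
    class = "cr_stepfun")
}

#' Evaluate a step function
#'
#' @param sf a [cr_stepfun()].
#' @param t vector of evaluation times.
#' @return `sf(t)`, using right-continuity: the value at a jump time is the
#'   post-jump value.
#' @export
sf_at <- function(sf, t) {
  idx <- findInterval(t, sf$times)
  ifelse(idx == 0, sf$initial_value, sf$values[pmax(idx, 1L)])
}

#' Left limit of a step function
#'
#' @inheritParams sf_at
#' @return `sf(t-)`: the value just before `t`.
#' @export
sf_left <- function(sf, t) {
  idx <- findInterval(t, sf$times, left.open = TRUE)
  ifelse(idx == 0, sf$initial_value, sf$values[pmax(idx, 1L)])
}

#' @export
print.cr_stepfun <- function(x, ...) {
  cat(sprintf("<cr_stepfun> %d jumps, start %.4g", length(x$times),
              x$initial_value))
  if (length(x$times))
    cat(sprintf(", range [%.4g, %.4g], final %.4g", min(x$times),
                max(x$times), x$values[length(x$values)]))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.cr_stepfun <- function(x, ...) {
  df <- data.frame(time = c(0, x$times),
                   value = c(x$initial_value, x$values))
  for (nm in setdiff(names(x), c("times", "values", "initial_value"))) {
    if (length(x[[nm]]) == length(x$times))
      df[[nm]] <- c(NA, x[[nm]])
  }
  df
}
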