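#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an optimization result into per-electrode currents
#'
#' @param x An `if_opt`.
#' @param ... Unused.
#' @return A tibble with `electrode`, `source` (`"single"` or
#'   `"s1"`/`"s2"`), `current_mA`.
#' @export
tidy.if_opt <- function(x, ...) {
  one <- function(s, tag) {
    ids <- attr(s, "ids")
    tibble::tibble(
      electrode = if (is.null(ids)) as.character(seq_along(s)) else ids,
      source = tag,
      current_mA = as.numeric(s))
  }
  if (!is.null(x$s1)) {
    dplyr::bind_rows(one(x$s1, "s1"), one(x$s2, "s2"))
  } else {
    one(x$s, "single")
  }
}

#' One-row summary of an optimization result
#'
#' @param x An `if_opt`.
#' @param ... Unused.
#' @return A one-row tibble: `objective`, power used vs cap, per-source
#'   total currents, feasibility.
#' @export
glance.if_opt <- function(x, ...) {
  if (!is.null(x$s1)) {
    tibble::tibble(objective = x$objective,
                   envelope_power = x$envelope_power, p_max = x$p_max,
                   sum_abs_s1 = x$sum_abs_s1, sum_abs_s2 = x$sum_abs_s2,
                   feasible = x$feasible)
  } else {
    tibble::tibble(objective = x$objective, power = x$power, p_max = x$p_max,
                   sum_abs_s = x$sum_abs_s, feasible = x$feasible)
  }
}

#' Tidy a power-budget sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return The sweep rows as a plain tibble with a `grand_optimal` flag.
#' @export
tidy.sweep_result <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x)[names(x)])
  out$grand_optimal <- seq_len(nrow(out)) == (attr(x, "grand_optimal") %||% -1L)
  out
}

#' One-row summary of a sweep: its grand-optimal point
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A one-row tibble with the grand-optimal `p_max`, `exponent`,
#'   `envelope_target`, `focality_cm` and source currents.
#' @export
glance.sweep_result <- function(x, ...) {
  go <- attr(x, "grand_optimal")
  if (is.na(go)) return(tibble::tibble())
  tibble::tibble(
    target = attr(x, "target")$name,
    exponent = x$exponent[go], p_max = x$p_max[go],
    objective = x$objective[go],
    envelope_target = x$envelope_target[go],
    focality_cm = x$focality_cm[go],
    sum_abs_s1 = x$sum_abs_s1[go], sum_abs_s2 = x$sum_abs_s2[go])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
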