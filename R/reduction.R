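#' Limit the number of active electrodes in a current pattern
#'
#' Implements the electrode-reduction rule used when few implanted
#' electrodes are wanted: for the anode pole and the cathode pole
#' separately, sort electrodes by absolute current, keep the minimal prefix
#' whose cumulative absolute current reaches at least `fraction` of that
#' pole's total (ties with the last kept electrode are also kept, which
#' makes the rule order-independent), zero out the rest, and rescale each
#' pole proportionally so that the pattern again carries the full budget:
#' anode total = cathode total = `I_max / 2`, restoring `sum(s) = 0` and
#' `sum(|s|) = I_max`.
#'
#' @param s A [current_pattern()] (its `I_max` attribute is the rescale
#'   budget) or plain numeric vector.
#' @param fraction Minimum kept fraction of each pole's total absolute
#'   current; `0 < fraction <= 1`. Default 0.75.
#' @param I_max Budget when `s` is a plain vector.
#' @return A `reduction_result` list: `s_limited` ([current_pattern()]),
#'   `kept` (logical), `kept_ids`, `kept_fraction_anode`,
#'   `kept_fraction_cathode`, `n_kept`.
#' @export
limit_electrodes <- function(s, fraction = 0.75, I_max = NULL) {
  if (inherits(s, "current_pattern")) {
    if (is.null(I_max)) I_max <- attr(s, "I_max")
    ids <- attr(s, "ids")
    src <- attr(s, "source")
  } else {
    ids <- names(s)
    src <- "single"
  }
  if (is.null(I_max)) I_max <- 1
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  s <- as.numeric(s)
  keep_pole <- function(idx) {
    if (length(idx) == 0L) return(integer(0))
    mag <- abs(s[idx])
    tot <- sum(mag)
    if (tot == 0) return(integer(0))
    ord <- order(mag, decreasing = TRUE)
    cum <- cumsum(mag[ord])
    n_keep <- which(cum >= fraction * tot - 1e-12)[1L]
    thr <- mag[ord[n_keep]]
    idx[mag >= thr - 1e-12]  # extend to ties with the last kept electrode
  }
  anode <- which(s > 0)
  cathode <- which(s < 0)
  keep_a <- keep_pole(anode)
  keep_c <- keep_pole(cathode)
  frac_a <- if (length(anode)) sum(abs(s[keep_a])) / sum(abs(s[anode])) else NA_real_
  frac_c <- if (length(cathode)) sum(abs(s[keep_c])) / sum(abs(s[cathode])) else NA_real_

  s_new <- numeric(length(s))
  if (length(keep_a)) s_new[keep_a] <- s[keep_a] * (I_max / 2) / sum(abs(s[keep_a]))
  if (length(keep_c)) s_new[keep_c] <- s[keep_c] * (I_max / 2) / sum(abs(s[keep_c]))
  if (length(keep_a) == 0L || length(keep_c) == 0L) {
    # a silent pole cannot be rescaled; record and return the zero pattern
    warning("a pole carries no current; limited pattern left empty", call. = FALSE)
    s_new <- numeric(length(s))
  }
  kept <- seq_along(s) %in% c(keep_a, keep_c)
  structure(list(
    s_limited = current_pattern(s_new, ids = ids, I_max = I_max, source = src),
    kept = kept,
    kept_ids = if (!is.null(ids)) ids[kept] else which(kept),
    kept_fraction_anode = frac_a,
    kept_fraction_cathode = frac_c,
    n_kept = sum(kept)
  ), class = "reduction_result")
}

#' Limit both sources of an interferential solution
#'
#' Applies [limit_electrodes()] to `s1` and `s2` of an interferential
#' optimization result and reports the union electrode count (an electrode
#' counts once if kept by either source or pole — the number of implants
#' needed).
#'
#' @param opt An `if_opt` with `s1` and `s2`.
#' @param fraction Kept fraction per pole (default 0.75).
#' @return A list: `r1`, `r2` (`reduction_result`s), `n_electrodes`
#'   (union), `kept_ids`.
#' @export
limit_electrodes_pair <- function(opt, fraction = 0.75) {
  stopifnot(inherits(opt, "if_opt"), !is.null(opt$s1))
  r1 <- limit_electrodes(opt$s1, fraction)
  r2 <- limit_electrodes(opt$s2, fraction)
  kept <- r1$kept | r2$kept
  ids <- attr(opt$s1, "ids")
  list(r1 = r1, r2 = r2, n_electrodes = sum(kept),
       kept_ids = if (!is.null(ids)) ids[kept] else which(kept))
}
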