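#' Credit ledger: cashed versus remaining interactions
#'
#' Bookkeeping for the credit of ecological interactions. `credit0` is the
#' number of interactions available to rewire at release; `cashed(t)` is the
#' cumulative number rewired by step (or time bin) `t`; `remaining(t)` is the
#' complement. The ledger enforces conservation:
#' `cashed(t) + remaining(t) = credit0` at every `t`, with `remaining`
#' non-increasing and non-negative.
#'
#' @param cashed non-decreasing, non-negative vector of cumulative rewired
#'   counts (one value per step or bin).
#' @param credit0 the initial credit; must be at least `max(cashed)`.
#' @param steps optional step/bin labels (defaults to `0:(length(cashed)-1)`).
#' @return a `credit_ledger`: list with `credit0`, `steps`, `cashed`,
#'   `remaining`.
#' @examples
#' credit_ledger(c(0, 10, 25), credit0 = 25)
#' @export
credit_ledger <- function(cashed, credit0, steps = NULL) {
  if (length(cashed) < 1L) stop("cashed must have at least one step")
  if (any(is.na(cashed)) || any(cashed < 0)) {
    stop("cashed counts must be non-negative")
  }
  if (is.unsorted(cashed)) stop("cashed counts must be non-decreasing")
  if (credit0 < 0) stop("credit0 must be non-negative")
  if (max(cashed) > credit0) {
    stop("credit0 (", credit0, ") is smaller than the maximal cashed count (",
         max(cashed), "): inconsistent inputs")
  }
  steps <- steps %||% (seq_along(cashed) - 1L)
  structure(
    list(credit0 = credit0, steps = steps, cashed = cashed,
         remaining = credit0 - cashed),
    class = "credit_ledger"
  )
}

#' Derive a credit ledger from a simulated trajectory
#'
#' Converts a rewiring trajectory into cashed/remaining credit bookkeeping,
#' either for one replicate or for the across-replicate mean curve (in which
#' case cashed counts are fractional but conservation still holds exactly).
#'
#' @param traj a [simulate_rewiring()] trajectory.
#' @param credit0 the initial credit; defaults to the partner-set degree,
#'   which force-seeding makes the exact asymptote.
#' @param replicate replicate index, or `NULL` (default) for the mean curve.
#' @return a [credit_ledger()].
#' @export
ledger_from_trajectory <- function(traj, credit0 = traj$degree,
                                   replicate = NULL) {
  stopifnot(inherits(traj, "rewiring_trajectory"))
  cashed <- if (is.null(replicate)) {
    colMeans(traj$richness)
  } else {
    if (replicate < 1 || replicate > traj$n_replicates) {
      stop("replicate index out of range")
    }
    traj$richness[replicate, ]
  }
  credit_ledger(cashed, credit0, steps = traj$steps)
}

#' @export
print.credit_ledger <- function(x, ...) {
  cat("Credit ledger: credit0 =", x$credit0, "over", length(x$steps),
      "steps\n")
  t_done <- rewiring_time(x)
  if (is.na(t_done)) {
    cat("  remaining credit at last step:",
        format(x$remaining[length(x$remaining)], digits = 4),
        "(credit not fully cashed)\n")
  } else {
    cat("  credit fully cashed at step", t_done, "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.credit_ledger <- function(x, ...) {
  data.frame(step = x$steps, cashed = x$cashed, remaining = x$remaining)
}

#' Rewiring time: when is the credit fully cashed?
#'
#' The rewiring time is the first step (or time bin) at which the remaining
#' credit of ecological interactions reaches zero — every link that could be
#' restored has become functional. For a ledger this is a single step index;
#' for a trajectory it is computed per replicate against `credit0` and
#' summarised across replicates. `NA` means "not reached" within the run.
#'
#' @param x a `credit_ledger` or `rewiring_trajectory`.
#' @param ... passed to methods.
#' @return for a ledger, a single step index or `NA`; for a trajectory, a
#'   `rewiring_time` object with per-replicate `times` and a `summary`
#'   (min/median/max over replicates that reached full cashing).
#' @examples
#' led <- credit_ledger(c(0, 10, 25), credit0 = 25)
#' rewiring_time(led)  # 2
#' @export
rewiring_time <- function(x, ...) UseMethod("rewiring_time")

#' @rdname rewiring_time
#' @export
rewiring_time.credit_ledger <- function(x, ...) {
  hit <- which(x$remaining == 0)
  if (length(hit) == 0L) NA_integer_ else x$steps[hit[1]]
}

#' @rdname rewiring_time
#' @param credit0 credit to cash; defaults to the trajectory's partner degree.
#' @export
rewiring_time.rewiring_trajectory <- function(x, credit0 = x$degree, ...) {
  times <- apply(x$richness, 1, function(r) {
    hit <- which(r >= credit0)
    if (length(hit) == 0L) NA_integer_ else x$steps[hit[1]]
  })
  reached <- !is.na(times)
  summary <- if (any(reached)) {
    c(min = min(times[reached]), median = stats::median(times[reached]),
      max = max(times[reached]))
  } else {
    c(min = NA_real_, median = NA_real_, max = NA_real_)
  }
  structure(
    list(times = times, reached = reached, summary = summary,
         credit0 = credit0),
    class = "rewiring_time"
  )
}

#' @export
print.rewiring_time <- function(x, ...) {
  cat("Rewiring time for credit0 =", x$credit0, ":", sum(x$reached), "/",
      length(x$times), "replicates reached full cashing\n")
  if (any(x$reached)) {
    cat("  min/median/max:", paste(x$summary, collapse = " / "), "\n")
  }
  invisible(x)
}
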