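#' Build an isoflurane exposure timeline
#'
#' Returns the nominal isoflurane concentration schedule for one of the two
#' exposure paradigms used to probe hysteresis at the population EC50
#' (0.6\% isoflurane). Both arms end on an extended 0.6\% step; the only
#' difference between them is the history with which that step is reached.
#'
#' \describe{
#'   \item{induction}{30 min of 100\% oxygen, then 0.6\% isoflurane for
#'     240 min (270 min total). The final step is approached from the awake
#'     side.}
#'   \item{emergence}{30 min oxygen, 60 min at 0.6\%, 30 min at 1.2\%, then
#'     0.6\% for 240 min (360 min total). The final step is approached from a
#'     deeply anesthetized state.}
#' }
#'
#' @param arm `"induction"` or `"emergence"`.
#' @return A tibble with columns `time_s` (segment onset, seconds from
#'   recording start) and `conc` (percent isoflurane), with attributes
#'   `arm`, `total_s` (recording duration) and `final_step_s` (onset of the
#'   final 0.6\% step, the reference time for all analysis periods).
#' @examples
#' make_exposure_timeline("emergence")
#' @export
make_exposure_timeline <- function(arm = c("induction", "emergence")) {
  arm <- match.arg(arm)
  sched <- switch(arm,
    induction = tibble::tibble(
      time_s = c(0, 1800),
      conc   = c(0, 0.6)
    ),
    emergence = tibble::tibble(
      time_s = c(0, 1800, 5400, 7200),
      conc   = c(0, 0.6, 1.2, 0.6)
    )
  )
  attr(sched, "arm") <- arm
  attr(sched, "total_s") <- switch(arm, induction = 270 * 60, emergence = 360 * 60)
  attr(sched, "final_step_s") <- switch(arm, induction = 1800, emergence = 7200)
  class(sched) <- c("ni_schedule", class(sched))
  sched
}

#' Concentration at given times
#'
#' Evaluates a concentration schedule (a right-continuous step function) at
#' arbitrary times.
#'
#' @param schedule A schedule from [make_exposure_timeline()].
#' @param time_s Numeric vector of times in seconds.
#' @return Numeric vector of percent isoflurane.
#' @export
conc_at <- function(schedule, time_s) {
  validate_schedule(schedule)
  idx <- findInterval(time_s, schedule$time_s)
  if (any(idx < 1)) stop("times before schedule start", call. = FALSE)
  schedule$conc[idx]
}

validate_schedule <- function(schedule) {
  if (!all(c("time_s", "conc") %in% names(schedule)))
    stop("schedule must have columns time_s and conc", call. = FALSE)
  if (schedule$time_s[1] != 0 || is.unsorted(schedule$time_s, strictly = TRUE))
    stop("schedule times must be strictly increasing and start at 0", call. = FALSE)
  if (any(schedule$conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  invisible(schedule)
}
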