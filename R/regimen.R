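#' Dosing regimen
#'
#' A regimen is an ordered set of bolus dose events (time in hours since
#' first administration, injected activity in MBq, cycle index) plus a
#' simulation horizon.
#'
#' @param dose_times Strictly increasing numeric vector of dose times (h).
#' @param activities Injected activity per dose (MBq); recycled.
#' @param horizon End of the observation period (h).
#' @param name Label for printing.
#' @return A list of class `regimen` with a `dose_events` tibble
#'   (`time`, `amt`, `cycle`) and `horizon`.
#' @export
regimen <- function(dose_times, activities = 7400, horizon = 24 * 7 * 24,
                    name = "custom") {
  if (length(dose_times) < 1 || is.unsorted(dose_times, strictly = TRUE)) {
    stop("dose_times must be strictly increasing", call. = FALSE)
  }
  if (any(activities < 0)) stop("activities must be >= 0", call. = FALSE)
  if (horizon <= max(dose_times)) {
    stop("horizon must exceed the last dose time", call. = FALSE)
  }
  structure(
    list(name = name,
         dose_events = tibble::tibble(
           time = as.numeric(dose_times),
           amt = rep_len(as.numeric(activities), length(dose_times)),
           cycle = seq_along(dose_times)),
         horizon = horizon),
    class = "regimen"
  )
}

#' Clinical dosing regimens
#'
#' The two schedules in clinical use: `"4x6"`, four cycles of 7.4 GBq with a
#' six-week interval (doses at weeks 0, 6, 12, 18), and `"2x2_repeated"`,
#' two cycles of 7.4 GBq two weeks apart repeated after twelve weeks (doses
#' at weeks 0, 2, 12, 14). Both use a 24-week horizon, i.e. endpoints are
#' read six weeks after the last `4x6` cycle and ten weeks after the last
#' `2x2_repeated` cycle.
#'
#' @param label `"4x6"` or `"2x2_repeated"`.
#' @param activity Injected activity per cycle (MBq).
#' @return A [regimen()].
#' @examples
#' build_regimen("4x6")$dose_events$time   # 0 1008 2016 3024
#' @export
build_regimen <- function(label = c("4x6", "2x2_repeated"), activity = 7400) {
  label <- match.arg(label)
  wk <- 7 * 24
  times <- switch(label,
                  "4x6" = c(0, 6, 12, 18) * wk,
                  "2x2_repeated" = c(0, 2, 12, 14) * wk)
  regimen(times, activity, horizon = 24 * wk, name = label)
}

#' @export
print.regimen <- function(x, ...) {
  cat("<regimen>", x$name, "-", nrow(x$dose_events), "doses, horizon",
      x$horizon / (7 * 24), "weeks\n")
  print(x$dose_events)
  invisible(x)
}
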