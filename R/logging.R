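# package-session state: event log and inner-model fit counter
.mo_state <- new.env(parent = emptyenv())
.mo_state$log <- character(0)
.mo_state$fits <- 0L
.mo_state$verbose <- FALSE

log_event <- function(fmt, ...) {
  line <- sprintf(fmt, ...)
  .mo_state$log <- c(.mo_state$log, line)
  if (isTRUE(.mo_state$verbose)) message("[moadjust] ", line)
  invisible(line)
}

bump_fit_counter <- function(by = 1L) {
  .mo_state$fits <- .mo_state$fits + as.integer(by)
  invisible(.mo_state$fits)
}

#' Session log of optimizer runs
#'
#' Every run of the optimizers appends events (fold creation, per-fold
#' fronts, adjuster training, budget accounting) to a session log, so the
#' full control flow of a dual-stage run can be audited after the fact.
#'
#' @param verbose For `mo_log_verbose()`: also `message()` each event as it
#'   happens.
#' @return `mo_log()` returns the logged lines; `mo_fit_count()` the number
#'   of inner-model fits since the last reset.
#' @export
mo_log <- function() .mo_state$log

#' @rdname mo_log
#' @export
mo_log_clear <- function() {
  .mo_state$log <- character(0)
  .mo_state$fits <- 0L
  invisible(NULL)
}

#' @rdname mo_log
#' @export
mo_log_verbose <- function(verbose = TRUE) {
  .mo_state$verbose <- isTRUE(verbose)
  invisible(NULL)
}

#' @rdname mo_log
#' @export
mo_fit_count <- function() .mo_state$fits
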