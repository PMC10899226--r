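# Condition helpers: every error/warning the package raises carries a class
# prefixed "ap_" so callers (and the pipeline's partial-failure handling) can
# dispatch on the failure kind rather than parse message text.

ap_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ap_error"), call = call))
}

ap_warn <- function(msg, class = "ap_warning") {
  warning(warningCondition(msg, class = c(class, "ap_warning")))
}

#' Package-level logger
#'
#' Routes informational messages through a single point with a `[audioprog]`
#' prefix. Suppressed when `options(audioprog.quiet = TRUE)`.
#'
#' @param ... Message parts, pasted together.
#' @return Invisibly, the message text.
#' @keywords internal
ap_log <- function(...) {
  txt <- paste0(...)
  if (!isTRUE(getOption("audioprog.quiet", FALSE))) {
    message("[audioprog] ", txt)
  }
  invisible(txt)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards
# so seeded operations do not perturb the session stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
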