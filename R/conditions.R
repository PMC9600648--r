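# Structured condition helpers. Every error raised by the package carries a
# subclass of "shesd_error" so callers can handle specific failure modes
# (e.g. the zero-MAD breakdown that triggers jittering) programmatically.

stop_shesd <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "shesd_error")))
}

warn_shesd <- function(message, class, ...) {
  warning(warningCondition(message, ..., class = c(class, "shesd_warning")))
}

is_wholenumber <- function(x, tol = sqrt(.Machine$double.eps)) {
  is.finite(x) & abs(x - round(x)) < tol
}
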