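`%||%` <- function(a, b) if (is.null(a)) b else a

# stage-tagged progress messages; suppressible via suppressMessages()
nt_log <- function(fmt, ...) {
  message("[neurotarget] ", sprintf(fmt, ...))
}

# fixed float format used by all report writers: 6 significant digits
fmt_num <- function(x) {
  out <- formatC(signif(x, 6), format = "g", digits = 6)
  out[is.na(x)] <- "NA"
  out
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == round(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
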