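# Internal helpers shared across the package.

# Validation errors carry class "apc_error" so the CLI can map them to exit
# code 1 while leaving usage errors (class "apc_usage_error") at exit code 2.
apc_stop <- function(..., class = "apc_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Round half away from zero (commercial rounding), as used in printed
# epidemiological tables; base round() rounds half to even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# First integer in a label: "40-44" -> 40, "85+" -> 85, "1976-1980" -> 1976.
# Returns NA for labels that do not start with digits.
label_start <- function(labels) {
  out <- suppressWarnings(as.numeric(sub("^\\s*([0-9]+).*$", "\\1", labels)))
  out[!grepl("^\\s*[0-9]", labels)] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
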