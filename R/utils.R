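# Timepoint labels used throughout; k = 0..3 is the treatment-cycle index.
TIMEPOINTS <- c("T0", "T1", "T2", "T3")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Deterministic per-patient substream seed derived from the global seed, so
# that patient i's draws do not depend on how many patients follow it.
patient_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) * 69621 %% 2147483647
  as.integer((s + as.double(i) * 7919) %% 2147483646) + 1L
}
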