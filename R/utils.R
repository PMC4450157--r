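# Internal helpers shared across modules.

abort_invalid <- function(msg, class = "fpvs_invalid_argument") {
  rlang::abort(msg, class = c(class, "fpvs_error"))
}

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# integer-valued within floating tolerance (values may arrive as doubles)
is_integerish <- function(x, tol = 1e-9) {
  is_number(x) && abs(x - round(x)) < tol
}

#' Round half away from zero
#'
#' Deterministic rounding used for trigger sample indices; base `round()`
#' rounds half to even, which is platform-stable but surprises when mapping
#' onsets to samples.
#' @noRd
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# derive a per-unit seed from a master seed, kept below .Machine$integer.max
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 1000003 + index * 7919) %% 2147483629)
}

stopifnot_channels <- function(labels, wanted) {
  missing <- setdiff(wanted, labels)
  if (length(missing) > 0L) {
    abort_invalid(paste0(
      "channel(s) not present in recording: ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}
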