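# Shared validation helpers and small utilities.

AA1 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

# 3-letter -> 1-letter, including phosphothreonine
AA3TO1 <- c(stats::setNames(names(AA3), AA3), TPO = "T")

stop_validation <- function(msg, ...) {
  rlang::abort(msg, class = "cdk2substrate_validation_error", ...)
}

stop_format <- function(msg, ...) {
  rlang::abort(msg, class = "cdk2substrate_format_error", ...)
}

stop_usage <- function(msg, ...) {
  rlang::abort(msg, class = "cdk2substrate_usage_error", ...)
}

stop_spec <- function(msg, ...) {
  rlang::abort(msg, class = "cdk2substrate_spec_error", ...)
}

assert_aa_string <- function(x, what = "sequence") {
  bad <- !stringr::str_detect(x, paste0("^[", paste(AA1, collapse = ""), "]+$"))
  if (any(bad)) {
    stop_validation(sprintf(
      "%s contains letters outside the 20 standard one-letter amino-acid codes: %s",
      what, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}

`%||%` <- rlang::`%||%`
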