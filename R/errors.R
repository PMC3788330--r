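# Condition classes shared across the package.  Every user-facing failure is
# signalled with one of these so that callers (and the CLI) can dispatch on
# class rather than on message text.

abort_validation <- function(message, ...) {
  rlang::abort(message, class = "regstore_validation", ...)
}

abort_permission <- function(message, ...) {
  rlang::abort(message, class = "regstore_permission", ...)
}

abort_not_found <- function(message, ...) {
  rlang::abort(message, class = c("regstore_not_found", "regstore_validation"), ...)
}

abort_kind <- function(message, ...) {
  rlang::abort(message, class = c("regstore_kind", "regstore_validation"), ...)
}

abort_integrity <- function(message, ...) {
  rlang::abort(message, class = c("regstore_integrity", "regstore_validation"), ...)
}

abort_ambiguous <- function(message, ...) {
  rlang::abort(message, class = c("regstore_ambiguous", "regstore_validation"), ...)
}
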