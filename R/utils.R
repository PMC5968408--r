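# Internal error helpers. All user-facing failures carry a citenet_* class so
# callers (and tests) can condition on the failure kind rather than message text.

abort_corpus <- function(message, ...) {
  abort(message, class = "citenet_corpus_error", ...)
}

abort_format <- function(message, ...) {
  abort(message, class = "citenet_format_error", ...)
}

abort_usage <- function(message, ...) {
  abort(message, class = "citenet_usage_error", ...)
}

abort_config <- function(message, ...) {
  abort(message, class = "citenet_config_error", ...)
}

abort_feasibility <- function(message, ...) {
  abort(message, class = "citenet_feasibility_error", ...)
}

abort_degenerate <- function(message, ...) {
  abort(message, class = "citenet_degenerate_table_error", ...)
}

# Collapse a handful of ids for an error message without flooding it.
id_phrase <- function(ids, max = 5L) {
  ids <- unique(as.character(ids))
  shown <- paste(head(ids, max), collapse = ", ")
  if (length(ids) > max) shown <- paste0(shown, ", ... (", length(ids), " total)")
  shown
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
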