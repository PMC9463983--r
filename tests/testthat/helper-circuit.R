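# Shared fixtures: parameter presets and a memoised store for expensive
# protocol runs reused across test files.

disinh <- function(...) circuit_params("disinhibition", ...)
copair <- function(...) circuit_params("copairing", ...)

.acc_env <- new.env(parent = emptyenv())

# compute-once accessor for heavyweight protocol results
acc <- function(name, expr) {
  if (is.null(.acc_env[[name]])) .acc_env[[name]] <- force(expr)
  .acc_env[[name]]
}
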