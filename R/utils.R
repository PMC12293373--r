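# Internal helpers: typed error conditions and seeded evaluation.

fs3d_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fs3d_error"), call = call))
}

config_error <- function(msg) fs3d_error(msg, "fs3d_config_error")
data_error <- function(msg) fs3d_error(msg, "fs3d_data_error")
format_error <- function(msg) fs3d_error(msg, "fs3d_format_error")
input_error <- function(msg) fs3d_error(msg, "fs3d_input_error")
episode_error <- function(msg) fs3d_error(msg, "fs3d_episode_error")
metric_error <- function(msg) fs3d_error(msg, "fs3d_metric_error")
numeric_error <- function(msg) fs3d_error(msg, "fs3d_numeric_error")

# All randomness in the package flows through this: the global RNG state is
# saved and restored, so package calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
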