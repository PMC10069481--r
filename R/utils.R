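# internal helpers shared across modules

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

abort_config <- function(msg) rlang::abort(msg, class = "hostpref_config_error")
abort_input  <- function(msg) rlang::abort(msg, class = "hostpref_input_error")

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_config(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort_config(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

`%||%` <- rlang::`%||%`
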