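# Internal helpers shared across modules.

# Round half away from zero (so .485 -> .49), which is the convention the
# printed wrong-acceptance tables follow; base round() rounds half to even.
round_half_up <- function(x, digits = 2) {
  scaled <- round(x * 10^digits, 9)  # absorb binary representation error first
  sign(scaled) * floor(abs(scaled) + 0.5) / 10^digits
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

stop_domain <- function(...) {
  stop(structure(class = c("plausr_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_usage <- function(...) {
  stop(structure(class = c("plausr_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("plausr_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

warn_class <- function(msg, class) {
  warning(structure(class = c(class, "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

check_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(name, " must be a single finite number")
  if (x < 0 || x > 1 || (open_left && x == 0) || (open_right && x == 1))
    stop_domain(name, " = ", format(x), " is outside ",
                if (open_left) "(" else "[", "0, 1",
                if (open_right) ")" else "]")
  x
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a master seed; keeps results reproducible when one
# call needs several independent streams. Stays inside the 32-bit signed range.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 104729) %% 2147483647
}
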