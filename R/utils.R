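# Shared vocabularies and error helpers.

load_levels <- c("none", "action_planning", "motor_execution", "verbal")
task_levels <- c("recall_own", "recall_partner")
role_levels <- c("focal", "partner")
recall_modes <- c("free_report", "extended")

# Cue symbols used by default: 15 letter/shape labels (the two non-letter
# symbols are spelled out so identifiers stay ASCII-safe on disk).
default_shapes <- c("A", "C", "F", "H", "I", "J", "K", "L", "O", "P",
                    "T", "V", "X", "triangle", "equals")

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "guessnull_schema_error", ...)
}

abort_integrity <- function(msg, ...) {
  rlang::abort(msg, class = "guessnull_integrity_error", ...)
}

abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = "guessnull_domain_error", ...)
}

# NOVEL:<token> codes mark reported actions outside the experiment's
# action inventory; they are intrusions by construction.
is_novel_code <- function(action_code) {
  startsWith(as.character(action_code), "NOVEL")
}

action_key <- function(shape_id, action_code) {
  paste(shape_id, action_code, sep = "\r")
}

check_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_domain(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

# Run `expr` under a private RNG stream when `seed` is given, leaving the
# caller's RNG state untouched; with seed = NULL the ambient stream is used.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
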