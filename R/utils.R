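# Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with a stage label and an index so that every
#' stage (and every subject within a stage) gets its own independent,
#' reproducible random stream. Adding subjects or stages never perturbs
#' the streams of existing ones.
#'
#' @param master Integer master seed.
#' @param stage Character stage label (e.g. "schedule", "agent").
#' @param index Non-negative integer index within the stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
sub_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  stopifnot(is.character(stage), length(stage) == 1L)
  code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (abs(master) %% 1000003) * 1009 + (code %% 65521) * 97 + abs(index) * 131
  as.integer(s %% 2147483647)
}

config_error <- function(field, msg) {
  stop(structure(
    class = c("helibelief_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field `%s`: %s", field, msg),
         call = sys.call(-1))
  ))
}

check_prob <- function(x, field, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    config_error(field, "must be a single numeric probability")
  }
  if (open) {
    if (x <= 0 || x >= 1) config_error(field, "must lie strictly in (0, 1)")
  } else {
    if (x < 0 || x > 1) config_error(field, "must lie in [0, 1]")
  }
  x
}
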