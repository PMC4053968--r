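#' Derive a reproducible sub-stream seed for a named pipeline stage
#'
#' A single run seed is fanned out to per-stage streams by hashing the stage
#' name, so toggling stages on or off never perturbs the draws of the others.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name (e.g. `"simulate"`, `"dfe"`).
#' @return An integer seed below 2^31 usable with [set.seed()].
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

#' @noRd
assert_bases <- function(x, allow = BASES) {
  if (!all(x %in% allow)) {
    stop("invalid base(s): ", paste(setdiff(x, allow), collapse = ","),
         call. = FALSE)
  }
  invisible(x)
}

# sample() without its size-1 surprise (sample(5) != sample(c(5)))
sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
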