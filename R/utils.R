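#' Derive an independent child seed from a master seed
#'
#' Deterministically maps a (seed, stream-name) pair to a 31-bit integer so
#' that different random stages (paradigm order, background noise, null data)
#' can be driven independently from one master seed.
#'
#' @param seed integer master seed.
#' @param stream character stream label.
#' @return an integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # simple string hash (djb2 variant) folded with the seed, kept below 2^31
  h <- 5381
  for (cc in utf8ToInt(stream)) h <- (h * 33 + cc) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 2654435) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ftfa <- function(..., class) {
  stop(structure(class = c(class, "ftfa_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# nearest-sample index offset for a time in seconds
sec_to_samples <- function(t_s, fs) as.integer(round(t_s * fs))
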