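#' Round half away from zero
#'
#' Deterministic rounding used for stratified partition sizes: 43.5 becomes
#' 44, unlike base [round()] which rounds half to even. Only defined for
#' non-negative inputs, which is all the partitioner needs.
#'
#' @param x non-negative numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  stopifnot(all(x >= 0))
  as.integer(floor(x + 0.5))
}

#' Derive a reproducible replicate seed
#'
#' Maps (base seed, backend id, signature id, partition index, replicate
#' index) to a 31-bit integer via a multiplicative string hash, so every
#' grid cell gets an independent but replayable random stream. Deterministic
#' backends drop the replicate index, making all replicates of a cell share
#' one stream.
#'
#' @param base_seed integer.
#' @param backend_id backend identifier string.
#' @param signature_id signature identifier string.
#' @param partition integer partition index.
#' @param replicate integer replicate index; ignored when
#'   `deterministic = TRUE`.
#' @param deterministic drop the replicate index from the hash?
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
replicate_seed <- function(base_seed, backend_id, signature_id, partition,
                           replicate, deterministic = FALSE) {
  key <- paste(base_seed, backend_id, signature_id, partition,
               if (deterministic) "fixed" else replicate, sep = "|")
  m <- 2147483647  # 2^31 - 1, prime
  h <- 17
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
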