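#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All stochastic code in the package funnels
# through this so a single seed fans out deterministically.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic sub-seed derivation (Lehmer step), kept below 2^31.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 48271 + 7919 * k) %% 2147483647)
}

# Trapezoidal integration used by the curve-area routines.
trapz_area <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

afw_log <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[afwave] %-12s %s", stage, paste0(...)))
  }
  invisible(NULL)
}

stop_stage <- function(stage, ...) {
  stop(sprintf("stage '%s': %s", stage, paste0(...)), call. = FALSE)
}

ecg_classes <- function() c("N", "A", "O", "~")
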