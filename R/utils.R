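# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's state on
# exit. All stochastic operations in the package funnel through this so that
# no function touches global random state as a side effect.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %s", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %s", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %s", name, upper), call. = FALSE)
  }
  invisible(x)
}

#' Standard muscle codes
#'
#' The 13 lower-limb muscle codes used throughout the package, in fixed
#' recording order: gluteus medius (ME), gluteus maximus (MA), tensor fasciae
#' latae (FL), rectus femoris (RF), vastus medialis (VM), vastus lateralis
#' (VL), semitendinosus (ST), biceps femoris (BF), tibialis anterior (TA),
#' peroneus longus (PL), gastrocnemius medialis (GM), gastrocnemius lateralis
#' (GL) and soleus (SO).
#'
#' @return Character vector of length 13.
#' @export
muscle_codes <- function() {
  c("ME", "MA", "FL", "RF", "VM", "VL", "ST",
    "BF", "TA", "PL", "GM", "GL", "SO")
}
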