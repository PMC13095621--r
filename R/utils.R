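# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a per-endplate seed from a global seed so cohorts are reproducible
# and independent of generation order. Kept below 2^31.
derive_seed <- function(seed, patient_index, segment_index) {
  s <- bitwXor(as.integer(seed %% 2147483647L),
               as.integer((patient_index * 131071L + segment_index * 8191L) %% 2147483647L))
  abs(s) %% 2147483629L + 1L
}

# Truncated-normal draw via inverse-CDF; used for class-consistent depths.
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) {
    # interval far in the tail: fall back to clamping at the nearer bound
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  qnorm(runif(n, plo, phi), mean, sd)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)

stopf <- function(fmt, ..., class = "epmorph_error") {
  abort(sprintf(fmt, ...), class = class)
}

# The five endplate segments measured per patient, in anatomical order.
segment_levels <- function() c("L4 sup", "L4 inf", "L5 sup", "L5 inf", "S1 sup")

shape_levels <- function() {
  c("uniform_concave", "asymmetric_concave", "flat_bottom", "flat")
}
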