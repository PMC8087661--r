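# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded child seed from a master seed and a stream index; keeps
# every derived seed a valid 32-bit integer.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 9973) %% 2147483587L) + 1L
}

# Display rounding to 2 decimals. Base round() on the double quotient is the
# package display convention; see the methods vignette for why.
round2 <- function(x) round(x, 2)

# glmnet nags about binomial classes below 8 observations; expected and
# benign at leave-one-out fold sizes, so muffle exactly that message.
glmnet_quiet <- function(expr) {
  withCallingHandlers(
    expr,
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w), fixed = TRUE)) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != floor(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

is_binary01 <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}

# Orthonormalize columns of M via QR, with the sign of each column fixed so
# the diagonal of R is positive (keeps the result close to M for small
# perturbations of an orthonormal matrix).
orthonormalize <- function(M) {
  qr_dec <- qr(M)
  Q <- qr.Q(qr_dec)
  R <- qr.R(qr_dec)
  s <- sign(diag(R))
  s[s == 0] <- 1
  sweep(Q, 2, s, `*`)
}
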