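# internal helpers shared across modules

geo_mean <- function(x) exp(mean(log(x)))

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible sub-seed from a run seed and an arbitrary key.
# Keeps results identical whether fits run serially or are re-ordered.
# Result stays below 2^31 - 1.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

stop_fex <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# condition label "<modA>.<modB>" (or just "<modA>" for one factor)
condition_labels <- function(design) {
  facs <- design$biological_factors
  if (length(facs) == 1L) {
    as.character(facs[[1L]])
  } else {
    paste(as.character(facs[[1L]]), as.character(facs[[2L]]), sep = ".")
  }
}
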