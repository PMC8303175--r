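# internal helpers shared across modules

# Evaluate expr with a temporary RNG state so generators are deterministic
# given their seed and leave the caller's RNG untouched.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a sub-stream seed from (seed, salt ints); kept inside 32-bit range.
.stream_seed <- function(seed, ...) {
  salts <- c(...)
  s <- as.numeric(seed)
  for (x in salts) s <- (s * 7919 + as.numeric(x) + 1) %% 2147483629
  as.integer(s)
}

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

.match_strand <- function(strand) {
  strand <- as.character(strand)
  .assert(all(strand %in% c("+", "-")), "strand must be '+' or '-'")
  strand
}

.opposite_strand <- function(strand) ifelse(strand == "+", "-", "+")

# format numbers for text output without scientific notation;
# whole numbers print without a decimal point (bedGraph round trips)
.fmt_num <- function(x) {
  ifelse(is.finite(x) & x == round(x),
         sprintf("%d", as.integer(round(x))),
         formatC(x, format = "g", digits = 10))
}
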