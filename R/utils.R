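# run expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# cache of log unsigned Stirling numbers of the first kind, rows by n
.stirling_cache <- new.env(parent = emptyenv())

# log |s(n, k)| for k = 0..n, via |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)|
log_stirling_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  row <- c(0)                                    # n = 0: |s(0,0)| = 1
  m <- 0L
  done <- as.integer(names(.stirling_cache))
  if (length(done) && any(done < n)) {
    m <- max(done[done < n])
    row <- .stirling_cache[[as.character(m)]]
  }
  while (m < n) {
    new <- numeric(m + 2L)                        # new[k+1] = log|s(m+1, k)|
    new[1] <- -Inf                                # |s(n, 0)| = 0 for n >= 1
    for (k in seq_len(m + 1L)) {
      a <- if (k <= m) log(m) + row[k + 1L] else -Inf   # m * |s(m, k)|
      b <- row[k]                                 # |s(m, k-1)|
      new[k + 1L] <- logsumexp(c(a, b))
    }
    row <- new
    m <- m + 1L
    .stirling_cache[[as.character(m)]] <- row
  }
  row
}
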