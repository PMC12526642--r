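`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# n independent sub-seeds derived deterministically from one master seed;
# kept below 2^31 so they are valid R integer seeds
seed_stream <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}

abort_validation <- function(...) {
  stop(paste0(...), call. = FALSE)
}

# centre-crop or mean-pad a signal to exactly n samples
fit_length <- function(x, n) {
  len <- length(x)
  if (len == n) return(x)
  if (len > n) {
    start <- (len - n) %/% 2L
    return(x[(start + 1L):(start + n)])
  }
  mu <- mean(x)
  left <- (n - len) %/% 2L
  c(rep(mu, left), x, rep(mu, n - len - left))
}

# split a space-joined sentence label into its word tokens
label_words <- function(label) {
  strsplit(label, " ", fixed = TRUE)[[1L]]
}

# longest common subsequence length between two character vectors
lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

# cheap content digest used to detect reference-set mutation between stages
signal_digest <- function(xs) {
  tot <- 0
  n <- 0L
  for (x in xs) {
    tot <- tot + sum(x) + sum(x * seq_along(x)) / length(x)
    n <- n + length(x)
  }
  sprintf("%d:%.12g", n, tot)
}
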