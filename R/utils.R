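# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this.
with_seed_ <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

s_to_min <- function(t_s) t_s / 60
min_to_s <- function(t_min) t_min * 60

# 6-connected component labelling of a logical 3D array (breadth-first).
# Volumes here are small (phantom scale), so a plain R queue is adequate.
label_components_ <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask)
  if (length(idx_all) == 0L) return(lab)
  # linear-index offsets of the 6 face neighbours, validity checked per axis
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      ai <- arrayInd(v, d)
      for (ax in 1:3) {
        for (dd in c(-1L, 1L)) {
          nb <- ai
          nb[ax] <- nb[ax] + dd
          if (nb[ax] < 1L || nb[ax] > d[ax]) next
          li <- nb[1L] + d[1L] * (nb[2L] - 1L) + d[1L] * d[2L] * (nb[3L] - 1L)
          if (mask[li] && lab[li] == 0L) {
            lab[li] <- nxt
            queue <- c(queue, li)
          }
        }
      }
    }
  }
  lab
}

# trapezoidal integral of y(x)
trapz_ <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
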