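#' @include AllClasses.R
NULL

# point-in-polygon by ray casting (even-odd rule); poly is an n x 2 matrix
pointInPolygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# centered moving average with edge replication, width in samples (odd)
movingAverage <- function(x, k) {
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(h + 1L):(h + length(x))]
}

# largest-remainder proportional allocation of n among weights w
allocateProportional <- function(n, w) {
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# deterministic child seed for stream i of a master seed (kept below 2^31)
childSeed <- function(seed, i) {
  (as.integer(seed) %% 1000000L) * 2003L + as.integer(i) %% 2003L
}

stopStage <- function(stage, msg) {
  stop(structure(class = c("ewimapStageError", "error", "condition"),
    list(message = sprintf("[%s] %s", stage, msg), call = sys.call(-1))))
}
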