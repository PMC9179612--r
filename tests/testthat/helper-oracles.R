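# Independent brute-force implementations used as oracles. These work from
# the definitions with plain loops and stay independent of the package's
# vectorized code paths.

# Per-sample, loop-based computation of all 23 window features.
naive_features <- function(w, fs = 25, tsw = 5) {
  m <- fs * tsw
  n <- nrow(w)
  s <- n / m
  series <- list()
  for (ax in c("x", "y", "z")) {
    v <- w[[paste0(ax, "_g")]]
    ave <- ab <- std <- numeric(s)
    for (k in 0:(s - 1)) {
      seg <- v[(m * k + 1):(m * (k + 1))]
      mu <- sum(seg) / m
      ave[k + 1] <- mu
      ab[k + 1] <- sum(abs(seg)) / m
      std[k + 1] <- sqrt(sum((seg - mu)^2) / m)
    }
    series[[paste0("ave_", ax)]] <- ave
    series[[paste0("abs_", ax)]] <- ab
    series[[paste0("std_", ax)]] <- std
  }
  order9 <- c(
    "ave_x", "ave_y", "ave_z", "abs_x", "abs_y", "abs_z",
    "std_x", "std_y", "std_z"
  )
  out <- c()
  for (nm in order9) {
    v <- series[[nm]]
    out[paste0("vstd_", nm)] <- sqrt(sum(v^2) / s)
    out[paste0("vmax_", nm)] <- max(abs(v))
  }
  vebda <- 0
  for (k in 1:s) {
    vebda <- vebda + sqrt(series$ave_x[k]^2 + series$ave_y[k]^2 + series$ave_z[k]^2)
  }
  out["vebda"] <- vebda / s
  mx <- sum(series$ave_x) / s
  my <- sum(series$ave_y) / s
  mz <- sum(series$ave_z) / s
  obda <- 0
  for (k in 1:s) {
    obda <- obda + abs(series$ave_x[k] - mx) + abs(series$ave_y[k] - my) +
      abs(series$ave_z[k] - mz)
  }
  out["obda"] <- obda / s
  norm1 <- function(v) v / max(abs(v))
  rho <- function(a, b) {
    a <- a - sum(a) / length(a)
    b <- b - sum(b) / length(b)
    da <- sqrt(sum(a^2))
    db <- sqrt(sum(b^2))
    if (da == 0 || db == 0) return(0)
    sum(a * b) / (da * db)
  }
  nx <- norm1(series$ave_x)
  ny <- norm1(series$ave_y)
  nz <- norm1(series$ave_z)
  out["rho_xy"] <- rho(nx, ny)
  out["rho_xz"] <- rho(nx, nz)
  out["rho_yz"] <- rho(ny, nz)
  out[feature_names()]
}

# Loop-based recount of the class pair of a label vector.
naive_class_pair <- function(labels, fmin = 0.4) {
  counts <- integer(8)
  for (b in labels) counts[b] <- counts[b] + 1
  freq <- counts / length(labels)
  c1 <- NA_integer_
  best <- -1
  for (b in 1:8) {
    if (freq[b] > best) {
      best <- freq[b]
      c1 <- b
    }
  }
  c2 <- c1
  second <- -1
  b2 <- NA_integer_
  for (b in 1:8) {
    if (b != c1 && freq[b] > second) {
      second <- freq[b]
      b2 <- b
    }
  }
  # a tie with c1's frequency means c1 won only by the lower-code rule;
  # b2 is then the higher-coded behavior with the same frequency
  if (!is.na(b2) && second >= fmin) c2 <- b2
  c(c1 = c1, c2 = c2)
}

# Exhaustive computation of the eight class weights and the combined vote.
naive_combine <- function(s, weights) {
  members <- function(lab) {
    unique(as.integer(strsplit(as.character(lab), "")[[1]]))
  }
  W <- numeric(8)
  for (k in 1:8) {
    for (i in 1:5) {
      if (k %in% members(s[[i]])) W[k] <- W[k] + weights[i]
    }
  }
  cand <- which(W == max(W))
  s1 <- suppressWarnings(as.integer(s[[1]]))
  s6 <- if (!is.na(s1) && s1 %in% cand) s1 else min(cand)
  list(W = W, s6 = s6)
}

# Loop-based accuracy recount.
naive_accuracy <- function(pred, actual) {
  hits <- 0
  for (i in seq_along(pred)) if (pred[i] == actual[i]) hits <- hits + 1
  100 * hits / length(pred)
}
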