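# Independent oracles, written deliberately without reusing package
# internals: plain loops and elementwise arithmetic only.

# literal step-by-step evaluation of the five-threshold protocol
brute_force_segment <- function(above, below, sub,
                                A = 3.8, B = 12, C = 3, Dcut = 0,
                                E = c(3, 4), use_E = FALSE) {
  d <- dim(above)
  mA <- array(as.integer(above >= A), d)
  mB <- array(as.integer(above >= B), d)
  mC <- array(as.integer(sub >= C), d)
  mE <- array(as.integer(below >= E[1] & below <= E[2]), d)
  mD <- brute_force_dilate(array(as.integer(sub < Dcut), d))
  f <- array(as.integer(mA == 1 & mC == 1 & mD == 0), d)
  g <- brute_force_dilate(f)
  h <- array(as.integer(g == 1 & mC == 1), d)
  excl <- mB == 1 & mC == 1
  if (use_E) excl <- excl | (mE == 1 & mC == 1)
  array(as.integer(h == 1 & !excl), d)
}

# triple-loop 26-neighbourhood dilation
brute_force_dilate <- function(mask) {
  d <- dim(mask)
  out <- array(0L, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    hit <- FALSE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      zz <- z + dz; yy <- y + dy; xx <- x + dx
      if (zz >= 1 && zz <= d[1] && yy >= 1 && yy <= d[2] &&
          xx >= 1 && xx <= d[3] && mask[zz, yy, xx] == 1) hit <- TRUE
    }
    if (hit) out[z, y, x] <- 1L
  }
  out
}

# stack-based flood fill, 26-connectivity; returns component sizes sorted
flood_fill_sizes <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  sizes <- integer(0)
  for (start in which(mask > 0)) {
    if (seen[start]) next
    stack <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      size <- size + 1L
      ai <- arrayInd(cur, d)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        z <- ai[1] + dz; y <- ai[2] + dy; x <- ai[3] + dx
        if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3]) next
        idx <- ((x - 1) * d[2] + (y - 1)) * d[1] + z
        if (mask[idx] > 0 && !seen[idx]) {
          seen[idx] <- TRUE
          stack <- c(stack, idx)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes)
}

# random dual-energy triple with all protocol branches populated
random_protocol_volumes <- function(seed, d = c(8, 8, 8)) {
  set.seed(seed)
  above <- array(runif(prod(d), 0, 16), d)
  below <- above * runif(prod(d), 0.5, 1.5)
  list(above = above, below = below, sub = above - below)
}

# small, fast phantom spec for unit tests (overridable defaults)
small_phantom_spec <- function(...) {
  args <- list(shape = c(16, 64, 64), n_yttria_blobs = 3,
               n_mineral_blobs = 2)
  user <- list(...)
  args[names(user)] <- user
  do.call(phantom_spec, args)
}
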