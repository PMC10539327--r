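# Independent oracles used across the suite.

# ---------------------------------------------------------------------------
# Brute-force dip oracle.
#
# Directly solves min_G sup |F_n - G| over unimodal distribution functions G
# as a family of small linear programmes (boot::simplex).  G is convex left
# of its mode and concave right of it, with one upward jump allowed at the
# mode; at each distinct sample value v_j with ecdf step F_{j-1} -> F_j the
# sup-norm band requires F_j - eps <= G(v_j) <= F_{j-1} + eps.  Mode
# configurations enumerated: all-convex, all-concave, mode at a data point
# (jump there, relaxed upper band at the modal point), and mode at gridded
# positions inside each gap (with junction slope constraints for the convex
# and concave extensions meeting at the jump).  Quadratic-ish in sample size;
# meant for exhaustive validation at small n.
dip_oracle <- function(x, m_grid = 15L) {
  x <- sort(x); n <- length(x); v <- unique(x); K <- length(v)
  if (K == 1L) return(1 / (2 * n))
  Fcum <- cumsum(tabulate(match(x, v), K)) / n
  F0 <- c(0, Fcum[-K])

  solve_cfg <- function(build) {
    env <- new.env()
    env$A1 <- NULL; env$b1 <- NULL; env$A2 <- NULL; env$b2 <- NULL
    build(env)
    obj <- numeric(env$nv); obj[env$nv] <- 1
    res <- try(boot::simplex(a = obj, A1 = env$A1, b1 = env$b1,
                             A2 = env$A2, b2 = env$b2, maxi = FALSE),
               silent = TRUE)
    if (inherits(res, "try-error") || res$solved != 1) return(Inf)
    res$value
  }
  helpers <- function(env, nv) {
    env$nv <- nv
    env$row <- function(i, val = 1) { r <- numeric(nv); r[i] <- val; r }
    env$le <- function(r, b) { env$A1 <- rbind(env$A1, r); env$b1 <- c(env$b1, b) }
    env$ge <- function(r, b) { env$A2 <- rbind(env$A2, r); env$b2 <- c(env$b2, b) }
    shape <- function(x1, i1, x2, i2, x3, i3, ge) {
      d12 <- x2 - x1; d23 <- x3 - x2; r <- numeric(nv)
      r[i1] <- r[i1] + 1 / d12; r[i2] <- r[i2] - 1 / d12 - 1 / d23
      r[i3] <- r[i3] + 1 / d23
      if (ge) env$ge(r, 0) else env$le(r, 0)
    }
    env$convex <- function(x1, i1, x2, i2, x3, i3) shape(x1, i1, x2, i2, x3, i3, TRUE)
    env$concave <- function(x1, i1, x2, i2, x3, i3) shape(x1, i1, x2, i2, x3, i3, FALSE)
  }
  band <- function(env, i, lo, hi, ie) {
    env$le(env$row(i) - env$row(ie), hi)
    env$ge(env$row(i) + env$row(ie), lo)
  }
  mono <- function(env, idx)
    for (q in seq_len(length(idx) - 1L))
      env$le(env$row(idx[q]) - env$row(idx[q + 1L]), 0)

  best <- Inf
  for (shp in c("concave", "convex")) {          # mode beyond either end
    best <- min(best, solve_cfg(function(env) {
      helpers(env, K + 1L); ie <- K + 1L
      for (i in seq_len(K)) band(env, i, Fcum[i], F0[i], ie)
      mono(env, seq_len(K))
      if (K >= 3L) for (i in 2L:(K - 1L))
        if (shp == "convex") env$convex(v[i-1], i-1, v[i], i, v[i+1], i+1)
        else env$concave(v[i-1], i-1, v[i], i, v[i+1], i+1)
    }))
  }
  for (j in seq_len(K)) {                        # mode at data point j
    best <- min(best, solve_cfg(function(env) {
      helpers(env, K + 2L); il <- K + 1L; ie <- K + 2L
      for (i in seq_len(K))
        band(env, i, Fcum[i], if (i == j) Fcum[i] else F0[i], ie)
      mono(env, seq_len(K))
      band(env, il, F0[j], F0[j], ie)            # left limit at the jump
      env$le(env$row(il) - env$row(j), 0)
      if (j >= 2L) env$ge(env$row(il) - env$row(j - 1L), 0)
      if (j >= 4L) for (i in 2L:(j - 2L))
        env$convex(v[i-1], i-1, v[i], i, v[i+1], i+1)
      if (j >= 3L) env$convex(v[j-2], j-2, v[j-1], j-1, v[j], il)
      if (K - j >= 2L) for (i in (j + 1L):(K - 1L))
        env$concave(v[i-1], i-1, v[i], i, v[i+1], i+1)
    }))
  }
  for (j in seq_len(K - 1L)) {                   # mode inside gap j
    for (t in seq_len(m_grid)) {
      m <- v[j] + (v[j + 1L] - v[j]) * t / (m_grid + 1)
      best <- min(best, solve_cfg(function(env) {
        helpers(env, K + 3L); ia <- K + 1L; ib <- K + 2L; ie <- K + 3L
        for (i in seq_len(K)) band(env, i, Fcum[i], F0[i], ie)
        mono(env, seq_len(K))
        band(env, ia, Fcum[j], Fcum[j], ie)      # pre-jump value at m
        band(env, ib, Fcum[j], Fcum[j], ie)      # post-jump value at m
        env$ge(env$row(ia) - env$row(j), 0)
        env$le(env$row(ia) - env$row(ib), 0)
        env$le(env$row(ib) - env$row(j + 1L), 0)
        if (j >= 2L) env$convex(v[j-1], j-1, v[j], j, m, ia)
        if (j >= 3L) for (i in 2L:(j - 1L))
          env$convex(v[i-1], i-1, v[i], i, v[i+1], i+1)
        if (K - j >= 2L) env$concave(m, ib, v[j+1], j+1, v[j+2], j+2)
        if (K - j >= 3L) for (i in (j + 2L):(K - 1L))
          env$concave(v[i-1], i-1, v[i], i, v[i+1], i+1)
      }))
    }
  }
  max(best, 1 / (2 * n))
}

# all multisets of size n over a value alphabet
multisets <- function(vals, n) {
  out <- list()
  rec <- function(prefix, start, left) {
    if (left == 0L) { out[[length(out) + 1L]] <<- prefix; return() }
    for (i in start:length(vals)) rec(c(prefix, vals[i]), i, left - 1L)
  }
  rec(numeric(0), 1L, n)
  out
}

# ---------------------------------------------------------------------------
# Expected heterozygosity under repeated full-sib mating, relative to the
# founders: classical recursion F_t = (1 + 2 F_{t-1} + F_{t-2}) / 4,
# equivalently H_t = H_{t-1}/2 + H_{t-2}/4 with H = 1 - F.
sib_h_ratio <- function(t) {
  H <- c(1, 1)  # founders unrelated and non-inbred
  for (i in seq_len(t)) H <- c(H, H[length(H)] / 2 + H[length(H) - 1L] / 4)
  H[length(H)]
}

# ---------------------------------------------------------------------------
# Cohort with exact genotypes (white-box builder for deterministic examples).
# geno: matrix of 0/1/2 dispersal-allele counts (individuals x loci); for
# X-linked males supply 0/1 and male = TRUE.
fixed_cohort <- function(arch, geno, male) {
  geno <- as.matrix(geno)
  maternal <- (geno >= 1L) * 1L
  paternal <- (geno == 2L) * 1L
  if (arch$sex_linked) paternal[male, ] <- NA_integer_
  dispersim:::new_cohort(maternal, paternal, male, arch, 0L, "FIX")
}
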