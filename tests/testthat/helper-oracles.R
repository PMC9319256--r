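# Independent oracles used to cross-check the package's closed-form and
# fitted results. These deliberately avoid the implementation's code paths:
# equilibria are solved by bisection on the mass-action equation, residue
# masses are rebuilt from elemental composition, and aggregation is done by
# brute-force enumeration.

# 1:1 complex concentration by bisection on (S - PL)(N - PL) = Kd * PL.
oracle_bound_bisection <- function(S, N, kd, tol = 1e-12) {
  if (S == 0 || N == 0) return(0)
  f <- function(pl) (S - pl) * (N - pl) - kd * pl
  lo <- 0; hi <- min(S, N)
  if (kd == 0) return(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, hi)) break
  }
  (lo + hi) / 2
}

# Per-injection ITC heats with the same perfusion bookkeeping but the
# equilibrium solved by bisection instead of the closed-form quadratic.
oracle_itc_heats <- function(ka, dh, n, q_bg, inj_uL, cell_uM, syringe_uM,
                             v0_uL) {
  kd_uM <- 1e6 / ka
  v <- inj_uL / v0_uL
  m <- cell_uM; l <- 0
  pl_prev <- oracle_bound_bisection(0, n * m, kd_uM)
  q <- numeric(length(v))
  for (i in seq_along(v)) {
    d <- exp(-v[i])
    m <- m * d
    l <- syringe_uM + (l - syringe_uM) * d
    pl <- oracle_bound_bisection(l, n * m, kd_uM)
    q[i] <- dh * v0_uL * 1e-3 *
      (pl - pl_prev + v[i] * (pl + pl_prev) / 2) + q_bg
    pl_prev <- pl
  }
  q
}

# Average residue masses rebuilt from elemental composition and standard
# atomic weights (independent of the literature residue-mass table used by
# the implementation).
oracle_peptide_mass <- function(seq_string) {
  comp <- list( # C, H, N, O, S atom counts per residue
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))
  aw <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
  codes <- strsplit(seq_string, "")[[1]]
  total <- Reduce(`+`, comp[codes])
  sum(total * aw) + 2 * aw[["H"]] + aw[["O"]]
}

# Brute-force enumeration of sliding windows of a string.
oracle_windows <- function(L, window, step) {
  starts <- seq(1, L - window + 1, by = step)
  data.frame(start = starts, end = starts + window - 1)
}

# Brute-force per-residue mean over covering fragments.
oracle_residue_means <- function(frag_start, frag_len, scores, residues) {
  vapply(residues, function(r) {
    covers <- frag_start <= r & (frag_start + frag_len - 1) >= r
    mean(scores[covers])
  }, numeric(1))
}
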