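# Shared miniature fixtures and independent oracles, built in code.

tiny_proteome <- function() {
  tibble::tibble(
    protein_ac = c("PROT1", "PROT2"),
    sequence = c(
      paste0("MAAASPTRGSLKQEDFAVSPTKNNRSGWTPLHQAAV"),      # 36 aa
      paste0("MSSTPGKEEALRSPVVTTDEAQKLVSNPR")               # 29 aa
    )
  )
}

# Brute-force tiling oracle: every window position enumerated directly.
oracle_tiles <- function(start, end, length = 16L, step = 4L) {
  span <- end - start + 1L
  if (span <= length) return(cbind(start, end))
  starts <- seq(start, end - length + 1L, by = step)
  if (max(starts) + length - 1L < end) starts <- c(starts, end - length + 1L)
  cbind(starts, starts + length - 1L)
}

# Permutation oracle for the two-sided Mann-Whitney test (no ties).
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  u_stat <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- u_stat(seq_len(n1))
  mu <- n1 * (length(y)) / 2
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_stat)
  mean(abs(all_u - mu) >= abs(obs - mu) - 1e-9)
}

# Independent two-dimensional equilibrium oracle: solves the coupled
# mass-action system for (free L, free I) by nested root bracketing,
# avoiding the package's single-variable parameterization.
oracle_equilibrium_pl <- function(pt, lt, it, kd, ki) {
  free_l <- function(l) {
    # for a trial free L, free P follows from the probe equilibrium,
    # then free I from the competitor balance
    p_of <- function(i) pt / (1 + l / kd + i / ki)
    g <- function(i) i * (1 + p_of(i) / ki) - it
    i <- if (it == 0) 0 else uniroot(g, c(0, it), tol = 1e-13)$root
    p <- p_of(i)
    l * (1 + p / kd) - lt
  }
  l <- uniroot(free_l, c(1e-15, lt), tol = 1e-13)$root
  p_of_l <- function(i) pt / (1 + l / kd + i / ki)
  g <- function(i) i * (1 + p_of_l(i) / ki) - it
  i <- if (it == 0) 0 else uniroot(g, c(0, it), tol = 1e-13)$root
  p <- p_of_l(i)
  p * l / kd
}
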