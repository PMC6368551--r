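# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Crank-Nicolson finite-difference solution of the dimensionless transport
# PDE dF/dt = D F'' - V F' on z in [0, L], F(0) = 1, F(L) = 0, F(z, 0) = 0.
# Central differences in space; the constant-coefficient system matrix is
# factorized once (sparse LU) and reused over the time steps. L must be
# large enough that the advecting-diffusing front never feels the far
# boundary.
cn_transport_oracle <- function(D, V, t_end, L = 40, nz = 2001, nt = 1500) {
  dz <- L / (nz - 1)
  dt <- t_end / nt
  n <- nz - 2L
  a <- D / dz^2
  b <- V / (2 * dz)
  A <- Matrix::bandSparse(n, n, k = -1:1,
                          diagonals = list(rep(a + b, n - 1L),
                                           rep(-2 * a, n),
                                           rep(a - b, n - 1L)))
  I <- Matrix::Diagonal(n)
  lu <- Matrix::lu(I - dt / 2 * A)
  M2 <- I + dt / 2 * A
  bc <- numeric(n)
  bc[1] <- (a + b) # inflow boundary F(0) = 1
  u <- numeric(n)
  for (k in seq_len(nt)) {
    u <- as.numeric(Matrix::solve(lu, as.numeric(M2 %*% u) + dt * bc))
  }
  list(z = seq(0, L, length.out = nz), F = c(1, u, 0))
}

# Naive exhaustive 5-deep enumeration of CHNOS compositions matching a
# neutral mass within bounds: the brute-force mirror of decompose_mass,
# including its plausibility filters, written independently.
naive_decompose <- function(neutral, bounds) {
  masses <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
              O = 15.9949146221, S = 31.97207069)
  hits <- list()
  for (nC in bounds$C[1]:bounds$C[2])
    for (nH in bounds$H[1]:bounds$H[2])
      for (nN in bounds$N[1]:bounds$N[2])
        for (nO in bounds$O[1]:bounds$O[2])
          for (nS in bounds$S[1]:bounds$S[2]) {
            m <- nC * masses["C"] + nH * masses["H"] + nN * masses["N"] +
              nO * masses["O"] + nS * masses["S"]
            ppm <- (m - neutral) / neutral * 1e6
            if (abs(ppm) > bounds$ppm_tol) next
            rdbe <- nC - nH / 2 + nN / 2 + 1
            if (rdbe < 0 || rdbe > bounds$rdbe_max || rdbe %% 1 != 0) next
            hc <- nH / nC
            oc <- nO / nC
            if (hc < bounds$hc_range[1] || hc > bounds$hc_range[2]) next
            if (oc < bounds$oc_range[1] || oc > bounds$oc_range[2]) next
            hits[[length(hits) + 1L]] <-
              data.frame(nC = nC, nH = nH, nN = nN, nO = nO, nS = nS,
                         ppm_error = unname(ppm))
          }
  if (length(hits) == 0L)
    return(data.frame(nC = integer(), nH = integer(), nN = integer(),
                      nO = integer(), nS = integer(), ppm_error = numeric()))
  do.call(rbind, hits)
}

# canonical formula key for set comparisons in tests
fkey <- function(df) paste(df$nC, df$nH, df$nN, df$nO, df$nS, sep = "_")

# published transport parameter set for Lake Hephaestus magnesium
hephaestus_mg_params <- function() {
  transport_params(Ds = 2.4e-10, Vs = 9.51e-11, C0 = 4720, Cbg = 61)
}
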