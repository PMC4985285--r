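# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

## ---- double-double (~32 significant digits) arithmetic ----
## Dekker/Knuth error-free transformations; enough precision to serve as an
## extended-precision product oracle for birthday-collision probabilities.

dd_two_sum <- function(a, b) {
  s <- a + b
  bb <- s - a
  err <- (a - (s - bb)) + (b - bb)
  c(s, err)
}

dd_split <- function(a) {
  t <- 134217729 * a  # 2^27 + 1
  hi <- t - (t - a)
  c(hi, a - hi)
}

dd_two_prod <- function(a, b) {
  p <- a * b
  as_ <- dd_split(a); bs <- dd_split(b)
  err <- ((as_[1] * bs[1] - p) + as_[1] * bs[2] + as_[2] * bs[1]) +
    as_[2] * bs[2]
  c(p, err)
}

dd_add <- function(x, y) {
  s <- dd_two_sum(x[1], y[1])
  e <- s[2] + x[2] + y[2]
  dd_two_sum(s[1], e)
}

dd_mul <- function(x, y) {
  p <- dd_two_prod(x[1], y[1])
  e <- p[2] + x[1] * y[2] + x[2] * y[1]
  dd_two_sum(p[1], e)
}

dd_from_ratio <- function(num, den) {
  q1 <- num / den
  p <- dd_two_prod(q1, den)
  r <- (num - p[1]) - p[2]
  c(q1, r / den)
}

# P(any collision among n uniform draws from N), exact product formula in
# double-double arithmetic
collision_oracle_dd <- function(n, N) {
  if (n > N) return(1)
  if (n < 2) return(0)
  prod <- c(1, 0)
  for (i in seq_len(n - 1)) {
    frac <- dd_from_ratio(i, N)
    fac <- dd_add(c(1, 0), -frac)
    prod <- dd_mul(prod, fac)
  }
  res <- dd_add(c(1, 0), -prod)
  res[1] + res[2]
}

## ---- RK4 integration of the 1:1 Langmuir ODE ----
## dR/dt = kon*C*(Rmax - R) - koff*R, integrated phase by phase on the
## protocol schedule; an independent check on the closed-form simulator.

ode_langmuir_rk4 <- function(times, protocol, kon, koff, Rmax, dt = 0.02) {
  conc <- protocol$concentrations
  n_inj <- length(conc)
  phases <- list()
  t0 <- 0
  for (i in seq_len(n_inj)) {
    phases[[length(phases) + 1L]] <- c(t0, t0 + protocol$t_assoc, conc[i])
    t0 <- t0 + protocol$t_assoc
    if (i < n_inj && protocol$t_gap > 0) {
      phases[[length(phases) + 1L]] <- c(t0, t0 + protocol$t_gap, 0)
      t0 <- t0 + protocol$t_gap
    }
  }
  phases[[length(phases) + 1L]] <- c(t0, t0 + protocol$t_final, 0)

  deriv <- function(R, C) kon * C * (Rmax - R) - koff * R
  out <- numeric(length(times))
  R <- 0
  for (ph in phases) {
    t_start <- ph[1]; t_end <- ph[2]; C <- ph[3]
    sel <- which(times >= t_start & times <= t_end)
    # march through the phase, recording R at each requested time
    t_cur <- t_start
    R_cur <- R
    for (j in sel) {
      target <- times[j]
      while (t_cur < target - 1e-12) {
        h <- min(dt, target - t_cur)
        k1 <- deriv(R_cur, C)
        k2 <- deriv(R_cur + h / 2 * k1, C)
        k3 <- deriv(R_cur + h / 2 * k2, C)
        k4 <- deriv(R_cur + h * k3, C)
        R_cur <- R_cur + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        t_cur <- t_cur + h
      }
      out[j] <- R_cur
    }
    # finish the phase to carry R across the boundary
    while (t_cur < t_end - 1e-12) {
      h <- min(dt, t_end - t_cur)
      k1 <- deriv(R_cur, C)
      k2 <- deriv(R_cur + h / 2 * k1, C)
      k3 <- deriv(R_cur + h / 2 * k2, C)
      k4 <- deriv(R_cur + h * k3, C)
      R_cur <- R_cur + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_cur <- t_cur + h
    }
    R <- R_cur
  }
  out
}

## ---- brute-force per-column counting ----

brute_consensus <- function(seqs) {
  L <- nchar(seqs[1])
  cons <- character(L)
  for (j in seq_len(L)) {
    col <- substr(seqs, j, j)
    tab <- table(col)
    best <- names(tab)[tab == max(tab)]
    cons[j] <- sort(best)[1]  # alphabetical tie-break
  }
  paste(cons, collapse = "")
}

brute_column_freq <- function(seqs, j, levels) {
  col <- substr(seqs, j, j)
  vapply(levels, function(a) mean(col == a), numeric(1))
}

## ---- misc helpers ----

random_profile <- function(support = setdiff(AA_CANONICAL, "C")) {
  w <- runif(length(support))
  position_profile(setNames(w / sum(w), support))
}

random_aa_seqs <- function(n, L, alphabet = AA_CANONICAL) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
}
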