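# Shared fixtures and independent oracles for the test suite.

# random interior 4-cell probability vector with all margins bounded away
# from zero (Dirichlet-ish via normalized gammas, floored)
rand_cell_probs <- function(floor = 0.02) {
  repeat {
    p <- stats::rgamma(4, shape = 1)
    p <- p / sum(p)
    if (all(p > floor)) return(cell_probs(p[1], p[2], p[3], p[4]))
  }
}

rand_paired_probs <- function(floor = 0.01) {
  repeat {
    p <- stats::rgamma(8, shape = 1)
    p <- p / sum(p)
    if (all(p > floor)) return(paired_cell_probs(p))
  }
}

PAIRED_CELLS <- c("p111", "p110", "p101", "p100", "p011", "p010", "p001", "p000")

rand_paired_counts <- function(n = 500) {
  p <- as.numeric(rand_paired_probs())
  repeat {
    cnt <- as.numeric(stats::rmultinom(1, n, p))
    names(cnt) <- PAIRED_CELLS
    pc <- paired_counts(cnt)
    m1 <- marginalize(pc, 1); m2 <- marginalize(pc, 2)
    if (!is.na(mcc(m1)) && !is.na(mcc(m2)) &&
        abs(mcc(m1)) < 1 && abs(mcc(m2)) < 1) return(pc)
  }
}

# swap the two classifiers of a paired table
swap_classifiers <- function(x) {
  v <- as.numeric(x)
  names(v) <- sub("^p(.)(.)(.)$", "p\\2\\1\\3", names(x))
  if (inherits(x, "paired_counts")) paired_counts(v) else paired_cell_probs(v)
}

# phi / psi evaluated on bare vectors, used as finite-difference targets
phi_raw <- function(p) {
  (p[1] * p[4] - p[2] * p[3]) /
    sqrt((p[1] + p[2]) * (p[1] + p[3]) * (p[4] + p[2]) * (p[4] + p[3]))
}
J1 <- rbind(c(1,0,1,0,0,0,0,0), c(0,1,0,1,0,0,0,0),
            c(0,0,0,0,1,0,1,0), c(0,0,0,0,0,1,0,1))
J2 <- rbind(c(1,0,0,0,1,0,0,0), c(0,1,0,0,0,1,0,0),
            c(0,0,1,0,0,0,1,0), c(0,0,0,1,0,0,0,1))
psi_raw <- function(p) phi_raw(drop(J1 %*% p)) - phi_raw(drop(J2 %*% p))

half_width <- function(ci) (ci$upper - ci$lower) / 2

rel_err <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-8))
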