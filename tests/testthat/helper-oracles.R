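# Independent oracles, kept deliberately separate from the package's own
# implementations: a dense nodal-analysis solver for the resistor network
# (plain R, Dirichlet formulation) and a variance-components ICC computed
# through stats::aov.

# connected component (node ids over 1..m rows, m+1..m+n cols) containing `start`
.net_component <- function(g, start) {
  m <- nrow(g); n <- ncol(g)
  seen <- logical(m + n)
  queue <- start
  seen[start] <- TRUE
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    if (u <= m) {
      nb <- m + which(g[u, ] > 0)
    } else {
      nb <- which(g[, u - m] > 0)
    }
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  which(seen)
}

# Effective conductance between row line `row` and column line `col` with all
# other lines floating: fix the two selected potentials (1 V / 0 V), solve the
# Kirchhoff current balance at every other connected node, return the current
# leaving the source node. Zero-conductance-isolated nodes carry no current
# and are eliminated.
oracle_forward_equivalent <- function(g, row, col) {
  g <- as.matrix(g)
  m <- nrow(g); n <- ncol(g)
  a <- row; b <- m + col
  v <- numeric(m + n)
  v[a] <- 1
  comp <- .net_component(g, a)
  if (!(b %in% comp)) return(0)     # no path: no current flows
  deg <- c(rowSums(g), colSums(g))
  unk <- setdiff(comp, c(a, b))
  if (length(unk) > 0) {
    A <- matrix(0, length(unk), length(unk))
    rhs <- numeric(length(unk))
    for (ii in seq_along(unk)) {
      u <- unk[ii]
      A[ii, ii] <- deg[u]
      if (u <= m) {
        for (c2 in which(g[u, ] > 0)) {
          vn <- m + c2; w <- g[u, c2]
          if (vn == a) rhs[ii] <- rhs[ii] + w
          else if (vn != b) A[ii, match(vn, unk)] <- A[ii, match(vn, unk)] - w
        }
      } else {
        c2 <- u - m
        for (r2 in which(g[, c2] > 0)) {
          vn <- r2; w <- g[r2, c2]
          if (vn == a) rhs[ii] <- rhs[ii] + w
          else if (vn != b) A[ii, match(vn, unk)] <- A[ii, match(vn, unk)] - w
        }
      }
    }
    v[unk] <- solve(A, rhs)
  }
  sum(g[row, ] * (1 - v[m + seq_len(n)]))
}

# ICC(A,1) through an independently computed two-way ANOVA decomposition
oracle_icc <- function(ref, test) {
  n <- length(ref)
  k <- 2
  d <- data.frame(y = c(ref, test),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- stats::anova(stats::aov(y ~ subj + rater, data = d))[["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
}

# population (denominator-N) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# small, fast synthetic cohort for module-level tests
tiny_cohort <- function(n_subjects = 4, duration = 12, master_seed = 11, ...) {
  simulate_cohort(cohort_config(n_subjects = n_subjects, duration = duration,
                                master_seed = master_seed, ...))
}
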