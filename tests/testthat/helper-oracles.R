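# Independent brute-force oracles used to cross-check the package's
# implementations on tiny inputs. These deliberately avoid the code paths
# (and, where possible, the libraries) they verify.

# Faith's PD by exhaustive union of root paths: for every present tip walk
# the parent pointers to the root, take the union of visited edges and sum
# their lengths.
oracle_faith_pd <- function(tree, present) {
  parent_edge <- function(node) which(tree$edge[, 2] == node)
  used <- integer(0)
  for (tip in match(present, tree$tip.label)) {
    node <- tip
    repeat {
      e <- parent_edge(node)
      if (length(e) == 0) break
      used <- union(used, e)
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[used])
}

# PERMANOVA one-factor R^2 and pseudo-F by direct partition of the squared
# dissimilarities (Anderson's sums-of-squares identities).
oracle_permanova_stats <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.factor(groups)
  sst <- sum(dm[lower.tri(dm)]^2) / n
  ssw <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- dm[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  ssa <- sst - ssw
  a <- nlevels(groups)
  list(r_squared = ssa / sst,
       pseudo_f = (ssa / (a - 1)) / (ssw / (n - a)))
}

# Bray-Curtis from the definition, one pair at a time.
oracle_bray <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# Shannon entropy from the definition.
oracle_shannon <- function(counts, base = 2) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

# Welch two-sample t statistic and CI from the textbook formulas.
oracle_welch <- function(xb, xa, conf = 0.95) {
  na <- length(xa); nb <- length(xb)
  va <- var(xa) / na; vb <- var(xb) / nb
  se <- sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  delta <- mean(xb) - mean(xa)
  tcrit <- qt(1 - (1 - conf) / 2, df)
  list(t = delta / se, lo = delta - tcrit * se, hi = delta + tcrit * se,
       p = 2 * pt(-abs(delta / se), df))
}

# Cycle segmentation by an explicit sample-by-sample state machine.
oracle_segment <- function(v, thr) {
  starts <- integer(0); below <- 0L; armed <- TRUE
  for (i in seq_along(v)) {
    if (v[i] >= thr) {
      if (armed) starts <- c(starts, i)
      armed <- FALSE; below <- 0L
    } else {
      below <- below + 1L
      if (below >= 2L) armed <- TRUE
    }
  }
  starts
}

# A small fully consistent synthetic reactor configuration reused across
# round-trip tests.
demo_reactor_config <- function() {
  list(reactor_id = "rt", applied_potential = 0.5,
       consumed_fraction = 0.25, yield_ethanol = 0.4, yield_acetate = 0.3,
       h2_umol = 0.2, c_i = 0.8, peak_current = 4e-6, peak_time = 40,
       unaccounted_carbon = 0.2)
}
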