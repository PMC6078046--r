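# Independent oracles used across the suite.

# Path-counting relationship oracle (Wright's paths): completely independent
# of the tabular recursion. Suitable for small pedigrees only.
path_counting_A <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  # all ancestor paths from animal i (each path starts at i, ends at an
  # ancestor, no repeats by construction since pedigrees are acyclic)
  paths_up <- function(i) {
    out <- list(i)
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) out <- c(out, lapply(paths_up(p), function(q) c(i, q)))
    }
    out
  }
  Fcoef <- numeric(n)  # inbreeding, filled in pedigree (topological) order
  pair_contrib <- function(pi, pj) {
    tot <- 0
    for (p in pi) for (q in pj) {
      a <- p[length(p)]
      if (q[length(q)] != a) next
      if (length(intersect(p, q)) != 1L) next  # must meet only at the ancestor
      tot <- tot + 0.5^((length(p) - 1) + (length(q) - 1)) * (1 + Fcoef[a])
    }
    tot
  }
  for (i in seq_len(n)) {
    if (!is.na(si[i]) && !is.na(di[i])) {
      # F_i = kinship(sire, dam) = A_{s,d} / 2 by paths
      Fcoef[i] <- pair_contrib(paths_up(si[i]), paths_up(di[i])) / 2
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  all_paths <- lapply(seq_len(n), paths_up)
  for (i in seq_len(n)) {
    A[i, i] <- 1 + Fcoef[i]
    for (j in seq_len(n)) {
      if (j < i) A[i, j] <- A[j, i] <- pair_contrib(all_paths[[i]], all_paths[[j]])
    }
  }
  A
}

# Random multi-generation pedigree with occasional related matings (so the
# inverse rules are exercised with nonzero inbreeding).
random_pedigree <- function(n, seed) {
  withr::local_seed(seed)
  id <- sprintf("A%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  nf <- max(3, ceiling(n / 4))
  for (i in (nf + 1):n) {
    pool <- id[seq_len(i - 1)]
    pick <- sample(pool, 2)
    sire[i] <- pick[1]; dam[i] <- pick[2]
  }
  as_pedigree(id = id, sire = sire, dam = dam)
}

# Fan-triangulation area oracle for convex polygons.
triangulation_area <- function(p) {
  tot <- 0
  for (k in 2:(nrow(p) - 1)) {
    a <- p[1, ]; b <- p[k, ]; c <- p[k + 1, ]
    tot <- tot + abs((b[1] - a[1]) * (c[2] - a[2]) -
                     (c[1] - a[1]) * (b[2] - a[2])) / 2
  }
  tot
}

# small config shortcut for fast simulated studies
quick_config <- function(n = 300, seed = 1, ...) {
  sim_config(offspring_total = n, seed = seed, ...)
}
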