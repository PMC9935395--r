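# Brute-force oracles: naive all-pairs scans kept deliberately independent of
# the package's vectorized implementations.

atom_xyz <- function(at, i) as.numeric(at[i, c("x", "y", "z")])

# interface residue sets by scanning every heavy-atom pair
brute_interface <- function(structure, chain_a, chain_b, cutoff = 10) {
  a <- chain_atoms(structure, chain_a)
  b <- chain_atoms(structure, chain_b)
  ra <- character(0); rb <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((atom_xyz(a, i) - atom_xyz(b, j))^2))
      if (d <= cutoff) {
        ra <- c(ra, paste(a$resno[i], a$insert[i]))
        rb <- c(rb, paste(b$resno[j], b$insert[j]))
      }
    }
  }
  list(a = sort(unique(ra)), b = sort(unique(rb)))
}

# Calpha-Calpha contact count by scanning every pair
brute_ca_contacts <- function(structure, chain_a, chain_b, cutoff = 8) {
  a <- chain_atoms(structure, chain_a, elety = "CA")
  b <- chain_atoms(structure, chain_b, elety = "CA")
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (sqrt(sum((atom_xyz(a, i) - atom_xyz(b, j))^2)) < cutoff) n <- n + 1L
    }
  }
  n
}

# clash fraction by scanning every candidate residue against every placed atom
brute_clash_fraction <- function(candidate_ca, placed_ca, clash_distance = 5) {
  if (nrow(placed_ca) == 0) return(0)
  hits <- 0L
  for (i in seq_len(nrow(candidate_ca))) {
    mind <- Inf
    for (j in seq_len(nrow(placed_ca))) {
      mind <- min(mind, sqrt(sum((candidate_ca[i, ] - placed_ca[j, ])^2)))
    }
    if (mind < clash_distance) hits <- hits + 1L
  }
  hits / nrow(candidate_ca)
}

# two-sided Fisher exact p by enumerating all tables with fixed margins
brute_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n_, k - x) - lchoose(m + n_, k)), numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
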