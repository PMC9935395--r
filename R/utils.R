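# shared numerical helpers

# All-pairs Euclidean distances between two n x 3 coordinate matrices.
# Returns an nrow(a) x nrow(b) matrix; clamped at zero before sqrt to
# absorb negative round-off on identical points.
cross_dist <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# residue key used wherever (protein, position) pairs index sites
site_key <- function(protein, position) paste(protein, position, sep = "_")
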