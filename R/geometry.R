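#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1; reflections suppressed) and
#' translation `t` minimizing the RMSD of `R p + t` against `q` over matched
#' points.
#'
#' @param p,q Matched n x 3 coordinate matrices (n >= 3, not all collinear).
#' @return A `cf_transform`: list with `rotation` (3 x 3), `translation`
#'   (length 3) and `rmsd` (Angstrom) at the optimum.
#' @export
kabsch <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!all(dim(p) == dim(q)) || ncol(p) != 3)
    abort("p and q must be matched n x 3 matrices")
  if (nrow(p) < 3) abort("at least 3 matched points are required")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  h <- crossprod(pc, qc)
  sv <- svd(h)
  # collinear point sets leave the rotation about the axis undetermined
  spread_p <- svd(pc, nu = 0, nv = 0)$d
  if (spread_p[2] < 1e-8 * max(spread_p[1], 1e-12))
    abort("degenerate (collinear) point set")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cq - r %*% cp)
  fitted <- sweep(tcrossprod(p, r), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - q)^2)))
  new_transform(r, tr, rmsd)
}

# weighted least-squares rigid superposition (weights >= 0, not all zero)
kabsch_weighted <- function(p, q, w) {
  w <- w / sum(w)
  cp <- colSums(p * w); cq <- colSums(q * w)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  h <- crossprod(pc * w, qc)
  sv <- svd(h)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) abort("degenerate weighted fit")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  new_transform(r, as.numeric(cq - r %*% cp))
}

new_transform <- function(rotation, translation, rmsd = NA_real_) {
  stopifnot(max(abs(crossprod(rotation) - diag(3))) < 1e-6,
            abs(det(rotation) - 1) < 1e-6)
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 rmsd = rmsd),
            class = "cf_transform")
}

#' @export
print.cf_transform <- function(x, ...) {
  cat("<cf_transform> rmsd:", format(x$rmsd, digits = 4), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param transform A `cf_transform`.
#' @param x An n x 3 matrix, an atom tibble with `x`,`y`,`z` columns, or a
#'   `cf_structure`.
#' @return The transformed object, same type as `x`.
#' @export
apply_transform <- function(transform, x) {
  tf_mat <- function(m)
    sweep(tcrossprod(as.matrix(m), transform$rotation), 2,
          transform$translation, "+")
  if (inherits(x, "cf_structure")) {
    x$atoms[, c("x", "y", "z")] <- as.data.frame(tf_mat(coords_matrix(x$atoms)))
    x
  } else if (is.data.frame(x)) {
    x[, c("x", "y", "z")] <- as.data.frame(tf_mat(coords_matrix(x)))
    x
  } else {
    tf_mat(x)
  }
}

#' Compose two rigid transforms
#' @param a,b `cf_transform`s; the result applies `b` first, then `a`.
#' @return A `cf_transform`.
#' @export
compose_transforms <- function(a, b) {
  new_transform(a$rotation %*% b$rotation,
                as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform A `cf_transform`.
#' @return A `cf_transform`.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  new_transform(rt, as.numeric(-rt %*% transform$translation))
}

#' TM-score normalization distance d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom (the floor is
#' binding for reference lengths up to 21).
#'
#' @param l Reference length (residues).
#' @return d0 in Angstrom.
#' @examples
#' tm_d0(100)  # ~3.652
#' @export
tm_d0 <- function(l) {
  out <- ifelse(l > 15, 1.24 * (l - 15)^(1 / 3) - 1.8, 0.5)
  pmax(out, 0.5)
}

#' TM-score between residue-matched coordinate sets
#'
#' `TM = max over superpositions of (1/L) * sum 1/(1 + (d_i/d0)^2)`,
#' normalized by the reference length `L`. The maximization seeds Kabsch fits
#' from contiguous fragments of length L, L/2, L/4, ..., 4 and iteratively
#' refits on the residues with `d_i < d0` until the inclusion set is stable,
#' keeping the best score seen.
#'
#' @param mobile,reference Matched n x 3 Calpha coordinate matrices
#'   (row i of `mobile` corresponds to row i of `reference`).
#' @param d0 Optional override of [tm_d0()] (e.g. to normalize by a longer
#'   reference of which these are the matched subset).
#' @param l_norm Normalization length; defaults to `nrow(reference)`.
#' @return A `cf_superposition`: `tm_score`, best `transform`, `rmsd` over
#'   all matched points at that transform, and `n_matched`.
#' @export
tm_score <- function(mobile, reference, d0 = NULL, l_norm = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    abort("mobile and reference must be matched n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) abort("at least 3 matched residues are required")
  l_norm <- l_norm %||% n
  d0 <- d0 %||% tm_d0(l_norm)

  score_at <- function(tf) {
    d <- sqrt(rowSums((apply_transform(tf, mobile) - reference)^2))
    list(tm = sum(1 / (1 + (d / d0)^2)) / l_norm, d = d)
  }

  best <- list(tm = -Inf, tf = NULL)
  len <- n
  lens <- integer(0)
  while (len >= 4) { lens <- c(lens, len); len <- len %/% 2 }
  if (n >= 3 && length(lens) == 0) lens <- n
  for (len in unique(pmin(lens, n))) {
    starts <- unique(c(seq(1, n - len + 1, by = max(1, len %/% 2)), n - len + 1))
    for (s in starts) {
      idx <- s:(s + len - 1)
      tf <- tryCatch(kabsch(mobile[idx, , drop = FALSE],
                            reference[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(tf)) next
      for (iter in 1:30) {
        sc <- score_at(tf)
        if (sc$tm > best$tm) best <- list(tm = sc$tm, tf = tf)
        new_idx <- which(sc$d < d0)
        if (length(new_idx) < 3 || identical(new_idx, idx)) break
        idx <- new_idx
        tf <- tryCatch(kabsch(mobile[idx, , drop = FALSE],
                              reference[idx, , drop = FALSE]),
                       error = function(e) NULL)
        if (is.null(tf)) break
      }
    }
  }
  if (is.null(best$tf)) abort("no valid superposition seed found")
  # polish with iteratively reweighted Kabsch (weights = d/dd of the TM term)
  tf <- best$tf
  for (iter in 1:50) {
    d <- sqrt(rowSums((apply_transform(tf, mobile) - reference)^2))
    w <- 1 / (1 + (d / d0)^2)^2
    tf2 <- tryCatch(kabsch_weighted(mobile, reference, w),
                    error = function(e) NULL)
    if (is.null(tf2)) break
    sc <- score_at(tf2)
    if (sc$tm <= best$tm + 1e-12) break
    best <- list(tm = sc$tm, tf = tf2)
    tf <- tf2
  }
  d_all <- sqrt(rowSums((apply_transform(best$tf, mobile) - reference)^2))
  structure(list(tm_score = best$tm, transform = best$tf,
                 rmsd = sqrt(mean(d_all^2)), n_matched = n),
            class = "cf_superposition")
}

#' @export
print.cf_superposition <- function(x, ...) {
  cat(sprintf("<cf_superposition> TM-score %.4f  rmsd %.3f A  (%d matched)\n",
              x$tm_score, x$rmsd, x$n_matched))
  invisible(x)
}

#' TM-score between two chains matched by residue number
#'
#' Correspondence is the intersection of Calpha residue numbers (intended for
#' two models of the same protein); an explicit correspondence can be given.
#'
#' @param structure_a,structure_b `cf_structure`s.
#' @param chain_a,chain_b Chain ids (mobile = a, reference = b).
#' @param correspondence Optional two-column matrix/data frame of residue
#'   numbers (`resno_a`, `resno_b`).
#' @inheritParams tm_score
#' @return A `cf_superposition`.
#' @export
tm_score_chains <- function(structure_a, chain_a, structure_b, chain_b,
                            correspondence = NULL, d0 = NULL) {
  ca_a <- chain_atoms(structure_a, chain_a, elety = "CA")
  ca_b <- chain_atoms(structure_b, chain_b, elety = "CA")
  if (is.null(correspondence)) {
    shared <- intersect(ca_a$resno, ca_b$resno)
    if (length(shared) == 0) abort("empty residue correspondence")
    correspondence <- cbind(shared, shared)
  }
  correspondence <- as.matrix(correspondence)
  ia <- match(correspondence[, 1], ca_a$resno)
  ib <- match(correspondence[, 2], ca_b$resno)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) abort("empty residue correspondence")
  tm_score(coords_matrix(ca_a)[ia[ok], , drop = FALSE],
           coords_matrix(ca_b)[ib[ok], , drop = FALSE], d0 = d0)
}

#' RMSD and TM-score of an assembly against a reference structure
#'
#' Chains are matched by protein accession; when a protein occurs in several
#' copies, the copy assignment minimizing the global RMSD is found by
#' exhaustive search over per-protein permutations (up to 8 copies /
#' `max_combinations` total assignments; greedy order otherwise). A single
#' global Kabsch superposition over all matched Calpha atoms yields the RMSD
#' and the TM-score, normalized by the total reference length.
#'
#' @param model A `cf_assembly` or a `cf_structure` with a `protein_map`.
#' @param reference A `cf_structure` (the experimental complex).
#' @param model_map,reference_map Tibbles `chain`, `protein` mapping chain ids
#'   to protein accessions. For a `cf_assembly`, `model_map` defaults to its
#'   own placement table.
#' @param max_combinations Cap on enumerated copy assignments, default 5000.
#' @return One-row tibble: `rmsd`, `tm_score`, `n_matched`, `n_chains_matched`.
#' @export
assembly_rmsd <- function(model, reference, model_map = NULL,
                          reference_map = NULL, max_combinations = 5000) {
  if (inherits(model, "cf_assembly")) {
    model_map <- model_map %||%
      tibble(chain = model$placed$chain_label, protein = model$placed$protein)
    model <- as_structure(model)
  }
  if (is.null(model_map) || is.null(reference_map))
    abort("model_map and reference_map (chain, protein) are required")

  ref_res_total <- nrow(distinct(reference$atoms, .data$chain, .data$resno,
                                 .data$insert))
  d0 <- tm_d0(ref_res_total)

  ca <- function(s, ch) {
    at <- chain_atoms(s, ch, elety = "CA")
    at[order(at$resno), c("resno", "x", "y", "z")]
  }

  # candidate chain pairings grouped by protein
  prots <- intersect(model_map$protein, reference_map$protein)
  if (length(prots) == 0) abort("no chains match between model and reference")
  per_prot <- lapply(prots, function(p) {
    mc <- model_map$chain[model_map$protein == p]
    rc <- reference_map$chain[reference_map$protein == p]
    k <- min(length(mc), length(rc))
    # assignments: which model chain maps to which reference chain
    perms <- perms_of(seq_along(mc), seq_along(rc), k)
    list(model = mc, ref = rc, assignments = perms)
  })
  n_comb <- prod(vapply(per_prot, function(z) length(z$assignments), 1))
  if (n_comb > max_combinations) {
    per_prot <- lapply(per_prot, function(z) {
      z$assignments <- z$assignments[1]
      z
    })
  }

  eval_assignment <- function(choice) {
    pm <- list(); pr <- list(); nchain <- 0
    for (i in seq_along(per_prot)) {
      z <- per_prot[[i]]
      asg <- z$assignments[[choice[i]]]
      for (j in seq_len(nrow(asg))) {
        a <- ca(model, z$model[asg[j, 1]])
        b <- ca(reference, z$ref[asg[j, 2]])
        shared <- intersect(a$resno, b$resno)
        if (length(shared) == 0) next
        pm[[length(pm) + 1]] <- coords_matrix(a[match(shared, a$resno), ])
        pr[[length(pr) + 1]] <- coords_matrix(b[match(shared, b$resno), ])
        nchain <- nchain + 1
      }
    }
    if (nchain == 0) return(NULL)
    p <- do.call(rbind, pm); q <- do.call(rbind, pr)
    if (nrow(p) < 3) return(NULL)
    tf <- kabsch(p, q)
    d <- sqrt(rowSums((apply_transform(tf, p) - q)^2))
    list(rmsd = tf$rmsd, tm = sum(1 / (1 + (d / d0)^2)) / ref_res_total,
         n = nrow(p), nchain = nchain)
  }

  grid <- expand.grid(lapply(per_prot, function(z) seq_along(z$assignments)))
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    res <- eval_assignment(as.integer(grid[g, ]))
    if (!is.null(res) && (is.null(best) || res$rmsd < best$rmsd)) best <- res
  }
  if (is.null(best)) abort("no chains match between model and reference")
  tibble(rmsd = best$rmsd, tm_score = best$tm, n_matched = best$n,
         n_chains_matched = best$nchain)
}

# all injective assignments of k model copies to k reference copies,
# as a list of k x 2 index matrices
perms_of <- function(midx, ridx, k) {
  if (k == 0) return(list())
  mcomb <- combn(midx, k, simplify = FALSE)
  rperm <- perm_list(ridx, k)
  out <- list()
  for (mc in mcomb) for (rp in rperm)
    out[[length(out) + 1]] <- cbind(mc, rp)
  out
}

perm_list <- function(v, k) {
  if (k == 1) return(lapply(v, identity))
  out <- list()
  for (i in seq_along(v)) {
    rest <- perm_list(v[-i], k - 1)
    for (r in rest) out[[length(out) + 1]] <- c(v[i], r)
  }
  out
}
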