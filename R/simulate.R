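# Synthetic ground-truth fixtures: idealized multi-chain complexes with known
# rigid transforms, planted crosslinks, and planted co-regulation clusters.
# Geometry is idealized (poly-lysine alpha-helices carrying CA, CB and NZ
# atoms) so that every geometric ground truth is exact by construction.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_rigid_motion <- function(translation_range = 20) {
  new_transform(random_rotation(), runif(3, -translation_range, translation_range))
}

# ideal alpha-helix chain: CA on a helix (radius 2.3 A, 100 deg/residue,
# 1.5 A rise), CB and NZ displaced radially outward
helix_chain <- function(n_res, chain_id, plddt, resid = "LYS") {
  i <- seq_len(n_res)
  theta <- (i - 1) * 100 * pi / 180
  mk <- function(r, name) tibble(
    chain = chain_id, resno = i, insert = "", resid = resid,
    elety = name, element = substr(name, 1, 1),
    x = r * cos(theta), y = r * sin(theta), z = 1.5 * i,
    b = plddt, plddt = plddt)
  bind_rows(mk(2.3, "CA"), mk(3.8, "CB"), mk(6.3, "NZ")) |>
    arrange(.data$resno, match(.data$elety, c("CA", "CB", "NZ")))
}

chain_offsets <- function(n_chains, geometry, spacing) {
  switch(geometry,
    chain = cbind((seq_len(n_chains) - 1) * spacing, 0, 0),
    ring = {
      r <- spacing / (2 * sin(pi / n_chains))
      phi <- 2 * pi * (seq_len(n_chains) - 1) / n_chains
      cbind(r * cos(phi), r * sin(phi), 0)
    },
    packed = {
      ncol_ <- ceiling(sqrt(n_chains))
      k <- seq_len(n_chains) - 1
      cbind((k %% ncol_) * spacing, (k %/% ncol_) * spacing, 0)
    },
    abort("geometry must be chain, ring or packed"))
}

adjacent_pairs <- function(n_chains, geometry, spacing) {
  off <- chain_offsets(n_chains, geometry, spacing)
  d <- cross_dist(off, off)
  pairs <- which(upper.tri(d) & abs(d - spacing) < 1e-6, arr.ind = TRUE)
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

plddt_profile <- function(profile, n_res) {
  switch(profile,
    constant = rep(90, n_res),
    gradient = round(seq(95, 50, length.out = n_res), 2),
    noisy = round(runif(n_res, 60, 95), 2),
    abort("plddt profile must be constant, gradient or noisy"))
}

#' Generate a synthetic multi-chain complex with ground-truth dimers
#'
#' Builds an idealized complex of poly-lysine alpha-helices (each residue
#' carries CA, CB and NZ heavy atoms) arranged so that adjacent chains form a
#' genuine interface (more than 20 Calpha contacts under 8 Angstrom) while
#' non-adjacent chains make no Calpha contacts — asserted post hoc. Each
#' adjacent pair is exported as a stand-alone dimer whose frame is the ground
#' truth perturbed by a recorded random rigid motion, emulating independently
#' predicted dimer models. Deterministic per seed.
#'
#' @param n_chains Number of chains (>= 2). Chains are labeled A, B, ... and
#'   assigned synthetic protein accessions P1, P2, ...
#' @param residues_per_chain Residues per chain (>= 10), default 30. At the
#'   default spacing, roughly 24 or more residues are needed for adjacent
#'   helices to exceed 20 Calpha contacts; shorter chains fail the adjacency
#'   assertion with an error.
#' @param geometry `"chain"` (linear), `"ring"`, or `"packed"` (grid).
#' @param spacing Axis-to-axis distance between adjacent chains in Angstrom,
#'   default 10 (adjacent helices then span Calpha distances of roughly
#'   5.4-14.6 Angstrom: contacts but no clashes).
#' @param plddt `"constant"` (90), `"gradient"` (95 down to 50), or
#'   `"noisy"` (uniform 60-95).
#' @param seed Integer seed; same seed gives identical output.
#' @return A list: `complex` (ground-truth `cf_structure`), `dimers` (tibble
#'   with `dimer_id`, `structure` list-column, `chain_a`, `protein_a`,
#'   `chain_b`, `protein_b`, `pdockq`), `transforms` (named list of
#'   `cf_transform` mapping each dimer's frame back onto the ground truth),
#'   and `chain_map` (tibble `chain`, `protein`).
#' @export
make_complex <- function(n_chains = 5, residues_per_chain = 30,
                         geometry = c("chain", "ring", "packed"),
                         spacing = 10, plddt = c("constant", "gradient", "noisy"),
                         seed = 1) {
  geometry <- match.arg(geometry)
  plddt <- match.arg(plddt)
  stopifnot(n_chains >= 2, residues_per_chain >= 10)
  with_seed(seed, {
    ids <- c(LETTERS, letters, as.character(0:9))[seq_len(n_chains)]
    off <- chain_offsets(n_chains, geometry, spacing)
    atoms <- bind_rows(lapply(seq_len(n_chains), function(k) {
      prof <- plddt_profile(plddt, residues_per_chain)
      ch <- helix_chain(residues_per_chain, ids[k], prof)
      ch$x <- ch$x + off[k, 1]; ch$y <- ch$y + off[k, 2]; ch$z <- ch$z + off[k, 3]
      ch
    }))
    complex <- new_structure(id = sprintf("synthetic_%s_%d", geometry, n_chains),
                             atoms = atoms, format = "synthetic")
    chain_map <- tibble(chain = ids, protein = paste0("P", seq_len(n_chains)))

    pairs <- adjacent_pairs(n_chains, geometry, spacing)
    # post-hoc adjacency invariant
    for (i in seq_len(n_chains - 1)) for (j in (i + 1):n_chains) {
      cd <- classify_direct(complex, ids[i], ids[j])
      adj <- any(pairs[, 1] == i & pairs[, 2] == j)
      if (adj && !cd$direct)
        abort("spacing violates the adjacency invariant (adjacent pair not direct)")
      if (!adj && cd$n_ca_contacts > 0)
        abort("spacing violates the adjacency invariant (non-adjacent contacts)")
    }

    dimers <- list(); transforms <- list()
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      dimer_id <- sprintf("D%02d_%s%s", r, ids[i], ids[j])
      motion <- random_rigid_motion()
      datoms <- atoms[atoms$chain %in% c(ids[i], ids[j]), , drop = FALSE]
      dstruct <- new_structure(id = dimer_id,
                               atoms = apply_transform(motion, datoms),
                               format = "synthetic")
      sc <- score_dimer(dstruct, ids[i], ids[j])
      dimers[[r]] <- tibble(dimer_id = dimer_id, structure = list(dstruct),
                            chain_a = ids[i], protein_a = chain_map$protein[i],
                            chain_b = ids[j], protein_b = chain_map$protein[j],
                            pdockq = sc$pdockq)
      transforms[[dimer_id]] <- invert_transform(motion)
    }
    list(complex = complex, dimers = bind_rows(dimers),
         transforms = transforms, chain_map = chain_map,
         geometry = geometry, spacing = spacing, seed = seed)
  })
}

#' Plant crosslinks with known satisfaction status
#'
#' Samples inter-chain lysine pairs from a synthetic complex so that a target
#' fraction lies within the crosslinkable span (NZ-NZ distance <=
#' `max_distance`) and the remainder beyond it, and emits the expected status
#' of every planted link for assertion.
#'
#' @param complex A `cf_structure` with lysine NZ atoms (e.g. from
#'   [make_complex()]).
#' @param chain_map Tibble `chain`, `protein`.
#' @param n_links Number of links to plant, default 20.
#' @param satisfied_fraction Target fraction at or under `max_distance`,
#'   default 0.5.
#' @param max_distance Span threshold in Angstrom, default 32.
#' @param seed Integer seed.
#' @return A list: `links` (tibble `protein_a`, `residue_a`, `protein_b`,
#'   `residue_b`) and `expected` (links plus `distance` and planted `status`).
#' @export
make_crosslinks <- function(complex, chain_map, n_links = 20,
                            satisfied_fraction = 0.5, max_distance = 32,
                            seed = 1) {
  nz <- complex$atoms[complex$atoms$elety == "NZ" &
                        complex$atoms$resid == "LYS", , drop = FALSE]
  if (nrow(nz) == 0) abort("complex has no lysine NZ atoms")
  with_seed(seed, {
    chains <- unique(nz$chain)
    if (length(chains) < 2) abort("need at least two chains bearing lysines")
    pool <- list()
    for (i in seq_along(chains)[-length(chains)])
      for (j in (i + 1):length(chains)) {
        a <- nz[nz$chain == chains[i], ]; b <- nz[nz$chain == chains[j], ]
        d <- cross_dist(coords_matrix(a), coords_matrix(b))
        idx <- which(d >= 0, arr.ind = TRUE)
        pool[[length(pool) + 1]] <- tibble(
          chain_a = chains[i], residue_a = a$resno[idx[, 1]],
          chain_b = chains[j], residue_b = b$resno[idx[, 2]],
          distance = d[idx])
      }
    pool <- bind_rows(pool)
    n_sat <- round(n_links * satisfied_fraction)
    sat_pool <- pool[pool$distance <= max_distance, ]
    vio_pool <- pool[pool$distance > max_distance, ]
    if (nrow(sat_pool) < n_sat || nrow(vio_pool) < n_links - n_sat)
      abort("not enough lysine pairs to plant the requested link mix")
    picked <- bind_rows(
      sat_pool[sample.int(nrow(sat_pool), n_sat), ],
      vio_pool[sample.int(nrow(vio_pool), n_links - n_sat), ])
    picked$status <- ifelse(picked$distance <= max_distance,
                            "satisfied", "violated")
    picked$protein_a <- chain_map$protein[match(picked$chain_a, chain_map$chain)]
    picked$protein_b <- chain_map$protein[match(picked$chain_b, chain_map$chain)]
    links <- picked[, c("protein_a", "residue_a", "protein_b", "residue_b")]
    list(links = links,
         expected = picked[, c("protein_a", "residue_a", "protein_b",
                               "residue_b", "distance", "status")])
  })
}

#' Generate a fold-change matrix with planted co-regulation clusters
#'
#' Each cluster draws one latent log2 fold-change signal per condition
#' (`N(0, signal_sd)`); a site's value is its cluster signal plus independent
#' Gaussian noise (`N(0, noise_sd)`). With `signal_sd/noise_sd` around 10 the
#' planted structure is strong, emulating clearly co-regulated interface
#' phosphosites; `signal_sd = 0` gives a null matrix with no structure.
#'
#' @param n_sites Number of phosphosites, default 60.
#' @param n_conditions Number of perturbation conditions, default 50.
#' @param n_clusters Number of planted clusters, default 3.
#' @param signal_sd SD of the shared per-cluster signal (log2 scale), default 2.
#' @param noise_sd SD of per-site noise, default 0.2.
#' @param missing_fraction Fraction of entries set missing at random, default 0.
#' @param seed Integer seed.
#' @return A list: `fc` (tibble `protein`, `position`, `cond_1`, ...) and
#'   `labels` (named integer vector of true cluster labels).
#' @export
make_fc_matrix <- function(n_sites = 60, n_conditions = 50, n_clusters = 3,
                           signal_sd = 2, noise_sd = 0.2,
                           missing_fraction = 0, seed = 1) {
  stopifnot(n_sites >= n_clusters, n_clusters >= 1)
  with_seed(seed, {
    labels <- sort(rep_len(seq_len(n_clusters), n_sites))
    latent <- matrix(rnorm(n_clusters * n_conditions, sd = signal_sd),
                     n_clusters, n_conditions)
    m <- latent[labels, , drop = FALSE] +
      matrix(rnorm(n_sites * n_conditions, sd = noise_sd), n_sites, n_conditions)
    if (missing_fraction > 0)
      m[sample.int(length(m), round(length(m) * missing_fraction))] <- NA
    colnames(m) <- paste0("cond_", seq_len(n_conditions))
    fc <- bind_cols(
      tibble(protein = paste0("SP", labels), position = seq_len(n_sites)),
      as_tibble(as.data.frame(m)))
    names(labels) <- site_key(fc$protein, fc$position)
    list(fc = fc, labels = labels)
  })
}
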