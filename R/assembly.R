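#' Assembly parameters
#'
#' Gates of the greedy dimer-assembly procedure: the shared chain of a
#' candidate dimer must superpose on its placed copy with TM-score strictly
#' above `tm_min`, and the incoming chain is rejected when strictly more than
#' `clash_fraction` of its residues lie within `clash_distance` (Calpha-
#' Calpha, strict `<`) of any placed chain.
#'
#' @param tm_min Shared-chain TM-score gate (strict `>`), default 0.8.
#' @param clash_distance Calpha clash distance in Angstrom (strict `<`),
#'   default 5.
#' @param clash_fraction Maximal tolerated clashing residue fraction
#'   (rejection requires strictly more), default 0.25.
#' @param start_dimer Optional dimer_id to seed from (default: highest pDockQ).
#' @param max_copies Cap on placed copies per protein, default `Inf`.
#' @return A list of class `cf_assembly_params`.
#' @export
assembly_params <- function(tm_min = 0.8, clash_distance = 5,
                            clash_fraction = 0.25, start_dimer = NULL,
                            max_copies = Inf) {
  stopifnot(tm_min > 0, clash_distance > 0,
            clash_fraction > 0, clash_fraction < 1)
  structure(list(tm_min = tm_min, clash_distance = clash_distance,
                 clash_fraction = clash_fraction, start_dimer = start_dimer,
                 max_copies = max_copies),
            class = "cf_assembly_params")
}

#' Rank dimers by pDockQ
#'
#' Descending pDockQ, ties broken lexicographically by `dimer_id` (stable and
#' deterministic).
#'
#' @param dimers Tibble with at least `dimer_id` and `pdockq` columns (see
#'   [make_complex()] or [read_dimer_manifest()]).
#' @return The reordered tibble.
#' @export
rank_dimers <- function(dimers) {
  if (nrow(dimers) == 0) return(dimers)
  arrange(dimers, desc(.data$pdockq), .data$dimer_id)
}

#' Clash fraction of a candidate chain against placed chains
#'
#' Fraction of the candidate's residues whose Calpha lies strictly within
#' `clash_distance` of any placed Calpha.
#'
#' @param candidate_ca n x 3 matrix of the candidate chain's Calpha
#'   coordinates (one row per residue).
#' @param placed_ca m x 3 matrix pooling the Calpha atoms of all placed
#'   chains (may have 0 rows).
#' @param clash_distance Strict Calpha-Calpha cutoff in Angstrom, default 5.
#' @return A fraction in \[0, 1\].
#' @export
chain_clash_fraction <- function(candidate_ca, placed_ca, clash_distance = 5) {
  candidate_ca <- as.matrix(candidate_ca)
  if (nrow(candidate_ca) == 0) abort("candidate has no Calpha atoms")
  if (is.null(placed_ca) || nrow(placed_ca) == 0) return(0)
  d <- cross_dist(candidate_ca, as.matrix(placed_ca))
  mean(apply(d, 1, min) < clash_distance)
}

new_assembly <- function(params) {
  structure(list(placed = tibble(chain_label = character(),
                                 protein = character(), copy = integer(),
                                 source_dimer = character(),
                                 atoms = list(), transform = list()),
                 log = tibble(sweep = integer(), dimer_id = character(),
                              action = character(), shared_protein = character(),
                              copy_tried = integer(), tm = numeric(),
                              clash_fraction = numeric()),
                 params = params),
            class = "cf_assembly")
}

#' @export
print.cf_assembly <- function(x, ...) {
  cat("<cf_assembly> ", nrow(x$placed), " placed chain(s): ",
      paste0(x$placed$protein, "/", x$placed$chain_label, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

assembly_chain_labels <- function(n) c(LETTERS, letters, as.character(0:9))[n]

place_chain <- function(assembly, protein, atoms, source_dimer, transform,
                        sweep, dimer_id, log_action, shared_protein = NA,
                        copy_tried = NA, tm = NA, clash = NA) {
  label <- assembly_chain_labels(nrow(assembly$placed) + 1)
  atoms$chain <- label
  copy <- sum(assembly$placed$protein == protein) + 1L
  assembly$placed <- bind_rows(assembly$placed, tibble(
    chain_label = label, protein = protein, copy = copy,
    source_dimer = source_dimer, atoms = list(atoms),
    transform = list(transform)))
  assembly$log <- bind_rows(assembly$log, tibble(
    sweep = sweep, dimer_id = dimer_id, action = log_action,
    shared_protein = as.character(shared_protein),
    copy_tried = as.integer(copy_tried),
    tm = as.numeric(tm), clash_fraction = as.numeric(clash)))
  assembly
}

log_decision <- function(assembly, sweep, dimer_id, action,
                         shared_protein = NA, copy_tried = NA, tm = NA,
                         clash = NA) {
  assembly$log <- bind_rows(assembly$log, tibble(
    sweep = sweep, dimer_id = dimer_id, action = action,
    shared_protein = as.character(shared_protein),
    copy_tried = as.integer(copy_tried), tm = as.numeric(tm),
    clash_fraction = as.numeric(clash)))
  assembly
}

placed_ca_pool <- function(assembly) {
  if (nrow(assembly$placed) == 0) return(matrix(numeric(), 0, 3))
  do.call(rbind, lapply(assembly$placed$atoms, function(at)
    coords_matrix(at[at$elety == "CA", , drop = FALSE])))
}

dimer_chain_atoms <- function(dimer_row, which_chain) {
  s <- dimer_row$structure[[1]]
  ch <- if (which_chain == "a") dimer_row$chain_a else dimer_row$chain_b
  chain_atoms(s, ch)
}

#' Attempt to add one dimer to a growing assembly
#'
#' Implements one step of the greedy procedure: the dimer must share exactly
#' one protein with the assembly; its shared chain is superposed (Kabsch over
#' Calpha atoms matched by residue number) onto each placed copy of that
#' protein in placement order; the superposition must pass the TM-score gate;
#' the transformed partner chain must not clash with the assembly. The first
#' copy passing both gates places the new chain. Every outcome is logged.
#'
#' @param assembly A `cf_assembly` (non-empty).
#' @param dimer One row of a dimer tibble (`dimer_id`, `structure`,
#'   `chain_a`, `protein_a`, `chain_b`, `protein_b`, `pdockq`).
#' @param params An [assembly_params()] object.
#' @param sweep Sweep counter recorded in the log.
#' @return List with `assembly` (updated) and `added` (logical).
#' @export
try_add_dimer <- function(assembly, dimer, params = assembly_params(),
                          sweep = 1L) {
  if (nrow(assembly$placed) == 0) abort("assembly is empty; seed it first")
  placed_prot <- assembly$placed$protein
  in_a <- dimer$protein_a %in% placed_prot
  in_b <- dimer$protein_b %in% placed_prot
  homodimer <- dimer$protein_a == dimer$protein_b

  if (!in_a && !in_b) {
    return(list(assembly = log_decision(assembly, sweep, dimer$dimer_id,
                                        "skipped_no_shared_chain"),
                added = FALSE))
  }
  if (in_a && in_b && !homodimer) {
    return(list(assembly = log_decision(assembly, sweep, dimer$dimer_id,
                                        "skipped_both_present"),
                added = FALSE))
  }

  # candidate (shared chain, incoming chain) pairings; a homodimer with its
  # protein placed tries both orientations
  cand <- if (homodimer) list(c("a", "b"), c("b", "a"))
          else if (in_a) list(c("a", "b")) else list(c("b", "a"))

  best_fail <- list(action = "rejected_tm", shared = NA, copy = NA,
                    tm = NA_real_, clash = NA_real_)
  for (orient in cand) {
    shared_prot <- if (orient[1] == "a") dimer$protein_a else dimer$protein_b
    new_prot <- if (orient[2] == "a") dimer$protein_a else dimer$protein_b
    if (sum(placed_prot == new_prot) >= params$max_copies) {
      return(list(assembly = log_decision(assembly, sweep, dimer$dimer_id,
                                          "skipped_max_copies",
                                          shared_protein = shared_prot),
                  added = FALSE))
    }
    shared_at <- dimer_chain_atoms(dimer, orient[1])
    new_at <- dimer_chain_atoms(dimer, orient[2])
    shared_ca <- shared_at[shared_at$elety == "CA", , drop = FALSE]

    copies <- which(placed_prot == shared_prot)
    for (ci in seq_along(copies)) {
      placed_at <- assembly$placed$atoms[[copies[ci]]]
      placed_ca <- placed_at[placed_at$elety == "CA", , drop = FALSE]
      shared_res <- intersect(shared_ca$resno, placed_ca$resno)
      if (length(shared_res) < 3) next
      p <- coords_matrix(shared_ca[match(shared_res, shared_ca$resno), ])
      q <- coords_matrix(placed_ca[match(shared_res, placed_ca$resno), ])
      sup <- tryCatch(tm_score(p, q), error = function(e) NULL)
      if (is.null(sup)) next
      if (sup$tm_score <= params$tm_min) {
        if (is.na(best_fail$tm) || sup$tm_score > best_fail$tm)
          best_fail <- list(action = "rejected_tm", shared = shared_prot,
                            copy = ci, tm = sup$tm_score, clash = NA_real_)
        next
      }
      tf <- kabsch(p, q)  # transform from all matched shared-chain Calphas
      moved <- apply_transform(tf, new_at)
      clash <- chain_clash_fraction(
        coords_matrix(moved[moved$elety == "CA", , drop = FALSE]),
        placed_ca_pool(assembly), params$clash_distance)
      if (clash > params$clash_fraction) {
        best_fail <- list(action = "rejected_clash", shared = shared_prot,
                          copy = ci, tm = sup$tm_score, clash = clash)
        next
      }
      assembly <- place_chain(assembly, new_prot, moved, dimer$dimer_id, tf,
                              sweep, dimer$dimer_id, "added",
                              shared_protein = shared_prot, copy_tried = ci,
                              tm = sup$tm_score, clash = clash)
      return(list(assembly = assembly, added = TRUE))
    }
  }
  assembly <- log_decision(assembly, sweep, dimer$dimer_id, best_fail$action,
                           shared_protein = best_fail$shared,
                           copy_tried = best_fail$copy, tm = best_fail$tm,
                           clash = best_fail$clash)
  list(assembly = assembly, added = FALSE)
}

#' Greedy assembly of a complex from scored dimer models
#'
#' Ranks the dimers by pDockQ, seeds the assembly with the top-ranked dimer
#' (or `params$start_dimer`), then sweeps the ranking attempting
#' [try_add_dimer()] for each remaining dimer. After any successful addition
#' the sweep restarts from the top; the procedure terminates when a full
#' sweep adds nothing. A dimer that has donated a chain is not retried;
#' rejected dimers are retried on later sweeps. The result is deterministic
#' for a given input.
#'
#' @param dimers Dimer tibble (`dimer_id`, `structure` list-column,
#'   `chain_a`, `protein_a`, `chain_b`, `protein_b`, `pdockq`).
#' @param params An [assembly_params()] object.
#' @return A `cf_assembly`: `placed` (chain table with coordinates,
#'   source dimers and applied transforms) and `log` (ordered decision
#'   records). Convert with [as_structure()]; summarize with
#'   [tidy.cf_assembly()] / [glance.cf_assembly()].
#' @export
assemble <- function(dimers, params = assembly_params()) {
  if (nrow(dimers) == 0) abort("at least one dimer is required")
  ranked <- rank_dimers(dimers)
  seed_idx <- if (!is.null(params$start_dimer)) {
    match(params$start_dimer, ranked$dimer_id)
  } else 1L
  if (is.na(seed_idx)) abort("start_dimer not found in the dimer set")

  assembly <- new_assembly(params)
  seed <- ranked[seed_idx, ]
  at_a <- dimer_chain_atoms(seed, "a")
  at_b <- dimer_chain_atoms(seed, "b")
  identity_tf <- new_transform(diag(3), c(0, 0, 0))
  assembly <- place_chain(assembly, seed$protein_a, at_a, seed$dimer_id,
                          identity_tf, 0L, seed$dimer_id, "seed")
  assembly <- place_chain(assembly, seed$protein_b, at_b, seed$dimer_id,
                          identity_tf, 0L, seed$dimer_id, "seed")

  used <- seed$dimer_id
  sweep_no <- 0L
  repeat {
    sweep_no <- sweep_no + 1L
    added_this_sweep <- FALSE
    for (i in seq_len(nrow(ranked))) {
      if (ranked$dimer_id[i] %in% used) next
      res <- try_add_dimer(assembly, ranked[i, ], params, sweep = sweep_no)
      assembly <- res$assembly
      if (res$added) {
        used <- c(used, ranked$dimer_id[i])
        added_this_sweep <- TRUE
        break  # restart the sweep from the top of the ranking
      }
    }
    if (!added_this_sweep) break
  }
  assembly
}

#' Merge a built assembly into a single structure
#'
#' Chains are labeled A, B, ... in placement order; the label-to-protein
#' mapping is attached as attribute `chain_map`.
#'
#' @param assembly A `cf_assembly`.
#' @return A `cf_structure`.
#' @export
as_structure <- function(assembly) {
  stopifnot(inherits(assembly, "cf_assembly"))
  atoms <- bind_rows(assembly$placed$atoms)
  s <- new_structure(id = "assembly", atoms = atoms, format = "assembly")
  attr(s, "chain_map") <- tibble(chain = assembly$placed$chain_label,
                                 protein = assembly$placed$protein,
                                 copy = assembly$placed$copy,
                                 source_dimer = assembly$placed$source_dimer)
  s
}

#' Read a dimer manifest
#'
#' Reads a TSV with columns `dimer_id`, `path`, `chain_a`, `protein_a`,
#' `chain_b`, `protein_b` and optionally `pdockq`; structures are loaded
#' from `path` (relative to `base_dir`) and pDockQ is computed with
#' [score_dimer()] when absent.
#'
#' @param path Manifest TSV path.
#' @param base_dir Directory against which relative structure paths resolve,
#'   default the manifest's directory.
#' @param params [scoring_params()] used when pDockQ must be computed.
#' @return A dimer tibble suitable for [assemble()].
#' @export
read_dimer_manifest <- function(path, base_dir = dirname(path),
                                params = scoring_params()) {
  man <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("dimer_id", "path", "chain_a", "protein_a", "chain_b", "protein_b")
  if (!all(req %in% names(man)))
    abort(paste0("manifest must have columns: ", paste(req, collapse = ", ")))
  structures <- lapply(man$path, function(p) {
    full <- if (file.exists(p)) p else file.path(base_dir, p)
    read_structure(full)
  })
  man$structure <- structures
  if (!"pdockq" %in% names(man)) {
    man$pdockq <- vapply(seq_len(nrow(man)), function(i)
      score_dimer(structures[[i]], man$chain_a[i], man$chain_b[i],
                  params)$pdockq, numeric(1))
  }
  man[, c("dimer_id", "structure", "chain_a", "protein_a", "chain_b",
          "protein_b", "pdockq")]
}
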