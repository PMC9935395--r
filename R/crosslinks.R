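#' Validate lysine-lysine crosslinks against a model
#'
#' For each restraint, measures the Euclidean distance between the NZ
#' (epsilon-amino) atoms of the two lysines and classifies the link as
#' `satisfied` (distance <= `max_distance`, inclusive), `violated`, or
#' `unevaluable` when the residue is missing, not a lysine, or has no NZ
#' atom. Residue numbers in the link table use author (UniProt-style)
#' numbering.
#'
#' @param links Tibble with columns `protein_a`, `residue_a`, `protein_b`,
#'   `residue_b`; an optional `model` column carries a model identifier
#'   through to the output.
#' @param structure A `cf_structure` holding the model.
#' @param chain_map Tibble with columns `protein`, `chain` resolving protein
#'   accessions to chain ids; every protein in `links` must resolve.
#' @param max_distance Maximal croslinkable NZ-NZ span in Angstrom
#'   (inclusive), default 32.
#' @param ca_fallback Use the Calpha atom when NZ is absent (default `FALSE`;
#'   enabling this measures backbone rather than epsilon-amino distance).
#' @return Tibble of class `cf_crosslinks`, one row per link: the input
#'   columns plus `distance`, `status` and `reason` (for unevaluable links).
#'   `summary()`/[glance.cf_crosslinks()] give per-status counts and the
#'   satisfied fraction.
#' @export
validate_crosslinks <- function(links, structure, chain_map, max_distance = 32,
                                ca_fallback = FALSE) {
  req <- c("protein_a", "residue_a", "protein_b", "residue_b")
  if (!all(req %in% names(links)))
    abort(paste0("links must have columns: ", paste(req, collapse = ", ")))
  if (!all(c("protein", "chain") %in% names(chain_map)))
    abort("chain_map must have columns protein, chain")

  prots <- unique(c(links$protein_a, links$protein_b))
  missing_p <- setdiff(prots, chain_map$protein)
  if (length(missing_p))
    abort(paste0("unmappable protein accession(s): ",
                 paste(missing_p, collapse = ", ")))

  site_atom <- function(protein, resno) {
    chain <- chain_map$chain[match(protein, chain_map$protein)]
    at <- structure$atoms[structure$atoms$chain == chain &
                            structure$atoms$resno == resno, , drop = FALSE]
    if (nrow(at) == 0) return(list(reason = "residue not found"))
    if (at$resid[1] != "LYS") return(list(reason = "not LYS"))
    nz <- at[at$elety == "NZ", , drop = FALSE]
    if (nrow(nz) == 0 && ca_fallback) nz <- at[at$elety == "CA", , drop = FALSE]
    if (nrow(nz) == 0) return(list(reason = "NZ atom absent"))
    list(xyz = as.numeric(nz[1, c("x", "y", "z")]))
  }

  out <- as_tibble(links)
  n <- nrow(out)
  out$distance <- rep(NA_real_, n)
  out$status <- rep("unevaluable", n)
  out$reason <- rep(NA_character_, n)
  out$max_distance <- rep(max_distance, n)
  for (i in seq_len(n)) {
    a <- site_atom(out$protein_a[i], out$residue_a[i])
    b <- site_atom(out$protein_b[i], out$residue_b[i])
    if (!is.null(a$reason) || !is.null(b$reason)) {
      out$reason[i] <- paste(stats::na.omit(c(a$reason, b$reason)), collapse = "; ")
      next
    }
    d <- sqrt(sum((a$xyz - b$xyz)^2))
    out$distance[i] <- d
    out$status[i] <- if (d <= max_distance) "satisfied" else "violated"
  }
  class(out) <- c("cf_crosslinks", class(out))
  out
}

#' @export
summary.cf_crosslinks <- function(object, ...) glance(object)

#' Crosslink support stratified by model confidence bin
#'
#' For a cohort of models, computes per confidence bin the number of models
#' with at least one evaluable link and the fraction of those with at least
#' one satisfied link. Models whose links are all unevaluable are excluded
#' from the denominators.
#'
#' @param records A `cf_crosslinks` table (or plain tibble with `model` and
#'   `status` columns), rows from all models combined.
#' @param scores Tibble `model`, `pdockq`.
#' @param cutoffs Passed to [confidence_bin()].
#' @return Tibble: `bin`, `n_models`, `n_supported`, `fraction_supported`.
#' @export
crosslink_support_by_bin <- function(records, scores, cutoffs = c(0.23, 0.5)) {
  if (nrow(records) == 0)
    return(tibble(bin = factor(character(), levels = c("low", "acceptable", "high")),
                  n_models = integer(), n_supported = integer(),
                  fraction_supported = numeric()))
  if (!"model" %in% names(records))
    abort("records must carry a 'model' column identifying the source model")
  per_model <- as_tibble(records) |>
    group_by(.data$model) |>
    summarise(n_evaluable = sum(.data$status != "unevaluable"),
              supported = any(.data$status == "satisfied"), .groups = "drop") |>
    filter(.data$n_evaluable > 0) |>
    left_join(scores, by = "model")
  if (any(is.na(per_model$pdockq)))
    abort("every model in records needs a pdockq in scores")
  per_model$bin <- confidence_bin(per_model$pdockq, cutoffs)
  per_model |>
    group_by(.data$bin) |>
    summarise(n_models = n(), n_supported = sum(.data$supported),
              fraction_supported = mean(.data$supported), .groups = "drop")
}
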