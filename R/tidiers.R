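# broom-style tidiers for the package's result objects

#' Tidy an interface result into per-residue rows
#'
#' @param x A `cf_interface` from [find_interface()] or [score_dimer()].
#' @param ... Unused.
#' @return Tibble with one row per interface residue: `chain`, `resno`,
#'   `insert`, `resid`, `plddt`, `min_dist`.
#' @exportS3Method generics::tidy
tidy.cf_interface <- function(x, ...) {
  bind_rows(
    mutate(x$residues_a, chain = x$chain_a, .before = 1),
    mutate(x$residues_b, chain = x$chain_b, .before = 1)
  )
}

#' One-row summary of an interface result
#'
#' @inheritParams tidy.cf_interface
#' @return Tibble: `chain_a`, `chain_b`, `n_contacts`, `mean_if_plddt`, `x`,
#'   `pdockq`, `bin`.
#' @exportS3Method generics::glance
glance.cf_interface <- function(x, ...) {
  res <- x
  tibble(chain_a = res$chain_a, chain_b = res$chain_b,
         n_contacts = res$n_contacts, mean_if_plddt = res$mean_if_plddt,
         x = res$x, pdockq = res$pdockq %||% NA_real_,
         bin = if (is.null(res$bin)) NA_character_ else as.character(res$bin))
}

#' Decision log of an assembly
#'
#' @param x A `cf_assembly`.
#' @param ... Unused.
#' @return The ordered decision-log tibble: `sweep`, `dimer_id`, `action`,
#'   `shared_protein`, `copy_tried`, `tm`, `clash_fraction`.
#' @exportS3Method generics::tidy
tidy.cf_assembly <- function(x, ...) x$log

#' One-row summary of an assembly
#'
#' @inheritParams tidy.cf_assembly
#' @return Tibble: `n_chains`, `n_proteins`, `n_sweeps`, `n_rejected_tm`,
#'   `n_rejected_clash`.
#' @exportS3Method generics::glance
glance.cf_assembly <- function(x, ...) {
  tibble(n_chains = nrow(x$placed),
         n_proteins = length(unique(x$placed$protein)),
         n_sweeps = max(c(0L, x$log$sweep)),
         n_rejected_tm = sum(x$log$action == "rejected_tm"),
         n_rejected_clash = sum(x$log$action == "rejected_clash"))
}

#' Cluster labels as a tibble
#'
#' @param x A `cf_clusters` from [cluster_sites()].
#' @param ... Unused.
#' @return Tibble: `site`, `cluster`.
#' @exportS3Method generics::tidy
tidy.cf_clusters <- function(x, ...) {
  tibble(site = names(x$labels), cluster = unname(x$labels))
}

#' One-row summary of a clustering
#'
#' @inheritParams tidy.cf_clusters
#' @return Tibble: `n_sites`, `n_clusters`, `cut_height`.
#' @exportS3Method generics::glance
glance.cf_clusters <- function(x, ...) {
  tibble(n_sites = length(x$labels), n_clusters = x$n_clusters,
         cut_height = x$cut_height %||% NA_real_)
}

#' Per-status summary of crosslink validation
#'
#' @param x A `cf_crosslinks` from [validate_crosslinks()].
#' @param ... Unused.
#' @return Tibble: `n_links`, `n_satisfied`, `n_violated`, `n_unevaluable`,
#'   `fraction_satisfied` (over evaluable links), `any_satisfied`.
#' @exportS3Method generics::glance
glance.cf_crosslinks <- function(x, ...) {
  ev <- x$status != "unevaluable"
  tibble(n_links = nrow(x),
         n_satisfied = sum(x$status == "satisfied"),
         n_violated = sum(x$status == "violated"),
         n_unevaluable = sum(!ev),
         fraction_satisfied = if (any(ev)) mean(x$status[ev] == "satisfied")
                              else NA_real_,
         any_satisfied = any(x$status == "satisfied"))
}
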