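#' Collect interface residues of scored dimers as a tidy table
#'
#' Flattens a set of scored dimers into one row per interface residue with
#' its protein accession and partner protein, plus the full modeled residue
#' universe, for use by [map_sites()].
#'
#' @param interfaces Named list of `cf_interface` objects (names = dimer ids),
#'   as returned by [score_dimer()].
#' @param structures Named list of the corresponding `cf_structure`s.
#' @param chain_maps Named list of tibbles `chain`, `protein` (one per dimer).
#' @param min_pdockq Keep only dimers with pDockQ strictly above this value
#'   (default 0.5, the high-confidence rule); use 0 to keep all.
#' @return A list with `interface_residues` (tibble: `dimer_id`, `protein`,
#'   `position`, `partner_protein`) and `modeled_residues` (tibble: `protein`,
#'   `position`).
#' @export
interface_residue_table <- function(interfaces, structures, chain_maps,
                                    min_pdockq = 0.5) {
  stopifnot(length(interfaces) == length(structures),
            length(interfaces) == length(chain_maps))
  ids <- names(interfaces) %||% as.character(seq_along(interfaces))
  if_rows <- list(); mod_rows <- list()
  for (i in seq_along(interfaces)) {
    res <- interfaces[[i]]
    cm <- chain_maps[[i]]
    s <- structures[[i]]
    pa <- cm$protein[match(res$chain_a, cm$chain)]
    pb <- cm$protein[match(res$chain_b, cm$chain)]
    for (ch in chain_ids(s)) {
      p <- cm$protein[match(ch, cm$chain)]
      mod_rows[[length(mod_rows) + 1]] <-
        tibble(protein = p, position = chain_residues(s, ch)$resno)
    }
    if (!is.null(res$pdockq) && res$pdockq <= min_pdockq) next
    if (nrow(res$residues_a))
      if_rows[[length(if_rows) + 1]] <-
        tibble(dimer_id = ids[i], protein = pa, position = res$residues_a$resno,
               partner_protein = pb)
    if (nrow(res$residues_b))
      if_rows[[length(if_rows) + 1]] <-
        tibble(dimer_id = ids[i], protein = pb, position = res$residues_b$resno,
               partner_protein = pa)
  }
  list(
    interface_residues = if (length(if_rows)) bind_rows(if_rows) else
      tibble(dimer_id = character(), protein = character(),
             position = integer(), partner_protein = character()),
    modeled_residues = distinct(bind_rows(mod_rows))
  )
}

#' Map site annotations onto interface residues
#'
#' Each site (mutation or phosphosite) is marked `at_interface = TRUE` when
#' its (protein, position) matches an interface residue of any confident
#' dimer involving that protein; one output row is emitted per site x
#' interface match. Sites on proteins absent from every model, or at
#' positions outside the modeled range, get `at_interface = NA` (with a
#' warning for out-of-range positions).
#'
#' @param sites Tibble with columns `protein`, `position`, `site_class`
#'   (e.g. pathogenic / benign / cancer / phosphosite).
#' @param interface_residues Tibble `dimer_id`, `protein`, `position`,
#'   `partner_protein` (see [interface_residue_table()]).
#' @param modeled_residues Tibble `protein`, `position`: the modeled residue
#'   universe defining "rest of the protein".
#' @return Tibble: the site columns plus `at_interface`, `dimer_id` and
#'   `partner_protein` (NA for non-interface sites).
#' @export
map_sites <- function(sites, interface_residues, modeled_residues) {
  req <- c("protein", "position", "site_class")
  if (!all(req %in% names(sites)))
    abort(paste0("sites must have columns: ", paste(req, collapse = ", ")))
  sites <- as_tibble(sites)

  modeled_prot <- unique(modeled_residues$protein)
  mkey <- site_key(modeled_residues$protein, modeled_residues$position)
  ikey <- site_key(interface_residues$protein, interface_residues$position)
  skey <- site_key(sites$protein, sites$position)

  out <- list()
  n_oob <- 0L
  for (i in seq_len(nrow(sites))) {
    row <- sites[i, ]
    if (!row$protein %in% modeled_prot) {
      row$at_interface <- NA
      row$dimer_id <- NA_character_; row$partner_protein <- NA_character_
      out[[length(out) + 1]] <- row
    } else if (!skey[i] %in% mkey) {
      n_oob <- n_oob + 1L
      row$at_interface <- NA
      row$dimer_id <- NA_character_; row$partner_protein <- NA_character_
      out[[length(out) + 1]] <- row
    } else {
      hits <- interface_residues[ikey == skey[i], , drop = FALSE]
      if (nrow(hits) == 0) {
        row$at_interface <- FALSE
        row$dimer_id <- NA_character_; row$partner_protein <- NA_character_
        out[[length(out) + 1]] <- row
      } else {
        for (j in seq_len(nrow(hits))) {
          r <- row
          r$at_interface <- TRUE
          r$dimer_id <- hits$dimer_id[j]
          r$partner_protein <- hits$partner_protein[j]
          out[[length(out) + 1]] <- r
        }
      }
    }
  }
  if (n_oob > 0)
    warn(paste0(n_oob, " site(s) fall outside the modeled residues of their ",
                "protein; at_interface set to NA"))
  bind_rows(out)
}

#' Interface enrichment of one site class over another
#'
#' Builds the 2x2 table (class1 at interface / elsewhere vs class2 at
#' interface / elsewhere), counting each (protein, position) once even if it
#' occurs in several dimers, and reports the fold enrichment
#' `(a/(a+b)) / (c/(c+d))` with a Fisher's exact p-value (two-sided by
#' default).
#'
#' @param mapped Output of [map_sites()]; rows with `at_interface = NA` are
#'   dropped.
#' @param class1,class2 Values of `site_class` to compare, default
#'   `"pathogenic"` vs `"benign"`.
#' @param alternative Passed to [stats::fisher.test()], default `"two.sided"`.
#' @param pseudocount Added to all four cells when a marginal is zero would
#'   otherwise make the fold undefined (default 0: error instead).
#' @return One-row tibble: `a`, `b`, `c`, `d`, `fold_enrichment`, `p_value`,
#'   `test_name`.
#' @export
interface_enrichment <- function(mapped, class1 = "pathogenic",
                                 class2 = "benign",
                                 alternative = "two.sided", pseudocount = 0) {
  m <- mapped |>
    filter(!is.na(.data$at_interface),
           .data$site_class %in% c(class1, class2)) |>
    distinct(.data$protein, .data$position, .data$site_class, .data$at_interface)
  if (!any(m$site_class == class1) || !any(m$site_class == class2))
    abort("need at least one site in each class")
  a <- sum(m$site_class == class1 & m$at_interface)
  b <- sum(m$site_class == class1 & !m$at_interface)
  c_ <- sum(m$site_class == class2 & m$at_interface)
  d <- sum(m$site_class == class2 & !m$at_interface)
  if (c_ == 0 || (a + b) == 0) {
    if (pseudocount > 0) {
      a <- a + pseudocount; b <- b + pseudocount
      c_ <- c_ + pseudocount; d <- d + pseudocount
    } else {
      abort("zero marginal makes fold enrichment undefined; set pseudocount > 0")
    }
  }
  fold <- (a / (a + b)) / (c_ / (c_ + d))
  p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                   alternative = alternative)$p.value
  tibble(a = a, b = b, c = c_, d = d, fold_enrichment = fold, p_value = p,
         test_name = paste0("fisher.exact.", alternative))
}

#' Rank interfaces by recurrent mutation density
#'
#' Mutation density of an interface is the number of mapped mutations per
#' interface position. Interfaces whose density reaches the upper quantile
#' threshold (default: top 25%, i.e. at or above the 75th percentile,
#' ties included) are flagged; with zero mutations everywhere nothing is
#' flagged. Empty interfaces are excluded.
#'
#' @param mutation_counts Tibble `dimer_id`, `n_mutations`.
#' @param interface_sizes Tibble `dimer_id`, `n_positions` (interface residue
#'   count).
#' @param top_fraction Fraction of interfaces to flag, default 0.25.
#' @return Tibble: `dimer_id`, `n_mutations`, `n_positions`, `density`,
#'   `top_flag`, sorted by decreasing density.
#' @export
recurrence_rank <- function(mutation_counts, interface_sizes,
                            top_fraction = 0.25) {
  d <- interface_sizes |>
    filter(.data$n_positions > 0) |>
    left_join(mutation_counts, by = "dimer_id") |>
    mutate(n_mutations = ifelse(is.na(.data$n_mutations), 0L, .data$n_mutations),
           density = .data$n_mutations / .data$n_positions)
  if (nrow(d) == 0)
    return(tibble(dimer_id = character(), n_mutations = integer(),
                  n_positions = integer(), density = numeric(),
                  top_flag = logical()))
  thr <- quantile(d$density, 1 - top_fraction, names = FALSE)
  d$top_flag <- d$density >= thr & d$density > 0
  arrange(d, desc(.data$density), .data$dimer_id)[,
    c("dimer_id", "n_mutations", "n_positions", "density", "top_flag")]
}
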