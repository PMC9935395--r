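#' pDockQ scoring parameters
#'
#' Constants of the sigmoid mapping interface size and confidence to a
#' predicted DockQ score:
#' pDockQ = height / (1 + exp(-slope * (x - midpoint))) + baseline, with
#' x = mean interface plDDT * log(number of interface residues) (natural log).
#'
#' @param height Sigmoid height, default 0.707.
#' @param slope Sigmoid slope, default 0.03148.
#' @param midpoint Sigmoid midpoint on the x scale, default 388.06.
#' @param baseline Additive baseline, default 0.03138.
#' @param interface_cutoff Heavy-atom distance (Angstrom) defining interface
#'   residues, default 10.
#' @return A list of class `cf_scoring_params`.
#' @export
scoring_params <- function(height = 0.707, slope = 0.03148, midpoint = 388.06,
                           baseline = 0.03138, interface_cutoff = 10) {
  stopifnot(height > 0, slope > 0, interface_cutoff > 0)
  structure(list(height = height, slope = slope, midpoint = midpoint,
                 baseline = baseline, interface_cutoff = interface_cutoff),
            class = "cf_scoring_params")
}

#' Detect interface residues between two chains
#'
#' A residue is interfacial when any of its heavy atoms lies within
#' `cutoff` Angstrom (inclusive) of any heavy atom of the other chain.
#' `n_contacts` is the number of interface residues summed over both chains;
#' `mean_if_plddt` averages the per-residue plDDT over the union with equal
#' residue weight.
#'
#' @param structure A `cf_structure` containing both chains.
#' @param chain_a,chain_b Chain ids.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (inclusive), default 10.
#' @return An object of class `cf_interface`: residue tables `residues_a` and
#'   `residues_b` (with per-residue minimum cross-chain distance), `n_contacts`,
#'   `mean_if_plddt` and `x = mean_if_plddt * log(n_contacts)`.
#' @export
find_interface <- function(structure, chain_a, chain_b, cutoff = 10) {
  at_a <- chain_atoms(structure, chain_a)
  at_b <- chain_atoms(structure, chain_b)
  if (nrow(at_a) == 0 || nrow(at_b) == 0) abort("empty chain")

  d <- cross_dist(coords_matrix(at_a), coords_matrix(at_b))
  min_a <- apply(d, 1, min)
  min_b <- apply(d, 2, min)

  res_min <- function(at, mn) {
    at$min_dist <- mn
    out <- at |>
      group_by(.data$resno, .data$insert, .data$resid, .data$plddt) |>
      summarise(min_dist = min(.data$min_dist), .groups = "drop") |>
      arrange(.data$resno, .data$insert)
    out[out$min_dist <= cutoff, , drop = FALSE]
  }
  ra <- res_min(at_a, min_a)
  rb <- res_min(at_b, min_b)
  n <- nrow(ra) + nrow(rb)
  mean_plddt <- if (n > 0) mean(c(ra$plddt, rb$plddt)) else NA_real_
  structure(
    list(chain_a = chain_a, chain_b = chain_b, cutoff = cutoff,
         residues_a = ra, residues_b = rb, n_contacts = n,
         mean_if_plddt = mean_plddt,
         x = if (n > 0) mean_plddt * log(n) else NA_real_,
         pdockq = NULL, bin = NULL),
    class = "cf_interface"
  )
}

#' pDockQ confidence score
#'
#' Sigmoid transform of `x = mean_if_plddt * log(n_contacts)` (natural log)
#' using the parameters in [scoring_params()]. `n_contacts = 0` yields 0
#' exactly (non-interacting pair), not the sigmoid baseline.
#'
#' @param mean_if_plddt Mean interface plDDT, in \[0, 100\]. Vectorized.
#' @param n_contacts Number of interface residues (both chains summed),
#'   non-negative integer. Vectorized.
#' @param params A [scoring_params()] object.
#' @return Numeric pDockQ score(s) in \[0, baseline + height).
#' @examples
#' pdockq(80, 128)
#' pdockq(388.06 / log(150), 150)  # sigmoid midpoint: 0.38488
#' @export
pdockq <- function(mean_if_plddt, n_contacts, params = scoring_params()) {
  stopifnot(length(mean_if_plddt) == length(n_contacts) ||
              length(mean_if_plddt) == 1L || length(n_contacts) == 1L)
  len <- max(length(mean_if_plddt), length(n_contacts))
  p <- rep_len(as.numeric(mean_if_plddt), len)
  n <- rep_len(as.numeric(n_contacts), len)
  if (any(n < 0 | n != floor(n), na.rm = TRUE))
    abort("n_contacts must be a non-negative integer")
  active <- !is.na(n) & n > 0
  if (any(active & (is.na(p) | p < 0 | p > 100)))
    abort("mean_if_plddt must lie in [0, 100]")
  out <- numeric(len)
  x <- p[active] * log(n[active])
  out[active] <- params$height / (1 + exp(-params$slope * (x - params$midpoint))) +
    params$baseline
  out
}

#' Confidence bin of a pDockQ score
#'
#' `high` for scores strictly above the upper cutoff (default 0.5),
#' `acceptable` strictly above the lower cutoff (default 0.23), else `low`.
#'
#' @param pdockq Numeric score(s) in \[0, 1\].
#' @param cutoffs Length-2 ascending vector `c(acceptable, high)`.
#' @return Factor with levels `low`, `acceptable`, `high`.
#' @export
confidence_bin <- function(pdockq, cutoffs = c(0.23, 0.5)) {
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  out <- ifelse(pdockq > cutoffs[2], "high",
                ifelse(pdockq > cutoffs[1], "acceptable", "low"))
  factor(out, levels = c("low", "acceptable", "high"))
}

#' Score a two-chain model
#'
#' Composes [find_interface()] and [pdockq()] and attaches the confidence
#' bin. Symmetric in chain order.
#'
#' @inheritParams find_interface
#' @param params A [scoring_params()] object.
#' @return A `cf_interface` with `pdockq` and `bin` populated; see
#'   [glance.cf_interface()] for a one-row tibble summary.
#' @export
score_dimer <- function(structure, chain_a, chain_b, params = scoring_params()) {
  res <- find_interface(structure, chain_a, chain_b,
                        cutoff = params$interface_cutoff)
  res$pdockq <- if (res$n_contacts > 0) {
    pdockq(res$mean_if_plddt, res$n_contacts, params)
  } else 0
  res$bin <- confidence_bin(res$pdockq)
  res
}

#' @export
print.cf_interface <- function(x, ...) {
  cat("<cf_interface> chains ", x$chain_a, ":", x$chain_b,
      "  interface residues: ", nrow(x$residues_a), "+", nrow(x$residues_b),
      sep = "")
  if (!is.null(x$pdockq))
    cat(sprintf("  mean plDDT %.1f  pDockQ %.4f (%s)",
                x$mean_if_plddt, x$pdockq, as.character(x$bin)))
  cat("\n")
  invisible(x)
}

#' Classify a chain pair as directly or indirectly interacting
#'
#' Direct interaction requires more than `min_contacts` Calpha-Calpha pairs
#' at distance strictly below `ca_cutoff` (both bounds strict).
#'
#' @param structure A `cf_structure`.
#' @param chain_a,chain_b Chain ids.
#' @param ca_cutoff Calpha distance cutoff in Angstrom (strict `<`), default 8.
#' @param min_contacts Contact-count threshold (strict `>`), default 20.
#' @return One-row tibble: `direct` (logical), `n_ca_contacts`, `ca_cutoff`,
#'   `min_contacts`.
#' @export
classify_direct <- function(structure, chain_a, chain_b,
                            ca_cutoff = 8, min_contacts = 20) {
  ca_a <- chain_atoms(structure, chain_a, elety = "CA")
  ca_b <- chain_atoms(structure, chain_b, elety = "CA")
  if (nrow(ca_a) == 0 || nrow(ca_b) == 0)
    abort("chain has no Calpha atoms")
  d <- cross_dist(coords_matrix(ca_a), coords_matrix(ca_b))
  n <- sum(d < ca_cutoff)
  tibble(direct = n > min_contacts, n_ca_contacts = n,
         ca_cutoff = ca_cutoff, min_contacts = min_contacts)
}
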