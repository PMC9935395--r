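test_that("dimers rank by descending pDockQ with lexicographic ties", {
  d <- tibble::tibble(dimer_id = c("b", "a", "c"), pdockq = c(0.7, 0.9, 0.5))
  expect_equal(rank_dimers(d)$dimer_id, c("a", "b", "c"))
  tie <- tibble::tibble(dimer_id = c("z2", "z1"), pdockq = c(0.6, 0.6))
  expect_equal(rank_dimers(tie)$dimer_id, c("z1", "z2"))
  expect_equal(nrow(rank_dimers(tie[0, ])), 0)
})

test_that("clash fraction matches the brute-force scan and its trivial cases", {
  set.seed(21)
  cand <- matrix(rnorm(30, sd = 5), 10, 3)
  expect_equal(chain_clash_fraction(cand, matrix(numeric(), 0, 3)), 0)
  expect_equal(chain_clash_fraction(cand, cand), 1)
  far <- cand + 100
  expect_equal(chain_clash_fraction(cand, far), 0)
  for (seed in 1:25) {
    set.seed(seed)
    a <- matrix(rnorm(24, sd = 4), 8, 3)
    b <- matrix(rnorm(36, sd = 4), 12, 3)
    expect_equal(chain_clash_fraction(a, b), brute_clash_fraction(a, b))
  }
})

test_that("try_add_dimer skips dimers sharing no or both proteins", {
  cx <- make_complex(n_chains = 5, seed = 22)
  ranked <- rank_dimers(cx$dimers)
  asm <- assemble(ranked[1, ])  # seed only: proteins of dimer 1
  # D03_CD shares nothing with {P1,P2}
  res <- try_add_dimer(asm, cx$dimers[3, ])
  expect_false(res$added)
  expect_equal(dplyr::last(res$assembly$log$action), "skipped_no_shared_chain")
  # re-offering the seed dimer: both proteins present
  res2 <- try_add_dimer(asm, cx$dimers[1, ])
  expect_equal(dplyr::last(res2$assembly$log$action), "skipped_both_present")
})

test_that("a compatible dimer is placed onto the ground-truth position", {
  cx <- make_complex(n_chains = 3, seed = 23)
  asm <- assemble(cx$dimers[1, ])      # chains A, B in dimer D01's frame
  res <- try_add_dimer(asm, cx$dimers[2, ])  # B-C, shares P2
  expect_true(res$added)
  # the placed chain C must coincide with ground truth once mapped through
  # the seed dimer's recorded frame
  placed_c <- res$assembly$placed$atoms[[3]]
  truth <- apply_transform(
    invert_transform(cx$transforms[[cx$dimers$dimer_id[1]]]),
    chain_atoms(cx$complex, "C"))
  expect_lt(max(abs(as.matrix(placed_c[, c("x", "y", "z")]) -
                      as.matrix(truth[, c("x", "y", "z")]))), 1e-6)
})

test_that("clashing chains are rejected and logged", {
  cx <- make_complex(n_chains = 3, seed = 24)
  asm <- assemble(cx$dimers)
  # forge a dimer sharing P1 whose partner lands exactly on placed chain B
  forged_atoms <- dplyr::bind_rows(
    chain_atoms(cx$complex, "A"),
    dplyr::mutate(chain_atoms(cx$complex, "B"), chain = "X"))
  forged <- tibble::tibble(
    dimer_id = "FORGED", structure = list(
      complexforge:::new_structure("forged", forged_atoms)),
    chain_a = "A", protein_a = "P1", chain_b = "X", protein_b = "PX",
    pdockq = 0.4)
  res <- try_add_dimer(asm, forged)
  expect_false(res$added)
  last <- dplyr::slice_tail(res$assembly$log, n = 1)
  expect_equal(last$action, "rejected_clash")
  expect_gt(last$clash_fraction, 0.25)
})

test_that("a shared chain in a different conformation fails the TM gate", {
  cx <- make_complex(n_chains = 3, seed = 25)
  asm <- assemble(cx$dimers)
  warped <- chain_atoms(cx$complex, "A")
  set.seed(1)
  warped[, c("x", "y", "z")] <- warped[, c("x", "y", "z")] +
    matrix(rnorm(nrow(warped) * 3, sd = 8), ncol = 3)
  far_partner <- dplyr::mutate(chain_atoms(cx$complex, "B"),
                               chain = "Y", x = x + 500)
  forged <- tibble::tibble(
    dimer_id = "WARPED", structure = list(
      complexforge:::new_structure("warped",
                                   dplyr::bind_rows(warped, far_partner))),
    chain_a = "A", protein_a = "P1", chain_b = "Y", protein_b = "PY",
    pdockq = 0.4)
  res <- try_add_dimer(asm, forged)
  expect_false(res$added)
  last <- dplyr::slice_tail(res$assembly$log, n = 1)
  expect_equal(last$action, "rejected_tm")
  expect_lte(last$tm, 0.8)
})

test_that("a single dimer assembles to itself with a seed log", {
  cx <- make_complex(n_chains = 2, seed = 26)
  asm <- assemble(cx$dimers)
  expect_equal(nrow(asm$placed), 2)
  expect_equal(asm$log$action, c("seed", "seed"))
  expect_equal(unique(asm$log$dimer_id), cx$dimers$dimer_id[1])
})

test_that("chain-of-dimers complexes reassemble completely and accurately", {
  for (spec in list(list(n = 5, geometry = "chain", seed = 27),
                    list(n = 8, geometry = "chain", seed = 28),
                    list(n = 5, geometry = "ring", seed = 29),
                    list(n = 6, geometry = "packed", seed = 30))) {
    cx <- make_complex(n_chains = spec$n, geometry = spec$geometry,
                       seed = spec$seed)
    asm <- assemble(cx$dimers)
    expect_equal(nrow(asm$placed), spec$n)
    r <- assembly_rmsd(asm, cx$complex, reference_map = cx$chain_map)
    expect_lt(r$rmsd, 1)
    expect_equal(sort(unique(asm$placed$protein)),
                 sort(cx$chain_map$protein))
  }
})

test_that("assembly is deterministic: identical inputs give identical logs", {
  cx <- make_complex(n_chains = 5, seed = 31, plddt = "noisy")
  log1 <- tidy(assemble(cx$dimers))
  log2 <- tidy(assemble(cx$dimers))
  expect_identical(log1, log2)
})

test_that("the finished assembly satisfies the clash invariant globally", {
  cx <- make_complex(n_chains = 6, seed = 32)
  asm <- assemble(cx$dimers)
  for (i in seq_len(nrow(asm$placed))) {
    cand <- asm$placed$atoms[[i]]
    others <- do.call(rbind, lapply(
      asm$placed$atoms[-i],
      function(at) as.matrix(at[at$elety == "CA", c("x", "y", "z")])))
    frac <- chain_clash_fraction(
      as.matrix(cand[cand$elety == "CA", c("x", "y", "z")]), others,
      asm$params$clash_distance)
    expect_lte(frac, asm$params$clash_fraction)
  }
})

test_that("as_structure merges placed chains in placement order", {
  cx <- make_complex(n_chains = 4, seed = 33)
  asm <- assemble(cx$dimers)
  s <- as_structure(asm)
  expect_equal(chain_ids(s), c("A", "B", "C", "D"))
  cm <- attr(s, "chain_map")
  expect_equal(cm$protein, asm$placed$protein)
  # written output round-trips
  p <- tempfile(fileext = ".pdb")
  write_structure(s, p)
  expect_equal(chain_ids(read_structure(p)), chain_ids(s))
})

test_that("a manifest on disk reproduces the in-memory assembly", {
  cx <- make_complex(n_chains = 3, seed = 34)
  dir <- tempfile(); dir.create(dir)
  rows <- list()
  for (i in seq_len(nrow(cx$dimers))) {
    d <- cx$dimers[i, ]
    f <- file.path(dir, paste0(d$dimer_id, ".pdb"))
    write_structure(d$structure[[1]], f)
    rows[[i]] <- tibble::tibble(
      dimer_id = d$dimer_id, path = basename(f), chain_a = d$chain_a,
      protein_a = d$protein_a, chain_b = d$chain_b, protein_b = d$protein_b)
  }
  man_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(dplyr::bind_rows(rows), man_path)
  dimers <- read_dimer_manifest(man_path)
  expect_equal(dimers$pdockq, cx$dimers$pdockq, tolerance = 1e-6)
  asm <- assemble(dimers)
  r <- assembly_rmsd(asm, cx$complex, reference_map = cx$chain_map)
  expect_lt(r$rmsd, 0.1)  # coordinates quantized to 3 decimals on disk
})
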