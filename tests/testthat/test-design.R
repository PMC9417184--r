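test_that("mutant enumeration is the full power set in binary-counter order", {
  sites7 <- mutation_sites(c("K98R", "A134R", "T148R", "G151E", "G281Q",
                             "T282Q", "G358Q"))
  subsets <- enumerate_mutants(sites7)
  expect_length(subsets, 128)
  expect_equal(subsets[[1]], integer(0))           # wild type first
  expect_equal(subsets[[2]], 1L)                   # binary counter: 0b0000001
  expect_equal(subsets[[6]], c(1L, 3L))            # 0b0000101
  expect_length(enumerate_mutants(sites7[1:3, ]), 8)
  expect_length(enumerate_mutants(sites7[0, ]), 1)
  dup <- sites7; dup$position[2] <- 98L
  expect_error(enumerate_mutants(dup), "duplicate")
  expect_error(mutation_sites("K98K"), "differ")
  expect_error(mutation_sites("junk"), "unparseable")
})

test_that("mutant assemblies carry the mutations on every symmetry copy", {
  sub <- planted_hbond_subunit()
  sites <- tibble::tibble(position = 1L, wild_aa = "A", mutant_aa = "W")
  symdef <- c2_symdef()
  wt <- build_mutant_assembly(sub, sites, integer(0), symdef)
  expect_equal(tibble::as_tibble(wt), tibble::as_tibble(apply_symmetry(sub, symdef)))
  mut <- build_mutant_assembly(sub, sites, 1L, symdef)
  expect_equal(sum(mut$aa == "W"), 4)  # CA + SC on each of 2 copies
  expect_equal(sum(wt$aa == "W"), 0)
  # glycine gaining a side chain grows pseudo-atoms
  sub_g <- assembly(dplyr::bind_rows(
    atom_row("A", 1, "GLY", "CA", 3, 0, 0),
    atom_row("A", 2, "ALA", "CA", 6, 0, 0),
    atom_row("A", 2, "ALA", "SC", 7.5, 0, 0, element = "C")
  ))
  sites_g <- tibble::tibble(position = 1L, wild_aa = "G", mutant_aa = "Q")
  mut_g <- build_mutant_assembly(sub_g, sites_g, 1L, c2_symdef())
  expect_equal(sum(mut_g$atom == "SC" & mut_g$aa == "Q"), 2)
  expect_error(
    build_mutant_assembly(sub_g, tibble::tibble(position = 99L, wild_aa = "G",
                                                mutant_aa = "Q"),
                          1L, c2_symdef()),
    "99")
})

test_that("surrogate score is deterministic, zero for empty interfaces, and
          equals minus the H-bond weight on a planted-bond fixture", {
  # zero jitter: all samples identical
  asm <- apply_symmetry(planted_hbond_subunit(), c2_symdef())
  s0 <- surrogate_score(asm, perturb_sigma = 0, n_samples = 5, seed = 1)
  expect_length(unique(s0$sample_scores), 1)
  # two groups 100 A apart: empty interface, score 0 with warning
  far <- assembly(dplyr::bind_rows(
    atom_row("A", 1, "GLY", "CA", 0, 0, 0),
    atom_row("B", 1, "GLY", "CA", 100, 0, 0)
  ), partition = c(A = "g1", B = "g2"))
  expect_warning(sf <- surrogate_score(far, n_samples = 3, seed = 1),
                 "empty interface")
  expect_equal(sf$sample_scores, c(0, 0, 0))
  # hand-computable 4-atom fixture: one TRP donor vs one ASP acceptor at
  # 3.2 A, nothing else within range -> score is exactly -hbond weight
  hb <- assembly(dplyr::bind_rows(
    atom_row("A", 1, "TRP", "CA", -4, 0, 0),
    atom_row("A", 1, "TRP", "SC", 0, 0, 0, element = "C"),
    atom_row("B", 1, "ASP", "CA", 5.7, 0, 0),
    atom_row("B", 1, "ASP", "SC", 3.2, 0, 0, element = "C")
  ), partition = c(A = "g1", B = "g2"))
  s_hb <- surrogate_score(hb, perturb_sigma = 0, n_samples = 1, seed = 1)
  expect_equal(s_hb$best_score, -surrogate_weights()$hbond)
})

test_that("planted beneficial mutations win the screen", {
  sub <- planted_hbond_subunit(n_motifs = 2)
  sites <- tibble::tibble(position = c(1L, 3L), wild_aa = c("A", "A"),
                          mutant_aa = c("W", "W"))
  scr <- run_screen(sub, sites, c2_symdef(), n_samples = 4,
                    perturb_sigma = 0, seed = 5)
  expect_equal(nrow(scr$candidates), 4)
  expect_equal(scr$selected, 3L)  # binary 0b11: both mutations
  expect_equal(scr$selected_mutations, "A1W+A3W")
  sel <- scr$candidates[scr$candidates$id == scr$selected, ]
  fin <- scr$candidates[scr$candidates$is_finalist, ]
  expect_true(all(sel$hbonds >= fin$hbonds))
  # each planted W-D bond appears once per symmetry copy
  expect_equal(sel$hbonds, 4L)
  expect_equal(sel$best_score, -4 * surrogate_weights()$hbond)
})

test_that("a clashing mutation loses to the wild type", {
  sub <- assembly(dplyr::bind_rows(
    atom_row("A", 1, "ALA", "CA", 3.3, 0.2, 0),
    atom_row("A", 1, "ALA", "SC", 3.3 - 1.53, 0.2, 0, element = "C")
  ))
  sites <- tibble::tibble(position = 1L, wild_aa = "A", mutant_aa = "R")
  scr <- run_screen(sub, sites, c2_symdef(), n_samples = 3,
                    perturb_sigma = 0, seed = 2)
  expect_equal(scr$selected, 0L)  # wild type
  wt_row <- scr$candidates[scr$candidates$id == 0L, ]
  mut_row <- scr$candidates[scr$candidates$id == 1L, ]
  expect_lt(wt_row$best_score, mut_row$best_score)
})

test_that("screens are byte-reproducible under a fixed seed", {
  hp <- make_homolog_pair(test_spec("D3", seed = 14), n_interface_diffs = 3,
                          n_noninterface_diffs = 2)
  sites <- tibble::tibble(position = hp$planted_interface$position,
                          wild_aa = hp$planted_interface$candidate_aa,
                          mutant_aa = hp$planted_interface$template_aa)
  s1 <- run_screen(hp$subunit, sites, hp$symdef, n_samples = 6, seed = 17)
  s2 <- run_screen(hp$subunit, sites, hp$symdef, n_samples = 6, seed = 17)
  expect_identical(s1$candidates, s2$candidates)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$selected_assembly, s2$selected_assembly)
  # selection invariant: no finalist beats the selected H-bond count
  sel <- s1$candidates[s1$candidates$id == s1$selected, ]
  fin <- s1$candidates[s1$candidates$is_finalist, ]
  expect_true(all(sel$hbonds >= fin$hbonds))
})

test_that("adding an attractive contact never worsens the zero-jitter score", {
  sub1 <- planted_hbond_subunit(n_motifs = 1)
  sub2 <- planted_hbond_subunit(n_motifs = 2)
  sites1 <- tibble::tibble(position = 1L, wild_aa = "A", mutant_aa = "W")
  sites2 <- tibble::tibble(position = c(1L, 3L), wild_aa = c("A", "A"),
                           mutant_aa = c("W", "W"))
  s_one <- run_screen(sub2, sites2[1, ], c2_symdef(), n_samples = 1,
                      perturb_sigma = 0, seed = 1)
  s_both <- run_screen(sub2, sites2, c2_symdef(), n_samples = 1,
                       perturb_sigma = 0, seed = 1)
  best_one <- min(s_one$candidates$best_score)
  best_both <- min(s_both$candidates$best_score)
  expect_lte(best_both, best_one)
})
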