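test_that("grid contacts equal the brute-force all-pairs oracle", {
  for (seed in 1:20) {
    asm <- random_two_group_fixture(seed)
    for (cutoff in c(3.6, 5.5)) {
      ct <- atomic_contacts(asm, "g1", "g2", cutoff)
      bf <- brute_pairs(asm, "g1", "g2", cutoff)
      got <- sort(paste(ct$chain_a, ct$seq_id_a, ct$atom_a, "|",
                        ct$chain_b, ct$seq_id_b, ct$atom_b))
      want <- if (is.null(bf)) character(0) else sort(paste(bf$i_atom, "|", bf$j_atom))
      expect_equal(got, want)
    }
  }
})

test_that("hydrogen bonds and salt bridges match the explicit-table oracle", {
  for (seed in 1:8) {
    asm <- random_two_group_fixture(seed)
    hb <- hydrogen_bonds(asm, "g1", "g2")
    bf <- brute_pairs(asm, "g1", "g2", 3.6)
    if (!is.null(bf)) {
      spl_a <- do.call(rbind, strsplit(bf$i_atom, " "))
      spl_b <- do.call(rbind, strsplit(bf$j_atom, " "))
      aa_of <- function(chain, seq) {
        asm$aa[match(paste(chain, seq), paste(asm$chain, asm$seq_id))]
      }
      aa_a <- aa_of(spl_a[, 1], spl_a[, 2]); aa_b <- aa_of(spl_b[, 1], spl_b[, 2])
      keep <- (oracle_donor(aa_a, spl_a[, 3]) & oracle_acceptor(aa_b, spl_b[, 3])) |
        (oracle_donor(aa_b, spl_b[, 3]) & oracle_acceptor(aa_a, spl_a[, 3]))
      expect_equal(nrow(hb), sum(keep))
    }
    # hydrogen bonds are a subset of contacts at equal cutoff
    ct36 <- atomic_contacts(asm, "g1", "g2", 3.6)
    key <- function(tb) paste(tb$chain_a, tb$seq_id_a, tb$atom_a,
                              tb$chain_b, tb$seq_id_b, tb$atom_b)
    expect_true(all(key(hb) %in% key(ct36)))
    sb <- salt_bridges(asm, "g1", "g2")
    expect_true(all(key(sb) %in% key(atomic_contacts(asm, "g1", "g2", 4.0))))
  }
})

test_that("contact cutoffs behave at the boundary and monotonically", {
  two <- assembly(dplyr::bind_rows(
    atom_row("A", 1, "GLY", "CA", 0, 0, 0),
    atom_row("B", 1, "GLY", "CA", 4, 0, 0)
  ), partition = c(A = "g1", B = "g2"))
  expect_equal(nrow(atomic_contacts(two, "g1", "g2", 5.5)), 1)
  expect_equal(atomic_contacts(two, "g1", "g2", 5.5)$distance, 4)
  expect_equal(nrow(atomic_contacts(two, "g1", "g2", 3.9)), 0)
  # shrinking the cutoff never adds records
  asm <- random_two_group_fixture(3)
  ns <- vapply(c(6, 5.5, 4.5, 3.6, 2.5),
               function(cf) nrow(atomic_contacts(asm, "g1", "g2", cf)),
               numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(atomic_contacts(asm, "g1", "nope", 5), "unknown partition group")
})

test_that("hydrogen-bond typing follows the donor/acceptor table", {
  mk <- function(resname_b, atom_b, elem_b, d) {
    assembly(dplyr::bind_rows(
      atom_row("A", 1, "GLY", "O", 0, 0, 0),
      atom_row("B", 1, resname_b, atom_b, d, 0, 0, element = elem_b)
    ), partition = c(A = "g1", B = "g2"))
  }
  # backbone O vs arginine NH1 at 2.9: canonical donor-acceptor pair
  expect_equal(nrow(hydrogen_bonds(mk("ARG", "NH1", "N", 2.9), "g1", "g2")), 1)
  # two carbons at 3.0: contact but never a hydrogen bond
  cc <- assembly(dplyr::bind_rows(
    atom_row("A", 1, "GLY", "CA", 0, 0, 0),
    atom_row("B", 1, "GLY", "CA", 3, 0, 0)
  ), partition = c(A = "g1", B = "g2"))
  expect_equal(nrow(hydrogen_bonds(cc, "g1", "g2")), 0)
  expect_equal(nrow(atomic_contacts(cc, "g1", "g2", 3.6)), 1)
  # arginine guanidinium vs aspartate carboxylate at 3.2: H-bond AND salt bridge
  rd <- assembly(dplyr::bind_rows(
    atom_row("A", 1, "ARG", "NH1", 0, 0, 0, element = "N"),
    atom_row("B", 1, "ASP", "OD1", 3.2, 0, 0, element = "O")
  ), partition = c(A = "g1", B = "g2"))
  expect_equal(nrow(hydrogen_bonds(rd, "g1", "g2")), 1)
  expect_equal(nrow(salt_bridges(rd, "g1", "g2")), 1)
})

test_that("salt bridges respect the 4.0 Angstrom cutoff", {
  mk <- function(d) assembly(dplyr::bind_rows(
    atom_row("A", 1, "LYS", "NZ", 0, 0, 0, element = "N"),
    atom_row("B", 1, "GLU", "OE1", d, 0, 0, element = "O")
  ), partition = c(A = "g1", B = "g2"))
  expect_equal(nrow(salt_bridges(mk(3.5), "g1", "g2")), 1)
  expect_equal(nrow(salt_bridges(mk(4.5), "g1", "g2")), 0)
})

test_that("interface residues follow the proximity and orientation criteria", {
  # residue at 5.0 A: proximity; residue at 7 A pointing toward: orientation;
  # residue at 7 A pointing away: not interfacial
  mk <- function(sc_x) assembly(dplyr::bind_rows(
    atom_row("A", 1, "SER", "CA", 0, 0, 0, element = "C"),
    atom_row("A", 1, "SER", "SC", sc_x, 0, 0, element = "C"),
    atom_row("B", 1, "GLY", "CA", 9, 0, 0, element = "C")
  ), partition = c(A = "g1", B = "g2"))
  toward <- interface_residues(mk(1.9), "g1", "g2")$interface_residues
  expect_equal(toward$criterion[toward$chain == "A"], "orientation")
  away <- interface_residues(mk(-1.9), "g1", "g2")$interface_residues
  expect_false("A" %in% away$chain)
  near <- assembly(dplyr::bind_rows(
    atom_row("A", 1, "SER", "CA", 0, 0, 0, element = "C"),
    atom_row("A", 1, "SER", "SC", 2.0, 0, 0, element = "C"),
    atom_row("B", 1, "GLY", "CA", 7.0, 0, 0, element = "C")
  ), partition = c(A = "g1", B = "g2"))
  # SC at 2.0 -> 5.0 A from the opposite atom: criterion i
  rep_near <- interface_residues(near, "g1", "g2")$interface_residues
  expect_equal(rep_near$criterion[rep_near$chain == "A"], "proximity")
})

test_that("interface reports are symmetric under group swap", {
  asm <- make_assembly(test_spec("D3", seed = 8))$assembly
  ab <- interface_residues(asm, "dimerA", "dimerB")
  ba <- interface_residues(asm, "dimerB", "dimerA")
  key <- function(tb) sort(paste(tb$group, tb$chain, tb$seq_id, tb$criterion))
  expect_equal(key(ab$interface_residues), key(ba$interface_residues))
  expect_equal(nrow(ab$contacts), nrow(ba$contacts))
  expect_equal(nrow(ab$hydrogen_bonds), nrow(ba$hydrogen_bonds))
})

test_that("percent identity follows the aligned-ungapped-column convention", {
  expect_equal(percent_identity("AAAA", "AAAA"), 100)
  expect_equal(percent_identity("AAAA", "AATA"), 75)
  expect_equal(percent_identity("WWW", "CCC"), 0)
  expect_error(percent_identity("", "AAA"), "non-empty")
})

test_that("differing interface sites recover exactly the planted differences", {
  hp <- make_homolog_pair(test_spec("D3", seed = 9), n_interface_diffs = 7,
                          n_noninterface_diffs = 3)
  sites <- differing_interface_sites(hp$template, hp$candidate_seq)
  expect_equal(sort(sites$position), sort(hp$planted_interface$position))
  # planted non-interfacial differences are never recovered
  expect_length(intersect(sites$position, hp$planted_noninterface$position), 0)
  # identical sequences give an empty site list
  tmpl_seq <- chain_sequence(hp$template, "A")
  none <- differing_interface_sites(hp$template, tmpl_seq)
  expect_equal(nrow(none), 0)
})
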