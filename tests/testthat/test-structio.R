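# Structure reading, ligand separation and binding-site detection.

test_that("generated fixture round-trips with counts, keys and coordinates preserved", {
  f <- cached_fixture()
  cx <- read_complex(f$pdb)
  expect_s3_class(cx, "ligand_complex")
  expect_equal(nrow(cx$residues), f$fx$truth$n_receptor_residues)
  expect_equal(cx$ligand_code, "LIG")
  expect_equal(nrow(cx$ligand_atoms), 12)

  out <- tempfile(fileext = ".pdb")
  write_complex(cx, out)
  cx2 <- read_complex(out)
  expect_identical(cx2$residues$key, cx$residues$key)
  expect_equal(as.matrix(cx2$atoms[, c("x", "y", "z")]),
               as.matrix(cx$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(as.matrix(cx2$ligand_atoms[, c("x", "y", "z")]),
               as.matrix(cx$ligand_atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("altLoc conformers resolve to the highest occupancy, ties alphabetical", {
  set_field <- function(line, start, stop, value) {
    substr(line, start, stop) <- value
    line
  }
  f <- cached_fixture()
  lines <- readLines(f$pdb)
  i <- grep("^ATOM.{9}CB", lines)[1]
  base <- lines[i]
  x <- as.numeric(substr(base, 31, 38))
  # conformer A occ 0.60 keeps original coords, B occ 0.40 is shifted 2 A
  confA <- set_field(set_field(base, 17, 17, "A"), 55, 60, "  0.60")
  confB <- set_field(set_field(base, 17, 17, "B"), 55, 60, "  0.40")
  confB <- set_field(confB, 31, 38, sprintf("%8.3f", x + 2))
  confB <- set_field(confB, 7, 11, " 9999")
  lines <- append(lines[-i], c(confA, confB), after = i - 1)
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  cx <- read_complex(p)
  key <- paste0(substr(base, 22, 22), ":",
                as.integer(substr(base, 23, 26)))
  got_x <- cx$atoms$x[cx$atoms$key == key & cx$atoms$elety == "CB"]
  expect_equal(got_x, x, tolerance = 1e-3)

  # equal occupancies: alphabetically first conformer (A) wins
  confB2 <- set_field(confB, 55, 60, "  0.60")
  lines2 <- readLines(f$pdb)
  lines2 <- append(lines2[-i], c(confA, confB2), after = i - 1)
  writeLines(lines2, p)
  cx2 <- read_complex(p)
  expect_equal(cx2$atoms$x[cx2$atoms$key == key & cx2$atoms$elety == "CB"],
               x, tolerance = 1e-3)
})

test_that("ligand auto-detection applies the heavy-atom and exclusion filters", {
  # decoy heterogen with only 3 atoms: filtered out, LIG picked
  f <- cached_fixture("decoy", fixture_spec(
    seed = 11, decoy = list(code = "EDO", n_atoms = 3)))
  cx <- read_complex(f$pdb)
  expect_equal(cx$ligand_code, "LIG")

  # a second large heterogen makes auto-detection ambiguous
  f2 <- cached_fixture("decoy8", fixture_spec(
    seed = 11, decoy = list(code = "XYZ", n_atoms = 8)))
  expect_error(read_complex(f2$pdb), "ambiguous.*LIG.*XYZ|ambiguous.*XYZ")
  expect_equal(read_complex(f2$pdb, ligand_code = "LIG")$ligand_code, "LIG")

  # waters and ions never become ligand candidates
  lines <- readLines(cached_fixture()$pdb)
  wat <- c(
    "HETATM 9000  O   HOH W 500      99.000  99.000  99.000  1.00  0.00           O",
    "HETATM 9001 NA    NA W 501      98.000  98.000  98.000  1.00  0.00          NA")
  p <- tempfile(fileext = ".pdb")
  writeLines(append(lines, wat, after = grep("^END", lines)[1] - 1), p)
  expect_equal(read_complex(p)$ligand_code, "LIG")
})

test_that("the distance cutoff is inclusive at the boundary", {
  # hand-written micro-complex: two single-atom residues at 3.90 and 4.10 A
  # from a six-atom ligand's nearest atom
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   3.900  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       0.000   0.000  -4.100  1.00  0.00           C",
    sprintf("HETATM %4d  C%d  LIG L  10    %8.3f%8.3f%8.3f  1.00  0.00           C",
            3:8, 1:6, c(0, 20, 21, 22, 23, 24), 0, 0),
    "END")
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  cx <- read_complex(p)
  site <- find_binding_site(cx, binding_site_spec(cutoff = 4.0))
  expect_identical(site, "A:1")
})

test_that("binding-site detection matches the brute-force scan and recovers the plan", {
  f <- cached_fixture()
  cx <- cached_complex()
  site <- find_binding_site(cx)
  expect_identical(site, f$fx$truth$pocket_keys)
  expect_identical(site, brute_force_site(cx, 4.0))

  # engineered plan from the spec example: an explicit 4-residue pocket
  plan <- data.frame(helix = c(1L, 1L, 2L, 2L), position = c(5L, 9L, 5L, 9L))
  f2 <- cached_fixture("plan4", fixture_spec(pocket_plan = plan, seed = 5,
                                             bundle_radius = 16))
  cx2 <- read_complex(f2$pdb)
  expect_identical(find_binding_site(cx2), f2$fx$truth$pocket_keys)
  expect_identical(find_binding_site(cx2), brute_force_site(cx2, 4.0))
})

test_that("binding site is invariant under joint rigid-body motion and monotone in the cutoff", {
  cx <- cached_complex()
  site <- find_binding_site(cx)

  rot <- function(deg) {
    th <- deg * pi / 180
    matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  }
  R <- rot(37) %*% matrix(c(1, 0, 0, 0, cos(0.5), -sin(0.5),
                            0, sin(0.5), cos(0.5)), 3, 3)
  shift <- c(11.2, -3.4, 7.9)
  cx_t <- cx
  cx_t$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(cx$atoms[, c("x", "y", "z")]) %*% t(R), 2, -shift)
  cx_t$ligand_atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(cx$ligand_atoms[, c("x", "y", "z")]) %*% t(R), 2, -shift)
  expect_identical(find_binding_site(cx_t), site)

  sites <- lapply(c(3, 4, 5, 8), function(cc)
    find_binding_site(cx, binding_site_spec(cutoff = cc)))
  for (i in seq_len(length(sites) - 1))
    expect_true(all(sites[[i]] %in% sites[[i + 1]]))
})

test_that("receptor restriction, fusion warning and pocket report behave", {
  f <- cached_fixture()
  cx <- read_complex(f$pdb, residue_range = c(1, 52))
  expect_true(all(cx$residues$resno <= 52))
  expect_error(read_complex(f$pdb, residue_range = c(900, 999)),
               "empty receptor")

  big <- cached_fixture("big", fixture_spec(
    helix_length = 70, seed = 2,
    pocket_plan = data.frame(helix = 3, position = 35)))
  expect_warning(read_complex(big$pdb), "450")

  rep <- pocket_report(cached_complex())
  expect_identical(paste0(rep$chain, ":", rep$res_seq),
                   f$fx$truth$pocket_keys)
  expect_true(all(rep$min_distance <= 4.0))
  expect_true(all(rep$min_distance >= 3.4))
})

test_that("modified residues are remapped to their parent amino acid", {
  f <- cached_fixture()
  lines <- readLines(f$pdb)
  # rewrite the first MET residue as selenomethionine HETATM records
  cx0 <- read_complex(f$pdb)
  met <- cx0$residues$resno[cx0$residues$resid == "MET"][1]
  skip_if(is.na(met), "fixture has no methionine")
  sel <- grepl(sprintf("^ATOM.{13}MET A%4d", met), lines)
  lines[sel] <- sub("^ATOM  ", "HETATM", sub(" MET ", " MSE ", lines[sel]))
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  cx <- read_complex(p)
  expect_equal(cx$residues$resid[cx$residues$resno == met], "MET")
  expect_equal(cx$residues$aa1[cx$residues$resno == met], "M")
  expect_equal(nrow(cx$residues), nrow(cx0$residues))
  expect_equal(cx$ligand_code, "LIG")
})

test_that("mmCIF input parses to the same complex as PDB", {
  f <- cached_fixture()
  # rewrite the fixture as a standard 21-column atom_site loop
  cif <- tempfile(fileext = ".cif")
  ln <- readLines(f$pdb)
  ln <- ln[grepl("^(ATOM|HETATM)", ln)]
  fields <- c("group_PDB", "id", "type_symbol", "label_atom_id",
              "label_alt_id", "label_comp_id", "label_asym_id",
              "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
              "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
              "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
              "auth_comp_id", "auth_asym_id", "auth_atom_id",
              "pdbx_PDB_model_num")
  rows <- vapply(ln, function(l) {
    paste(trimws(substr(l, 1, 6)), trimws(substr(l, 7, 11)),
          substr(l, 77, 78), trimws(substr(l, 13, 16)), ".",
          trimws(substr(l, 18, 20)), substr(l, 22, 22), "1",
          trimws(substr(l, 23, 26)), "?", trimws(substr(l, 31, 38)),
          trimws(substr(l, 39, 46)), trimws(substr(l, 47, 54)),
          "1.00", "0.00", "?", trimws(substr(l, 23, 26)),
          trimws(substr(l, 18, 20)), substr(l, 22, 22),
          trimws(substr(l, 13, 16)), "1")
  }, "", USE.NAMES = FALSE)
  writeLines(c("data_FX", "#", "loop_", paste0("_atom_site.", fields),
               rows, "#"), cif)
  cx_pdb <- read_complex(f$pdb)
  cx_cif <- read_complex(cif, ligand_code = "LIG", chain_id = "A")
  expect_identical(cx_cif$residues$resno, cx_pdb$residues$resno)
  expect_identical(find_binding_site(cx_cif), find_binding_site(cx_pdb))
})
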