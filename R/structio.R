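# Structure input: read ligand-receptor complexes, separate receptor from
# ligand, resolve altLocs, remap common modified residues, and detect
# binding-site residues by distance cutoff. Parsing of PDB/mmCIF goes
# through bio3d; this module owns the complex model built on top of it.

.aa321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# modified residue -> parent 3-letter code
.modres_map <- c(MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR",
                 CSO = "CYS", HYP = "PRO", MLY = "LYS", PCA = "GLU",
                 KCX = "LYS", CME = "CYS")

# waters, monatomic ions, cryo-agents and other non-ligand heterogens
# excluded from ligand auto-detection (user-extensible via `exclude`)
.default_het_exclude <- c(
  "HOH", "DOD", "WAT", "NA", "K", "CL", "MG", "ZN", "CA", "MN", "FE", "NI",
  "CU", "CO", "CD", "BR", "IOD", "SO4", "PO4", "GOL", "EDO", "PEG", "PGE",
  "PG4", "MPD", "DMS", "ACT", "FMT", "TRS", "EPE", "MES", "BME", "OLC",
  "OLA", "OLB", "CLR", "CHS", "PLM", "MYR", "BOG", "LDA", "LMT", "NAG",
  "BMA", "MAN", "FUC", "GLC")

.res_key <- function(chain, resno, insert) {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, insert)
}

# resolve alternate conformations: keep the highest-occupancy copy of each
# atom; ties broken by the alphabetically first altLoc
.resolve_altloc <- function(at) {
  alt <- ifelse(is.na(at$alt), "", at$alt)
  if (!any(alt != "")) return(at)
  o <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$resid, at$elety, sep = "|")
  ord <- order(key, -o, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at[order(as.integer(at$eleno)), , drop = FALSE]
}

#' Binding-site detection parameters
#'
#' @param cutoff contact distance in Angstrom (default 4.0); a receptor
#'   residue belongs to the binding site when any of its atoms lies within
#'   `cutoff` (inclusive) of any ligand atom.
#' @param heavy_atoms_only when `TRUE` (default) hydrogens are ignored on
#'   both sides of the distance test, so results do not depend on whether
#'   hydrogens were modelled.
#' @return object of class `binding_site_spec`.
#' @export
binding_site_spec <- function(cutoff = 4.0, heavy_atoms_only = TRUE) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0,
            is.logical(heavy_atoms_only))
  structure(list(cutoff = cutoff, heavy_atoms_only = heavy_atoms_only),
            class = "binding_site_spec")
}

#' Read a ligand-receptor complex from a PDB or mmCIF file
#'
#' Loads the first model, resolves alternate locations to the
#' highest-occupancy conformer, remaps common modified residues (MSE and
#' friends) to their parent amino acids, separates the receptor polymer
#' chain from the ligand heterogen and flags hydrogens.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param ligand_code 3-letter chemical component id of the ligand, or
#'   `NULL` to auto-detect: exactly one non-water, non-ion heterogen with at
#'   least 6 heavy atoms must remain after the exclusion list is applied.
#' @param chain_id receptor chain, or `NULL` to pick the chain with the most
#'   polymer residues.
#' @param residue_range optional inclusive `c(lo, hi)` author-numbering
#'   interval restricting the receptor (used to excise fusion domains such
#'   as BRIL or T4 lysozyme).
#' @param exclude heterogen codes never considered ligand candidates;
#'   extends the built-in water/ion/cryo-agent list.
#' @param source_id identifier recorded in outputs; defaults to the file
#'   base name.
#' @return object of class `ligand_complex` with elements `source_id`,
#'   `residues` (one row per receptor residue, sequence order), `atoms`
#'   (receptor atoms), `ligand_code` and `ligand_atoms`.
#' @export
read_complex <- function(path, ligand_code = NULL, chain_id = NULL,
                         residue_range = NULL,
                         exclude = character(), source_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) suppressWarnings(
      bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    else withCallingHandlers(
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
      # altLocs are resolved below; bio3d's note about them is noise here
      warning = function(w) {
        if (grepl("alt records", conditionMessage(w), ignore.case = TRUE))
          invokeRestart("muffleWarning")
      }),
    error = function(e) stop("failed to parse structure file '", path,
                             "': ", conditionMessage(e)))
  at <- pdb$atom
  at <- .resolve_altloc(at)
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  elesy <- at$elesy
  elesy[is.na(elesy) | elesy == ""] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                                           at$elety[is.na(elesy) | elesy == ""])
  at$elesy <- toupper(elesy)
  at$hydrogen <- at$elesy %in% c("H", "D")

  # remap modified residues to their parents and treat them as polymer
  modsel <- at$resid %in% names(.modres_map)
  if (any(modsel)) {
    at$type[modsel] <- "ATOM"
    at$resid[modsel] <- .modres_map[at$resid[modsel]]
    at$elesy[modsel & at$elesy == "SE"] <- "S"
    at$elety[modsel & at$elety == "SE"] <- "SD"
  }

  poly <- at[at$type == "ATOM" & at$resid %in% names(.aa321), , drop = FALSE]
  if (!nrow(poly)) stop("no polymer residues found in '", path, "'")
  if (is.null(chain_id)) {
    nres <- tapply(paste(poly$resno, poly$insert), poly$chain,
                   function(x) length(unique(x)))
    chain_id <- names(nres)[which.max(nres)]
  }
  rec <- poly[poly$chain == chain_id, , drop = FALSE]
  if (!nrow(rec)) stop("no polymer residues in chain '", chain_id, "'")
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2)
    rec <- rec[rec$resno >= residue_range[1] & rec$resno <= residue_range[2], ,
               drop = FALSE]
    if (!nrow(rec)) stop("empty receptor after residue_range filter")
  }
  rec$key <- .res_key(rec$chain, rec$resno, rec$insert)

  # residue table in file (sequence) order
  first_idx <- !duplicated(rec$key)
  residues <- data.frame(
    key = rec$key[first_idx], chain = rec$chain[first_idx],
    resno = rec$resno[first_idx], insert = rec$insert[first_idx],
    resid = rec$resid[first_idx],
    aa1 = unname(.aa321[rec$resid[first_idx]]),
    stringsAsFactors = FALSE)
  if (nrow(residues) > 450)
    warning("receptor chain '", chain_id, "' has ", nrow(residues),
            " residues; typical GPCRs have fewer than 450 - consider ",
            "excising fusion domains with residue_range")

  # ligand selection among heterogens
  het <- at[at$type == "HETATM", , drop = FALSE]
  excl <- union(.default_het_exclude, toupper(exclude))
  het <- het[!(toupper(het$resid) %in% excl), , drop = FALSE]
  if (is.null(ligand_code)) {
    if (!nrow(het)) stop("no ligand candidates found (all heterogens excluded)")
    heavy <- het[!het$hydrogen, , drop = FALSE]
    sizes <- tapply(seq_len(nrow(heavy)), heavy$resid, length)
    cand <- names(sizes)[sizes >= 6]
    if (length(cand) == 0)
      stop("no heterogen with >= 6 heavy atoms; candidates seen: ",
           paste(names(sizes), collapse = ", "))
    if (length(cand) > 1)
      stop("ambiguous ligand auto-detection; candidates: ",
           paste(cand, collapse = ", "), " - pass ligand_code explicitly")
    ligand_code <- cand
  }
  lig <- het[het$resid == ligand_code, , drop = FALSE]
  if (!nrow(lig)) stop("ligand component '", ligand_code, "' not found")
  # several copies: keep the instance closest to the receptor centroid
  inst <- paste(lig$chain, lig$resno, sep = "|")
  if (length(unique(inst)) > 1) {
    cen <- colMeans(rec[, c("x", "y", "z")])
    dmin <- tapply(seq_len(nrow(lig)), inst, function(i)
      min(sqrt((lig$x[i] - cen[1])^2 + (lig$y[i] - cen[2])^2 +
                 (lig$z[i] - cen[3])^2)))
    lig <- lig[inst == names(dmin)[which.min(dmin)], , drop = FALSE]
  }

  structure(list(
    source_id = if (is.null(source_id))
      sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
    else source_id,
    chain_id = chain_id,
    residues = residues,
    atoms = rec[, c("key", "chain", "resno", "insert", "resid", "elety",
                    "elesy", "x", "y", "z", "o", "hydrogen")],
    ligand_code = ligand_code,
    ligand_atoms = lig[, c("elety", "elesy", "x", "y", "z", "o", "hydrogen")]
  ), class = "ligand_complex")
}

#' @export
print.ligand_complex <- function(x, ...) {
  cat("ligand_complex:", x$source_id, "\n",
      " receptor chain ", x$chain_id, ": ", nrow(x$residues), " residues (",
      nrow(x$atoms), " atoms)\n",
      " ligand ", x$ligand_code, ": ", nrow(x$ligand_atoms), " atoms\n",
      sep = "")
  invisible(x)
}

# minimum receptor-atom to ligand-atom distance per residue
.min_dist_by_residue <- function(cx, heavy_atoms_only = TRUE) {
  ra <- cx$atoms
  la <- cx$ligand_atoms
  if (heavy_atoms_only) {
    ra <- ra[!ra$hydrogen, , drop = FALSE]
    la <- la[!la$hydrogen, , drop = FALSE]
  }
  if (!nrow(ra) || !nrow(la))
    return(setNames(rep(Inf, nrow(cx$residues)), cx$residues$key))
  rxyz <- as.matrix(ra[, c("x", "y", "z")])
  lxyz <- as.matrix(la[, c("x", "y", "z")])
  mind <- rep(Inf, nrow(rxyz))
  for (i in seq_len(nrow(lxyz))) {
    d2 <- (rxyz[, 1] - lxyz[i, 1])^2 + (rxyz[, 2] - lxyz[i, 2])^2 +
      (rxyz[, 3] - lxyz[i, 3])^2
    mind <- pmin(mind, d2)
  }
  mind <- sqrt(mind)
  by_res <- tapply(mind, factor(ra$key, levels = cx$residues$key), min)
  res <- as.numeric(by_res)
  res[is.na(res)] <- Inf
  setNames(res, cx$residues$key)
}

#' Binding-site residues of a complex
#'
#' Returns the receptor residues having at least one atom within the cutoff
#' distance (Euclidean, inclusive) of at least one ligand atom, in receptor
#' sequence order.
#'
#' @param cx a [read_complex()] result.
#' @param spec a [binding_site_spec()].
#' @return character vector of residue keys (`chain:resSeq[icode]`).
#' @export
find_binding_site <- function(cx, spec = binding_site_spec()) {
  stopifnot(inherits(cx, "ligand_complex"), inherits(spec, "binding_site_spec"))
  mind <- .min_dist_by_residue(cx, spec$heavy_atoms_only)
  names(mind)[mind <= spec$cutoff]
}

#' Per-residue pocket report
#'
#' @param cx a [read_complex()] result.
#' @param spec a [binding_site_spec()].
#' @return data frame (chain, res_seq, icode, res_name, min_distance) for
#'   the binding-site residues.
#' @export
pocket_report <- function(cx, spec = binding_site_spec()) {
  mind <- .min_dist_by_residue(cx, spec$heavy_atoms_only)
  sel <- mind <= spec$cutoff
  r <- cx$residues[sel, , drop = FALSE]
  data.frame(chain = r$chain, res_seq = r$resno, icode = r$insert,
             res_name = r$resid, min_distance = round(unname(mind[sel]), 3),
             stringsAsFactors = FALSE)
}

#' Write the pocket report as TSV
#'
#' @inheritParams pocket_report
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pocket_report <- function(cx, path, spec = binding_site_spec()) {
  utils::write.table(pocket_report(cx, spec), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complex back to PDB
#'
#' Receptor atoms followed by ligand HETATM records; used for round-trip
#' checks and for exporting range-filtered receptors.
#'
#' @param cx a [read_complex()] result.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(cx, path) {
  stopifnot(inherits(cx, "ligand_complex"))
  ra <- cx$atoms; la <- cx$ligand_atoms
  n <- nrow(ra) + nrow(la)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(rbind(ra[, c("x", "y", "z")],
                                       la[, c("x", "y", "z")])))),
    type = c(rep("ATOM", nrow(ra)), rep("HETATM", nrow(la))),
    resno = c(ra$resno, rep(max(ra$resno) + 10L, nrow(la))),
    resid = c(ra$resid, rep(cx$ligand_code, nrow(la))),
    eleno = seq_len(n),
    elety = c(ra$elety, la$elety),
    elesy = c(ra$elesy, la$elesy),
    insert = c(ra$insert, rep("", nrow(la))),
    chain = c(ra$chain, rep("L", nrow(la))),
    o = rep(1, n), b = rep(0, n))
  invisible(path)
}
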