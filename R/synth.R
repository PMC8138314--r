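# Synthetic ligand-receptor fixture generator.
#
# Builds an idealized seven-helix transmembrane bundle (NeRF chain growth with
# exact backbone torsions, helices placed on a circle with alternating
# direction, unmodelled loops as resSeq gaps) plus a multi-atom ligand placed
# so that a designated residue set lies within a stated contact distance while
# every other residue stays beyond a spacer distance. Ground truth (helix
# ranges, pocket keys, expected digit strings) is recorded independently of
# the profiling pipeline so the pipeline can be tested against it.

# Residue-group tables used ONLY to compute the truth digit strings. These
# duplicate the profiler defaults on purpose: the truth must be derivable
# without running the pipeline.
.synth_g8 <- c(G = 0, A = 0, V = 0, L = 0, I = 0, P = 0, M = 0, C = 0,
               F = 0, W = 0, Y = 0, S = 1, T = 1, N = 1, Q = 1,
               D = 2, E = 2, K = 3, R = 3, H = 3)
.synth_g10 <- c(G = 0, A = 0, V = 0, L = 0, I = 0, P = 0, M = 0, C = 0,
                F = 1, W = 1, Y = 1, S = 2, T = 2, N = 2, Q = 2,
                D = 3, E = 3, K = 4, R = 4, H = 4)

.aa123 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Specification of a synthetic ligand-receptor fixture
#'
#' Collects the parameters of the synthetic seven-helix bundle and of the
#' ligand placement, with validation. Defaults emulate a compact class A
#' GPCR-like bundle: 7 helices of 24 residues, a ligand contacting a small
#' pocket at 3.5 A while all remaining residues stay at least 6 A away,
#' straddling the 4 A cutoff used for binding-site detection.
#'
#' @param n_helices number of helices (default 7).
#' @param helix_length residues per helix; scalar or one value per helix
#'   (default 24).
#' @param sequences optional character vector of per-helix residue strings
#'   (1-letter codes); when `NULL`, sequences are drawn at random under
#'   `seed`.
#' @param pocket_plan data frame with columns `helix` and `position`
#'   (1-based position within the helix) naming the residues the ligand is
#'   placed against.
#' @param contact_distance ligand-to-pocket-residue distance in Angstrom.
#' @param spacer_distance minimum ligand distance to every non-pocket
#'   residue, Angstrom.
#' @param seed integer seed for random sequences.
#' @param bundle_radius circle radius on which helix axes sit, Angstrom.
#' @param phi,psi backbone torsions in degrees applied to every helix
#'   residue (defaults: ideal alpha helix, -57/-47).
#' @param resseq_gap resSeq numbering gap between consecutive helices
#'   (unmodelled loops).
#' @param chain_id receptor chain identifier.
#' @param ligand_code 3-letter chemical component id of the ligand.
#' @param n_ligand_atoms total ligand heavy atoms (contact atoms plus
#'   central filler atoms; must be >= number of pocket-plan rows).
#' @param decoy optional list(code=, n_atoms=) adding a small extra hetero
#'   component far from the receptor (exercises ligand auto-detection).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_helices = 7, helix_length = 24, sequences = NULL,
                         pocket_plan = data.frame(
                           helix = c(3L, 3L, 5L, 6L, 7L),
                           position = c(10L, 17L, 12L, 12L, 12L)),
                         contact_distance = 3.5, spacer_distance = 6.0,
                         seed = 1L, bundle_radius = 13.0,
                         phi = -57, psi = -47, resseq_gap = 4L,
                         chain_id = "A", ligand_code = "LIG",
                         n_ligand_atoms = 12L, decoy = NULL) {
  stopifnot(n_helices >= 1, all(helix_length >= 4))
  if (length(helix_length) == 1) helix_length <- rep(helix_length, n_helices)
  stopifnot(length(helix_length) == n_helices)
  if (!is.null(sequences)) {
    stopifnot(length(sequences) == n_helices,
              all(nchar(sequences) == helix_length))
    bad <- setdiff(unique(strsplit(paste(sequences, collapse = ""), "")[[1]]),
                   names(.aa123))
    if (length(bad))
      stop("sequences contain non-standard residue codes: ",
           paste(bad, collapse = ", "))
  }
  pocket_plan <- as.data.frame(pocket_plan)
  stopifnot(all(c("helix", "position") %in% names(pocket_plan)))
  if (nrow(pocket_plan)) {
    stopifnot(all(pocket_plan$helix >= 1), all(pocket_plan$helix <= n_helices),
              all(pocket_plan$position >= 1),
              all(pocket_plan$position <=
                    helix_length[pocket_plan$helix]))
    if (anyDuplicated(pocket_plan[c("helix", "position")]))
      stop("duplicate pocket plan entries")
  }
  if (!(contact_distance > 0 && contact_distance < spacer_distance))
    stop("contact_distance must be positive and below spacer_distance")
  if (n_ligand_atoms < max(nrow(pocket_plan), 6L))
    stop("n_ligand_atoms must be at least max(6, number of pocket residues)")
  structure(list(
    n_helices = as.integer(n_helices),
    helix_length = as.integer(helix_length),
    sequences = sequences, pocket_plan = pocket_plan,
    contact_distance = contact_distance, spacer_distance = spacer_distance,
    seed = as.integer(seed), bundle_radius = bundle_radius,
    phi = phi, psi = psi, resseq_gap = as.integer(resseq_gap),
    chain_id = chain_id, ligand_code = ligand_code,
    n_ligand_atoms = as.integer(n_ligand_atoms), decoy = decoy
  ), class = "fixture_spec")
}

# Build one helix with NeRF chain growth; returns a data.frame of backbone
# (+CB) atoms with exact phi/psi torsions for every residue.
.build_helix_atoms <- function(seq1, phi, psi) {
  L <- nchar(seq1)
  aa <- strsplit(seq1, "")[[1]]
  rows <- list()
  # residue 1 bootstrap
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  cc <- place_atom(c(0, 1, 0), n, ca, 1.525, 111.2, -120)  # arbitrary start
  prev <- list(n = n, ca = ca, c = cc)
  add <- function(i, name, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      resi = i, elety = name, x = xyz[1], y = xyz[2], z = xyz[3])
  }
  for (i in seq_len(L)) {
    if (i > 1L) {
      n <- place_atom(prev$n, prev$ca, prev$c, 1.329, 116.2, psi)
      ca <- place_atom(prev$ca, prev$c, n, 1.458, 121.7, 180)   # omega trans
      cc <- place_atom(prev$c, n, ca, 1.525, 111.2, phi)
    } else {
      n <- prev$n; ca <- prev$ca; cc <- prev$c
    }
    o <- place_atom(n, ca, cc, 1.231, 120.8, psi + 180)
    add(i, "N", n); add(i, "CA", ca); add(i, "C", cc); add(i, "O", o)
    if (aa[i] != "G") {
      cb <- place_atom(cc, n, ca, 1.521, 110.4, 122.6)
      add(i, "CB", cb)
    }
    prev <- list(n = n, ca = ca, c = cc)
  }
  do.call(rbind, rows)
}

# Deterministic direction grid on the hemisphere around `base` used to pick
# the ligand-atom direction that maximizes clearance from non-pocket atoms.
.direction_grid <- function(base) {
  base <- unitv(base)
  ref <- if (abs(base[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unitv(vcross(base, ref))
  v <- vcross(base, u)
  dirs <- list(base)
  for (tilt in c(15, 30, 45, 60)) {
    for (az in seq(0, 330, by = 30)) {
      t <- tilt * pi / 180; a <- az * pi / 180
      dirs[[length(dirs) + 1L]] <-
        unitv(cos(t) * base + sin(t) * (cos(a) * u + sin(a) * v))
    }
  }
  dirs
}

#' Generate a synthetic ligand-receptor complex with ground truth
#'
#' Constructs the bundle described by a [fixture_spec()], places the ligand,
#' verifies the geometric plan by a brute-force all-pairs distance scan and
#' returns the PDB text together with the recorded truth. Deterministic for
#' a given spec (byte-identical PDB text on repeated calls).
#'
#' @param spec a [fixture_spec()].
#' @return object of class `gpcr_fixture`: list with `pdb` (character vector
#'   of PDB lines), `truth` (helix ranges, pocket keys, per-scheme expected
#'   digit strings, sequences) and `spec`.
#' @export
make_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  sequences <- spec$sequences
  if (is.null(sequences)) {
    if (exists(".Random.seed", envir = globalenv()))
      old_seed <- get(".Random.seed", envir = globalenv())
    else old_seed <- NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
    sequences <- vapply(seq_len(spec$n_helices), function(k)
      paste(sample(names(.aa123), spec$helix_length[k], replace = TRUE),
            collapse = ""), "")
    # planned contact residues need a C-beta anchor: no glycine there
    if (nrow(spec$pocket_plan)) {
      for (r in seq_len(nrow(spec$pocket_plan))) {
        h <- spec$pocket_plan$helix[r]; pos <- spec$pocket_plan$position[r]
        if (substring(sequences[h], pos, pos) == "G") {
          repl <- sample(setdiff(names(.aa123), "G"), 1)
          substring(sequences[h], pos, pos) <- repl
        }
      }
    }
  }

  L <- spec$helix_length
  # author-numbering start of each helix (resSeq gaps = unmodelled loops)
  hstart <- cumsum(c(1L, L[-length(L)] + spec$resseq_gap))
  nh <- spec$n_helices
  rb <- spec$bundle_radius
  plan <- spec$pocket_plan

  helix_frames <- vector("list", nh)
  for (k in seq_len(nh)) {
    at <- .build_helix_atoms(sequences[k], spec$phi, spec$psi)
    xyz <- as.matrix(at[, c("x", "y", "z")])
    ca <- xyz[at$elety == "CA", , drop = FALSE]
    cen <- colMeans(ca)
    pc <- svd(sweep(ca, 2, cen))$v[, 1]
    if (sum((ca[nrow(ca), ] - ca[1, ]) * pc) < 0) pc <- -pc
    up <- if (k %% 2 == 1) c(0, 0, 1) else c(0, 0, -1)
    r1 <- rotmat_between(pc, up)
    xyz <- sweep(xyz, 2, cen) %*% t(r1)
    # phase: point the anchor residue's side chain at the bundle axis
    theta <- 2 * pi * (k - 1) / nh
    pos2d <- rb * c(cos(theta), sin(theta))
    prows <- plan$position[plan$helix == k]
    anchor_resi <- if (length(prows)) prows[1] else ceiling(L[k] / 2)
    ai <- which(at$resi == anchor_resi &
                  at$elety == ifelse(any(at$resi == anchor_resi & at$elety == "CB"),
                                     "CB", "CA"))[1]
    want <- atan2(-pos2d[2], -pos2d[1])
    have <- atan2(xyz[ai, 2], xyz[ai, 1])
    r2 <- rotmat_axis_angle(c(0, 0, 1), (want - have) * 180 / pi)
    xyz <- xyz %*% t(r2)
    xyz[, 1] <- xyz[, 1] + pos2d[1]
    xyz[, 2] <- xyz[, 2] + pos2d[2]
    at[, c("x", "y", "z")] <- xyz
    at$helix <- k
    at$resno <- hstart[k] - 1L + at$resi
    helix_frames[[k]] <- at
  }
  rec <- do.call(rbind, helix_frames)
  aa_by_resno <- new.env()
  for (k in seq_len(nh)) {
    aas <- strsplit(sequences[k], "")[[1]]
    for (i in seq_len(L[k]))
      assign(as.character(hstart[k] - 1L + i), aas[i], envir = aa_by_resno)
  }
  rec$aa <- vapply(as.character(rec$resno), function(r)
    get(r, envir = aa_by_resno), "")

  # pocket residue resnos and anchors
  plan$resno <- hstart[plan$helix] - 1L + plan$position
  rec_xyz <- as.matrix(rec[, c("x", "y", "z")])
  pocket_resnos <- plan$resno
  nonpocket_mask <- !(rec$resno %in% pocket_resnos)

  lig <- matrix(NA_real_, 0, 3)
  for (j in seq_len(nrow(plan))) {
    sel <- which(rec$resno == plan$resno[j] &
                   rec$elety == ifelse(any(rec$resno == plan$resno[j] &
                                             rec$elety == "CB"), "CB", "CA"))
    anchor <- rec_xyz[sel[1], ]
    base <- c(-anchor[1], -anchor[2], 0)
    if (vnorm(base) < 1e-6) base <- c(1, 0, 0)
    best <- NULL; best_d <- -Inf
    for (dir in .direction_grid(base)) {
      cand <- anchor + spec$contact_distance * dir
      d <- sqrt(colSums((t(rec_xyz[nonpocket_mask, , drop = FALSE]) - cand)^2))
      dmin <- min(d)
      if (dmin > best_d) { best_d <- dmin; best <- cand }
    }
    if (best_d < spec$spacer_distance)
      stop("geometric infeasibility: pocket plan entry (helix ", plan$helix[j],
           ", position ", plan$position[j], ") cannot be contacted at ",
           spec$contact_distance, " A while keeping non-pocket residues beyond ",
           spec$spacer_distance, " A (best clearance ", round(best_d, 2), " A)")
    lig <- rbind(lig, best)
  }
  n_fill <- spec$n_ligand_atoms - nrow(plan)
  if (n_fill > 0) {
    zc <- if (nrow(lig)) mean(lig[, 3]) else 0
    fill_z <- zc + 1.5 * (seq_len(n_fill) - (n_fill + 1) / 2)
    for (z in fill_z) {
      cand <- c(0, 0, z)
      d <- sqrt(colSums((t(rec_xyz[nonpocket_mask, , drop = FALSE]) - cand)^2))
      if (min(d) < spec$spacer_distance)
        stop("geometric infeasibility: central filler atom at z=",
             round(z, 2), " closer than spacer to a non-pocket residue")
      lig <- rbind(lig, cand)
    }
  }

  # brute-force verification of the plan
  dmat <- matrix(NA_real_, nrow(lig), nrow(rec_xyz))
  for (i in seq_len(nrow(lig)))
    dmat[i, ] <- sqrt(colSums((t(rec_xyz) - lig[i, ])^2))
  min_by_res <- tapply(apply(dmat, 2, min), rec$resno, min)
  pk <- as.character(pocket_resnos)
  if (any(min_by_res[pk] > spec$contact_distance + 1e-6))
    stop("internal error: planned pocket residue not at contact distance")
  npk <- setdiff(names(min_by_res), pk)
  if (any(min_by_res[npk] < spec$spacer_distance - 1e-6))
    stop("geometric infeasibility: non-pocket residue within spacer distance")

  # truth
  helix_ranges <- data.frame(
    tm = seq_len(nh), chain = spec$chain_id,
    start = hstart, end = hstart + L - 1L)
  pocket_sorted <- sort(pocket_resnos)
  pocket_keys <- paste0(spec$chain_id, ":", pocket_sorted)
  digits_for <- function(gmap, off) {
    vapply(seq_len(nh), function(k) {
      aas <- strsplit(sequences[k], "")[[1]]
      res <- hstart[k] - 1L + seq_len(L[k])
      paste(gmap[aas] + off * (res %in% pocket_resnos), collapse = "")
    }, "")
  }
  truth <- list(
    helix_ranges = helix_ranges,
    pocket_keys = pocket_keys,
    pocket_resnos = pocket_sorted,
    sequences = sequences,
    expected_8dp = digits_for(.synth_g8, 4L),
    expected_10dp = digits_for(.synth_g10, 5L),
    ligand_code = spec$ligand_code,
    n_receptor_residues = sum(L))

  # assemble PDB text through bio3d
  n_rec <- nrow(rec)
  lig_names <- sprintf("C%d", seq_len(nrow(lig)))
  type <- c(rep("ATOM", n_rec), rep("HETATM", nrow(lig)))
  resno <- c(rec$resno, rep(max(rec$resno) + 10L, nrow(lig)))
  resid <- c(unname(.aa123[rec$aa]), rep(spec$ligand_code, nrow(lig)))
  elety <- c(rec$elety, lig_names)
  elesy <- c(substr(rec$elety, 1, 1), rep("C", nrow(lig)))
  chain <- c(rep(spec$chain_id, n_rec), rep("L", nrow(lig)))
  xyz <- rbind(rec_xyz, lig)
  if (!is.null(spec$decoy)) {
    nd <- spec$decoy$n_atoms
    ztop <- max(rec_xyz[, 3]) + 8
    dx <- cbind(0, 1.4 * (seq_len(nd) - 1), ztop + 1.4 * (seq_len(nd) - 1))
    type <- c(type, rep("HETATM", nd))
    resno <- c(resno, rep(max(resno) + 5L, nd))
    resid <- c(resid, rep(spec$decoy$code, nd))
    elety <- c(elety, sprintf("C%d", seq_len(nd)))
    elesy <- c(elesy, rep("C", nd))
    chain <- c(chain, rep("L", nd))
    xyz <- rbind(xyz, dx)
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp, xyz = as.numeric(t(xyz)), type = type,
                   resno = resno, resid = resid,
                   eleno = seq_along(resno), elety = elety, elesy = elesy,
                   chain = chain, o = rep(1, length(resno)),
                   b = rep(0, length(resno)))
  pdb_lines <- readLines(tmp)
  structure(list(pdb = pdb_lines, truth = truth, spec = spec),
            class = "gpcr_fixture")
}

#' Write a synthetic fixture to disk
#'
#' @param fixture object from [make_complex()].
#' @param path output PDB path.
#' @param annotation_path optional path for the matching helix annotation
#'   file (`TM<k> <chain> <start> <end>` lines).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(fixture, path, annotation_path = NULL) {
  stopifnot(inherits(fixture, "gpcr_fixture"))
  writeLines(fixture$pdb, path)
  if (!is.null(annotation_path)) {
    hr <- fixture$truth$helix_ranges
    writeLines(c("# helix annotation generated alongside the fixture",
                 sprintf("TM%d %s %d %d", hr$tm, hr$chain, hr$start, hr$end)),
               annotation_path)
  }
  invisible(path)
}

#' Generate a related pair of fixtures with a known expected score relation
#'
#' @param spec_a base [fixture_spec()].
#' @param relation one of `"identical"`, `"pocket_subset"` (the second
#'   fixture's pocket is a contiguous sub-run of the first's on each helix;
#'   under identity scoring with pocket scope, N equals the pocket size
#'   ratio), `"group_shuffled"` (residues swapped within physico-chemical
#'   groups; digit strings are unchanged, so N = 1).
#' @param drop for `"pocket_subset"`: how many pocket-plan rows to drop from
#'   the end of the plan (default 2).
#' @return list with fixtures `a`, `b`, the `relation` and `expected`, a list
#'   describing the score relation the pair encodes.
#' @export
make_pair <- function(spec_a, relation = c("identical", "pocket_subset",
                                           "group_shuffled"), drop = 2L) {
  relation <- match.arg(relation)
  fa <- make_complex(spec_a)
  spec_b <- spec_a
  expected <- NULL
  if (relation == "identical") {
    expected <- list(N_ab = 1, N_ba = 1)
  } else if (relation == "pocket_subset") {
    n <- nrow(spec_a$pocket_plan)
    if (drop < 1 || drop >= n)
      stop("drop must leave at least one pocket residue")
    spec_b$pocket_plan <- spec_a$pocket_plan[seq_len(n - drop), , drop = FALSE]
    spec_b$sequences <- fa$truth$sequences
    expected <- list(N_b_as_target = (n - drop) / n, scope = "pocket",
                     model = "identity")
  } else {
    swap <- c(A = "V", V = "A", L = "I", I = "L", M = "C", C = "M", P = "P",
              G = "G", F = "W", W = "F", Y = "Y", S = "T", T = "S",
              N = "Q", Q = "N", D = "E", E = "D", K = "R", R = "K", H = "H")
    spec_b$sequences <- vapply(fa$truth$sequences, function(s)
      paste(swap[strsplit(s, "")[[1]]], collapse = ""), "",
      USE.NAMES = FALSE)
    expected <- list(N_ab = 1, N_ba = 1)
  }
  fb <- make_complex(spec_b)
  list(a = fa, b = fb, relation = relation, expected = expected)
}
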