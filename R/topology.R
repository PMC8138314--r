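# Transmembrane topology: map receptor residues onto the seven
# transmembrane helices, either from a user annotation file or detected
# from backbone phi/psi dihedrals, so that profiles can be split into seven
# per-helix strings.

# phi/psi window accepted as alpha-helical, degrees
.helix_phi_window <- c(-100, -30)
.helix_psi_window <- c(-80, -5)

.new_helix_annotation <- function(segments, source) {
  stopifnot(is.data.frame(segments),
            all(c("tm", "chain", "start", "end") %in% names(segments)))
  if (nrow(segments) != 7)
    stop("expected 7 segments (TM1..TM7), got ", nrow(segments))
  segments <- segments[order(segments$start), , drop = FALSE]
  segments$tm <- 1:7
  if (any(segments$end - segments$start + 1 < 4))
    stop("each helix segment must span at least 4 residues")
  for (i in 2:7) {
    if (segments$chain[i] == segments$chain[i - 1] &&
        segments$start[i] <= segments$end[i - 1])
      stop("overlapping helix segments: TM", i - 1, " and TM", i)
  }
  rownames(segments) <- NULL
  structure(list(segments = segments, source = source),
            class = "helix_annotation")
}

#' @export
print.helix_annotation <- function(x, ...) {
  cat("helix_annotation (source:", x$source, ")\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Read a helix annotation file
#'
#' Plain-text annotation, one line per helix: `TM<k> <chain> <start> <end>`
#' (inclusive author numbering); `#` starts a comment. Exactly seven
#' non-overlapping segments are required.
#'
#' @param path annotation file.
#' @param cx optional [read_complex()] result; when given, every range must
#'   resolve to at least one existing receptor residue.
#' @return object of class `helix_annotation` with source `"user"`.
#' @export
read_helix_annotation <- function(path, cx = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  if (length(ln) != 7)
    stop("expected 7 segments (TM1..TM7) in '", path, "', got ", length(ln))
  parts <- strsplit(ln, "[[:space:]]+")
  bad <- vapply(parts, function(p) length(p) != 4, TRUE)
  if (any(bad))
    stop("malformed annotation line(s): ",
         paste(ln[bad], collapse = " | "))
  segments <- data.frame(
    tm = as.integer(sub("^TM", "", vapply(parts, `[`, "", 1),
                        ignore.case = TRUE)),
    chain = vapply(parts, `[`, "", 2),
    start = as.integer(vapply(parts, `[`, "", 3)),
    end = as.integer(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE)
  if (anyNA(segments$start) || anyNA(segments$end) || anyNA(segments$tm))
    stop("non-numeric helix range in '", path, "'")
  if (any(segments$end < segments$start))
    stop("helix range with end < start in '", path, "'")
  ann <- .new_helix_annotation(segments, "user")
  if (!is.null(cx)) {
    for (i in 1:7) {
      s <- ann$segments[i, ]
      hit <- cx$residues$chain == s$chain &
        cx$residues$resno >= s$start & cx$residues$resno <= s$end
      if (!any(hit))
        stop("annotation TM", s$tm, " (", s$chain, " ", s$start, "-", s$end,
             ") resolves to no residue of ", cx$source_id)
    }
  }
  ann
}

# phi/psi per residue; residues are sequence-adjacent when they share a
# chain and their author numbers are consecutive (resSeq gaps, e.g.
# unmodelled loops, break the chain)
.backbone_dihedrals <- function(cx) {
  res <- cx$residues
  at <- cx$atoms[!cx$atoms$hydrogen, , drop = FALSE]
  bb <- function(key, name) {
    i <- which(at$key == key & at$elety == name)
    if (!length(i)) return(NULL)
    c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
  }
  n <- nrow(res)
  have_bb <- logical(n)
  coords <- vector("list", n)
  for (i in seq_len(n)) {
    coords[[i]] <- list(N = bb(res$key[i], "N"), CA = bb(res$key[i], "CA"),
                        C = bb(res$key[i], "C"))
    have_bb[i] <- !any(vapply(coords[[i]], is.null, TRUE))
  }
  if (mean(have_bb) < 0.9)
    stop("backbone N/CA/C missing for more than 10% of residues; ",
         "cannot detect helices")
  adjacent <- c(FALSE, res$chain[-1] == res$chain[-n] &
                  res$resno[-1] == res$resno[-n] + 1L &
                  res$insert[-1] == "" & res$insert[-n] == "")
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!have_bb[i]) next
    if (i > 1 && adjacent[i] && have_bb[i - 1])
      phi[i] <- dihedral_angle(coords[[i - 1]]$C, coords[[i]]$N,
                               coords[[i]]$CA, coords[[i]]$C)
    if (i < n && adjacent[i + 1] && have_bb[i + 1])
      psi[i] <- dihedral_angle(coords[[i]]$N, coords[[i]]$CA,
                               coords[[i]]$C, coords[[i + 1]]$N)
  }
  data.frame(key = res$key, chain = res$chain, resno = res$resno,
             phi = phi, psi = psi, adjacent = adjacent,
             stringsAsFactors = FALSE)
}

#' Detect the seven transmembrane helices from backbone dihedrals
#'
#' A residue is alpha-helical when its phi falls in (-100, -30) and its psi
#' in (-80, -5) degrees. Core marking requires a three-residue consensus
#' (residues i-1..i+1 all strictly in-window, undefined dihedrals count as
#' out-of-window); each marked run is then extended outward over adjacent
#' residues whose defined dihedrals are in-window, which recovers the helix
#' termini eroded by the consensus (dihedrals are undefined across chain
#' breaks and at termini). Runs shorter than `min_len` are discarded; the
#' seven longest remaining runs, ordered by sequence position, become
#' TM1..TM7.
#'
#' @param cx a [read_complex()] result with backbone N/CA/C present for at
#'   least 90% of residues.
#' @param min_len minimum helix length in residues (default 8).
#' @return object of class `helix_annotation` with source `"detected"`.
#' @export
detect_helices <- function(cx, min_len = 8L) {
  stopifnot(inherits(cx, "ligand_complex"))
  dh <- .backbone_dihedrals(cx)
  n <- nrow(dh)
  inw_strict <- !is.na(dh$phi) & !is.na(dh$psi) &
    dh$phi > .helix_phi_window[1] & dh$phi < .helix_phi_window[2] &
    dh$psi > .helix_psi_window[1] & dh$psi < .helix_psi_window[2]
  # loose test for boundary extension: undefined dihedrals ignored, but at
  # least one must be defined and in-window
  okphi <- is.na(dh$phi) |
    (dh$phi > .helix_phi_window[1] & dh$phi < .helix_phi_window[2])
  okpsi <- is.na(dh$psi) |
    (dh$psi > .helix_psi_window[1] & dh$psi < .helix_psi_window[2])
  inw_loose <- okphi & okpsi & !(is.na(dh$phi) & is.na(dh$psi))
  marked <- logical(n)
  for (i in seq_len(n))
    marked[i] <- i > 1 && i < n &&
      inw_strict[i - 1] && inw_strict[i] && inw_strict[i + 1]
  # runs of marked residues
  runs <- rle(marked)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- data.frame(start = starts[runs$values], end = ends[runs$values])
  if (nrow(seg)) {
    for (r in seq_len(nrow(seg))) {
      while (seg$start[r] > 1 && inw_loose[seg$start[r] - 1] &&
             dh$adjacent[seg$start[r]])
        seg$start[r] <- seg$start[r] - 1L
      while (seg$end[r] < n && inw_loose[seg$end[r] + 1] &&
             dh$adjacent[seg$end[r] + 1])
        seg$end[r] <- seg$end[r] + 1L
    }
    # extension can make adjacent runs touch; merge
    seg <- seg[order(seg$start), , drop = FALSE]
    keep <- !duplicated(seg$start)
    seg <- seg[keep, , drop = FALSE]
    merged <- seg[1, , drop = FALSE]
    if (nrow(seg) > 1) {
      for (r in 2:nrow(seg)) {
        if (seg$start[r] <= merged$end[nrow(merged)] + 0L)
          merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], seg$end[r])
        else merged <- rbind(merged, seg[r, ])
      }
    }
    seg <- merged
  }
  seg <- seg[seg$end - seg$start + 1L >= min_len, , drop = FALSE]
  if (nrow(seg) < 7)
    stop("fewer than 7 qualifying helices detected (found ", nrow(seg),
         " runs of length >= ", min_len, ")")
  len <- seg$end - seg$start + 1L
  seg <- seg[order(-len, seg$start)[1:7], , drop = FALSE]
  seg <- seg[order(seg$start), , drop = FALSE]
  .new_helix_annotation(data.frame(
    tm = 1:7, chain = dh$chain[seg$start],
    start = dh$resno[seg$start], end = dh$resno[seg$end],
    stringsAsFactors = FALSE), "detected")
}

#' Helix membership of a residue
#'
#' @param ann a `helix_annotation`.
#' @param key residue key (`chain:resSeq[icode]`) or a vector of keys.
#' @return integer vector: helix index 1-7, or `NA` for loop/terminal
#'   residues. Segment ranges are inclusive at both ends.
#' @export
helix_of <- function(ann, key) {
  stopifnot(inherits(ann, "helix_annotation"))
  m <- regmatches(key, regexec("^(.+):(-?[0-9]+)", key))
  chain <- vapply(m, `[`, "", 2)
  resno <- as.integer(vapply(m, `[`, "", 3))
  out <- rep(NA_integer_, length(key))
  for (i in 1:7) {
    s <- ann$segments[i, ]
    hit <- chain == s$chain & resno >= s$start & resno <= s$end
    out[hit & is.na(out)] <- s$tm
  }
  out
}
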