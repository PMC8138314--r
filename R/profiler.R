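# Residue profiling: reduce the 20-letter amino-acid alphabet to small
# physico-chemical groups, double the alphabet with a binding-site flag and
# build per-helix integer profile strings.
#
# 8DP: four groups -- hydrophobic 0, hydrophilic 1, negatively charged 2,
# positively charged 3; +4 for binding-site residues (symbols 0-7).
# 10DP: the hydrophobic group is split into aliphatic 0 and aromatic 1
# (hydrophilic 2, negative 3, positive 4); +5 for binding-site residues
# (symbols 0-9). Splitting out the aromatics lets pi-stacking-dominated
# pockets score differently from purely aliphatic ones.

.group_names_8 <- c("hydrophobic", "hydrophilic", "negative", "positive")
.group_names_10 <- c("aliphatic", "aromatic", "hydrophilic", "negative",
                     "positive")

.default_groups_8 <- c(
  G = 0, A = 0, V = 0, L = 0, I = 0, P = 0, M = 0, C = 0, F = 0, W = 0, Y = 0,
  S = 1, T = 1, N = 1, Q = 1, D = 2, E = 2, K = 3, R = 3, H = 3)
.default_groups_10 <- c(
  G = 0, A = 0, V = 0, L = 0, I = 0, P = 0, M = 0, C = 0,
  F = 1, W = 1, Y = 1, S = 2, T = 2, N = 2, Q = 2, D = 3, E = 3,
  K = 4, R = 4, H = 4)

#' Profiling scheme (8DP or 10DP)
#'
#' @param name `"8DP"` or `"10DP"`.
#' @param groups optional named integer vector remapping 1-letter residue
#'   codes to group indices (dense, `0 .. n_groups-1`); all 20 standard
#'   residues must be covered. Defaults are the package's built-in tables
#'   (see Details).
#' @details Default group membership: 8DP hydrophobic
#'   \{G,A,V,L,I,P,M,C,F,W,Y\}, hydrophilic \{S,T,N,Q\}, negative \{D,E\},
#'   positive \{K,R,H\}; 10DP splits hydrophobic into aliphatic
#'   \{G,A,V,L,I,P,M,C\} and aromatic \{F,W,Y\}. Histidine sits with the
#'   positives (protonatable at pH 7), tyrosine with the aromatics. All of
#'   this is overridable via `groups` or [read_group_config()].
#' @return object of class `profile_scheme` with fields `name`, `groups`,
#'   `group_names`, `n_groups` and `flag_offset`.
#' @export
profile_scheme <- function(name = c("8DP", "10DP"), groups = NULL) {
  name <- match.arg(name)
  if (is.null(groups))
    groups <- if (name == "8DP") .default_groups_8 else .default_groups_10
  group_names <- if (name == "8DP") .group_names_8 else .group_names_10
  ng <- length(group_names)
  aa <- names(.default_groups_8)
  if (!all(aa %in% names(groups)))
    stop("groups must cover all 20 standard residues; missing: ",
         paste(setdiff(aa, names(groups)), collapse = ", "))
  groups <- groups[aa]
  if (!all(groups %in% 0:(ng - 1)))
    stop("group indices must be dense integers 0..", ng - 1)
  if (length(unique(groups)) != ng)
    stop("every group must contain at least one residue")
  structure(list(name = name, groups = groups, group_names = group_names,
                 n_groups = ng, flag_offset = ng),
            class = "profile_scheme")
}

#' Read a residue-group configuration file
#'
#' Key-value lines `"<1-letter code> <group name>"`; `#` comments allowed.
#' Group names must match the scheme's (`hydrophobic`, `hydrophilic`,
#' `negative`, `positive` for 8DP; `aliphatic`, `aromatic`, `hydrophilic`,
#' `negative`, `positive` for 10DP).
#'
#' @param path config file.
#' @param name scheme name the table is for.
#' @return a [profile_scheme()] built from the file.
#' @export
read_group_config <- function(path, name = c("8DP", "10DP")) {
  name <- match.arg(name)
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "[[:space:]]+")
  code <- toupper(vapply(parts, `[`, "", 1))
  gname <- tolower(vapply(parts, `[`, "", 2))
  gnames <- if (name == "8DP") .group_names_8 else .group_names_10
  if (!all(gname %in% gnames))
    stop("unknown group name(s): ",
         paste(unique(setdiff(gname, gnames)), collapse = ", "))
  groups <- setNames(match(gname, gnames) - 1L, code)
  profile_scheme(name, groups = groups)
}

#' Profile symbol of one residue
#'
#' @param res_code 1-letter residue code.
#' @param scheme a [profile_scheme()].
#' @param is_binding whether the residue is part of the binding site; if so
#'   the group index is raised by the scheme's flag offset (4 for 8DP, 5
#'   for 10DP).
#' @return integer symbol in `0 .. 2*n_groups-1`.
#' @export
classify_residue <- function(res_code, scheme, is_binding = FALSE) {
  stopifnot(inherits(scheme, "profile_scheme"))
  g <- scheme$groups[res_code]
  if (anyNA(g))
    stop("unknown residue code(s): ",
         paste(unique(res_code[is.na(g)]), collapse = ", "))
  unname(g + scheme$flag_offset * as.integer(is_binding))
}

#' Build the per-helix profile of a complex
#'
#' Converts each helix's residues into integer symbols under the scheme,
#' flagging residues in `pocket`. Loop and terminal residues are not
#' profiled; pocket residues falling outside every helix are recorded and a
#' warning is emitted.
#'
#' @param cx a [read_complex()] result.
#' @param ann a `helix_annotation`.
#' @param pocket character vector of binding-site residue keys, typically
#'   from [find_binding_site()].
#' @param scheme a [profile_scheme()].
#' @return object of class `complex_profile`: `source_id`, `ligand_code`,
#'   `scheme`, `helices` (list of 7, each with `helix_index`, `symbols`,
#'   `keys`), `pocket_keys`, `dropped_pocket_keys`.
#' @export
build_profile <- function(cx, ann, pocket, scheme) {
  stopifnot(inherits(cx, "ligand_complex"), inherits(ann, "helix_annotation"),
            inherits(scheme, "profile_scheme"))
  bad <- setdiff(pocket, cx$residues$key)
  if (length(bad))
    stop("pocket keys not in receptor: ", paste(bad, collapse = ", "))
  hx <- helix_of(ann, cx$residues$key)
  helices <- vector("list", 7)
  for (k in 1:7) {
    sel <- which(!is.na(hx) & hx == k)
    if (!length(sel))
      stop("helix TM", k, " contains no receptor residue after mapping")
    keys <- cx$residues$key[sel]
    symbols <- classify_residue(cx$residues$aa1[sel], scheme,
                                is_binding = FALSE)
    flag <- keys %in% pocket
    symbols[flag] <- symbols[flag] + scheme$flag_offset
    helices[[k]] <- list(helix_index = k, symbols = symbols, keys = keys)
  }
  dropped <- pocket[is.na(hx[match(pocket, cx$residues$key)])]
  if (length(dropped))
    warning(length(dropped), " pocket residue(s) outside all helices are ",
            "not profiled: ", paste(dropped, collapse = ", "))
  structure(list(source_id = cx$source_id, ligand_code = cx$ligand_code,
                 scheme = scheme, helices = helices,
                 pocket_keys = pocket, dropped_pocket_keys = dropped),
            class = "complex_profile")
}

#' @export
print.complex_profile <- function(x, ...) {
  cat(render_profile(x), sep = "\n")
  invisible(x)
}

#' Human-readable rendering of a complex profile
#'
#' One digit line per helix (`TM<k> <digits>`) followed by a legend naming
#' each flagged (binding-site) residue and its symbol.
#'
#' @param p a [build_profile()] result.
#' @return character vector of lines.
#' @export
render_profile <- function(p) {
  stopifnot(inherits(p, "complex_profile"))
  off <- p$scheme$flag_offset
  lines <- c(sprintf("# %s | ligand %s | scheme %s", p$source_id,
                     p$ligand_code, p$scheme$name))
  legend <- character()
  for (h in p$helices) {
    lines <- c(lines, sprintf("TM%d %s", h$helix_index,
                              paste(h$symbols, collapse = "")))
    fl <- which(h$symbols >= off)
    if (length(fl))
      legend <- c(legend, sprintf("  TM%d %s->%d", h$helix_index,
                                  h$keys[fl], h$symbols[fl]))
  }
  if (length(legend)) c(lines, "legend:", legend)
  else c(lines, "legend: no binding-site residues")
}

#' Parse digit strings back out of a rendered profile
#'
#' Inverse of the digit-line part of [render_profile()]; used for
#' round-trip checks and for reading profiles saved as text.
#'
#' @param lines character vector as produced by [render_profile()].
#' @return list of 7 integer vectors, one per helix.
#' @export
parse_profile_digits <- function(lines) {
  dl <- grep("^TM[1-7] [0-9]*$", lines, value = TRUE)
  if (length(dl) != 7) stop("expected 7 'TM<k> <digits>' lines, got ",
                            length(dl))
  idx <- as.integer(sub("^TM([1-7]) .*$", "\\1", dl))
  digs <- sub("^TM[1-7] ", "", dl)
  out <- vector("list", 7)
  for (i in seq_along(idx))
    out[[idx[i]]] <- as.integer(strsplit(digs[i], "")[[1]])
  out
}

#' Export a profile as JSON
#'
#' @param p a [build_profile()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(p, path) {
  stopifnot(inherits(p, "complex_profile"))
  doc <- list(
    source_id = p$source_id, ligand_code = p$ligand_code,
    scheme = p$scheme$name,
    digits = setNames(lapply(p$helices, function(h)
      paste(h$symbols, collapse = "")),
      paste0("TM", vapply(p$helices, `[[`, 1L, "helix_index"))),
    residues = setNames(lapply(p$helices, `[[`, "keys"),
                        paste0("TM", vapply(p$helices, `[[`, 1L,
                                            "helix_index"))),
    pocket = p$pocket_keys,
    dropped_pocket = p$dropped_pocket_keys)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
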