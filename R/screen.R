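# All-vs-all screening: profile a set of complexes once, align every
# ordered pair, filter by the normalized-score threshold and rank hits.

#' Profile one structure file end to end
#'
#' Convenience wrapper: read the complex, obtain the helix annotation
#' (user file or dihedral detection), detect the binding site and build
#' the profile.
#'
#' @param path structure file (PDB/mmCIF).
#' @param scheme a [profile_scheme()].
#' @param annotation path to a helix annotation file, or `NULL` to detect
#'   helices from backbone dihedrals.
#' @param cutoff binding-site distance cutoff in Angstrom (default 4.0).
#' @param ligand_code,chain_id,residue_range passed to [read_complex()].
#' @param source_id identifier recorded in outputs.
#' @return a [build_profile()] result.
#' @export
profile_structure <- function(path, scheme, annotation = NULL, cutoff = 4.0,
                              ligand_code = NULL, chain_id = NULL,
                              residue_range = NULL, source_id = NULL) {
  cx <- read_complex(path, ligand_code = ligand_code, chain_id = chain_id,
                     residue_range = residue_range, source_id = source_id)
  ann <- if (is.null(annotation)) detect_helices(cx)
  else read_helix_annotation(annotation, cx)
  pocket <- find_binding_site(cx, binding_site_spec(cutoff = cutoff))
  build_profile(cx, ann, pocket, scheme)
}

#' Read a screening manifest
#'
#' TSV with header columns `id`, `path`, `ligand_code`, `receptor_label`,
#' `annotation_path`; empty or `NA` `ligand_code`/`annotation_path` mean
#' auto-detection. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest TSV.
#' @return data frame of manifest rows.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  mf <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "path", "ligand_code", "receptor_label", "annotation_path")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(mf$id) | mf$id == "" | is.na(mf$path) | mf$path == "")
  if (length(bad))
    stop("malformed manifest row(s) ", paste(bad + 1, collapse = ", "),
         " (counting the header as line 1): id and path are required")
  if (anyDuplicated(mf$id)) stop("duplicate ids in manifest")
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | p == "", NA,
                            ifelse(grepl("^/", p), p, file.path(base, p)))
  mf$path <- fix(mf$path)
  mf$annotation_path <- fix(mf$annotation_path)
  mf$ligand_code[mf$ligand_code %in% c("", "auto")] <- NA
  mf
}

#' All-vs-all profile screening
#'
#' Profiles every complex once, computes the directed normalized-score
#' matrix over all ordered pairs (reference self-scores are computed once
#' per complex and cached) and collects the hits at or above the
#' threshold.
#'
#' @param manifest a data frame as returned by [read_manifest()] (or a
#'   path to a manifest TSV).
#' @param scheme a [profile_scheme()].
#' @param model a `substitution_model` for that scheme.
#' @param threshold normalized-score hit threshold, must be positive
#'   (default 0.5).
#' @param scope `"helix"` or `"pocket"` alignment scope.
#' @param cutoff binding-site cutoff in Angstrom.
#' @param on_error `"stop"` (default) or `"skip"`: skip logs a warning for
#'   a complex that fails to load/profile and drops it from the screen.
#' @return object of class `screen_table`: `ids`, `N_matrix` (rows =
#'   target, columns = reference, unit diagonal), `hits` (target,
#'   reference, N; sorted by descending N, ties by target then reference
#'   id), `labels`, `config`, `n_skipped`.
#' @export
run_screen <- function(manifest, scheme, model, threshold = 0.5,
                       scope = c("helix", "pocket"), cutoff = 4.0,
                       on_error = c("stop", "skip")) {
  scope <- match.arg(scope)
  on_error <- match.arg(on_error)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive")
  profiles <- list()
  skipped <- character()
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    p <- tryCatch(
      profile_structure(row$path, scheme,
                        annotation = if (is.na(row$annotation_path)) NULL
                        else row$annotation_path,
                        cutoff = cutoff,
                        ligand_code = if (is.na(row$ligand_code)) NULL
                        else row$ligand_code,
                        source_id = row$id),
      error = function(e) e)
    if (inherits(p, "error")) {
      if (on_error == "stop") stop("complex '", row$id, "' failed: ",
                                   conditionMessage(p))
      warning("skipping complex '", row$id, "': ", conditionMessage(p))
      skipped <- c(skipped, row$id)
    } else profiles[[row$id]] <- p
  }
  ids <- names(profiles)
  if (length(ids) < 2)
    stop("need at least 2 usable complexes, have ", length(ids))
  # one self-alignment per complex, reused as the R denominator
  self_totals <- vapply(ids, function(i)
    sum(vapply(1:7, function(k)
      align_helix(profiles[[i]]$helices[[k]], profiles[[i]]$helices[[k]],
                  model, scheme = scheme, scope = scope)$score, 0)), 0)
  Nm <- matrix(NA_real_, length(ids), length(ids),
               dimnames = list(target = ids, reference = ids))
  for (t in ids) for (r in ids) {
    Nm[t, r] <- if (t == r) 1.0
    else align_complexes(profiles[[t]], profiles[[r]], model, scope = scope,
                         ref_self = self_totals[[r]])$normalized
  }
  off <- which(row(Nm) != col(Nm) & Nm >= threshold, arr.ind = TRUE)
  hits <- data.frame(target = ids[off[, 1]], reference = ids[off[, 2]],
                     N = Nm[off], stringsAsFactors = FALSE)
  hits <- hits[order(-hits$N, hits$target, hits$reference), , drop = FALSE]
  rownames(hits) <- NULL
  labels <- stats::setNames(manifest$receptor_label, manifest$id)[ids]
  structure(list(ids = ids, N_matrix = Nm, hits = hits, labels = labels,
                 config = list(scheme = scheme$name,
                               mode = model$params$mode,
                               miss = model$params$miss,
                               gap = model$params$gap,
                               flag_policy = model$params$flag_policy,
                               aggregate = model$params$aggregate,
                               scope = scope, threshold = threshold,
                               cutoff = cutoff),
                 n_skipped = length(skipped), skipped = skipped),
            class = "screen_table")
}

#' @export
print.screen_table <- function(x, ...) {
  cat("screen_table:", length(x$ids), "complexes |", nrow(x$hits),
      "hits at N >=", x$config$threshold, "\n")
  print(round(x$N_matrix, 3))
  invisible(x)
}

#' Split hits into same-receptor and cross-receptor lists
#'
#' @param table a [run_screen()] result.
#' @param receptor_labels optional named character vector mapping complex
#'   id to receptor name; defaults to the manifest labels stored in the
#'   table.
#' @return list with `same_receptor`, `cross_receptor` (hit data frames)
#'   and `fraction_cross` (share of hits involving two different
#'   receptors).
#' @export
partition_hits <- function(table, receptor_labels = NULL) {
  stopifnot(inherits(table, "screen_table"))
  if (is.null(receptor_labels)) receptor_labels <- table$labels
  miss <- setdiff(unique(c(table$hits$target, table$hits$reference)),
                  names(receptor_labels))
  if (length(miss) || anyNA(receptor_labels[c(table$hits$target,
                                              table$hits$reference)]))
    stop("missing receptor label for: ",
         paste(unique(c(miss,
                        table$hits$target[is.na(
                          receptor_labels[table$hits$target])],
                        table$hits$reference[is.na(
                          receptor_labels[table$hits$reference])])),
               collapse = ", "))
  same <- receptor_labels[table$hits$target] ==
    receptor_labels[table$hits$reference]
  list(same_receptor = table$hits[same, , drop = FALSE],
       cross_receptor = table$hits[!same, , drop = FALSE],
       fraction_cross = if (nrow(table$hits)) mean(!same) else NA_real_)
}

#' Write screen outputs
#'
#' Writes `score_matrix.tsv` (directed N matrix), `hits.tsv` and
#' `run_metadata.json` (config echo; the screen is deterministic given its
#' inputs and configuration) into a directory.
#'
#' @param table a [run_screen()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(table, dir) {
  stopifnot(inherits(table, "screen_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- as.data.frame(table$N_matrix)
  m <- cbind(target = rownames(m), m)
  utils::write.table(m, file.path(dir, "score_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(table$hits, file.path(dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- c(table$config,
            list(n_complexes = length(table$ids), n_hits = nrow(table$hits),
                 skipped = table$skipped,
                 tool_version = as.character(
                   utils::packageVersion("gpcrprofile")),
                 determinism = "no randomness: identical inputs and config give identical outputs"))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
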