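# Profile alignment: Smith-Waterman local dynamic programming with a
# linear gap penalty on per-helix integer strings, per-helix scores, total
# score T, reference self-score R and the normalized score N = T/R that
# ranks repurposing candidates.

#' Local alignment of two symbol strings
#'
#' Smith-Waterman dynamic program with substitution table `model$table`
#' and linear gap penalty `model$params$gap`:
#' `H(i,j) = max(0, H(i-1,j-1)+s(a_i,b_j), H(i-1,j)+gap, H(i,j-1)+gap)`.
#' The score is the maximum over the table; the traceback starts from the
#' maximal cell (ties: smallest row, then smallest column) and prefers
#' diagonal over up over left, so outputs are bit-stable across runs. A
#' zero score yields an empty alignment.
#'
#' @param a,b integer vectors of symbols in `0 .. nrow(model$table)-1`.
#' @param model a `substitution_model`.
#' @return list with `score`, `aligned_a`, `aligned_b` (gapped symbol
#'   vectors, `NA` = gap), and 1-based inclusive `a_start`, `a_end`,
#'   `b_start`, `b_end` offsets (0 when empty).
#' @export
align_symbols <- function(a, b, model) {
  stopifnot(inherits(model, "substitution_model"))
  tab <- model$table
  na_ <- nrow(tab)
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) && (min(a) < 0 || max(a) >= na_))
    stop("symbol out of alphabet in first string")
  if (length(b) && (min(b) < 0 || max(b) >= na_))
    stop("symbol out of alphabet in second string")
  gap <- model$params$gap
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  if (n && m) {
    for (i in seq_len(n)) {
      srow <- tab[a[i] + 1, b + 1]
      for (j in seq_len(m)) {
        H[i + 1, j + 1] <- max(0, H[i, j] + srow[j],
                               H[i, j + 1] + gap, H[i + 1, j] + gap)
      }
    }
  }
  best <- max(H)
  if (best <= 0)
    return(list(score = 0, aligned_a = integer(), aligned_b = integer(),
                a_start = 0L, a_end = 0L, b_start = 0L, b_end = 0L))
  hits <- which(H == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- unname(hits[1, 1]); j <- unname(hits[1, 2])
  a_end <- i - 1L; b_end <- j - 1L
  ra <- integer(); rb <- integer()
  while (H[i, j] > 0) {
    if (i > 1 && j > 1 &&
        abs(H[i, j] - (H[i - 1, j - 1] + tab[a[i - 1] + 1, b[j - 1] + 1])) <
        1e-9) {
      ra <- c(a[i - 1], ra); rb <- c(b[j - 1], rb)
      i <- i - 1L; j <- j - 1L
    } else if (i > 1 && abs(H[i, j] - (H[i - 1, j] + gap)) < 1e-9) {
      ra <- c(a[i - 1], ra); rb <- c(NA_integer_, rb)
      i <- i - 1L
    } else if (j > 1 && abs(H[i, j] - (H[i, j - 1] + gap)) < 1e-9) {
      ra <- c(NA_integer_, ra); rb <- c(b[j - 1], rb)
      j <- j - 1L
    } else {
      stop("traceback failed (inconsistent DP table)")  # nocov
    }
  }
  list(score = best, aligned_a = ra, aligned_b = rb,
       a_start = i, a_end = a_end, b_start = j, b_end = b_end)
}

# restrict a helix symbol string to its flagged (binding-site) positions
.scope_symbols <- function(h, scheme, scope) {
  if (scope == "helix") return(h$symbols)
  h$symbols[h$symbols >= scheme$flag_offset]
}

#' Align one helix of two profiles
#'
#' @param a,b helix entries of two [build_profile()] results with the same
#'   helix index.
#' @param model a `substitution_model`.
#' @param scheme the shared [profile_scheme()] (needed for pocket scope).
#' @param scope `"helix"` aligns the full helix strings, `"pocket"` only
#'   the flagged (binding-site) positions.
#' @return an [align_symbols()] result plus `helix_index`.
#' @export
align_helix <- function(a, b, model, scheme = NULL,
                        scope = c("helix", "pocket")) {
  scope <- match.arg(scope)
  if (a$helix_index != b$helix_index)
    stop("helix indices differ (", a$helix_index, " vs ", b$helix_index,
         "); helices are aligned only to their counterparts")
  sa <- if (scope == "pocket") .scope_symbols(a, scheme, scope) else a$symbols
  sb <- if (scope == "pocket") .scope_symbols(b, scheme, scope) else b$symbols
  out <- align_symbols(sa, sb, model)
  out$helix_index <- a$helix_index
  out
}

#' Align two complex profiles and normalize
#'
#' Aligns each of the seven helices of `target` against the corresponding
#' helix of `reference`, sums the per-helix local scores into the total T,
#' computes the reference self-alignment total R the same way, and reports
#' the normalized score N = T/R. N close to or above 0.5 flags the two
#' ligands as mutual repurposing candidates.
#'
#' @param target,reference [build_profile()] results under the same scheme.
#' @param model a `substitution_model`.
#' @param scope `"helix"` (full helix strings, default) or `"pocket"`
#'   (binding-site positions only).
#' @param ref_self optional precomputed reference self-total R (cached by
#'   the screening driver).
#' @return object of class `alignment_summary`: `target_id`,
#'   `reference_id`, `per_helix` (7 alignments), `total` (T), `ref_self`
#'   (R), `normalized` (N), `scope`.
#' @export
align_complexes <- function(target, reference, model,
                            scope = c("helix", "pocket"), ref_self = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(target, "complex_profile"),
            inherits(reference, "complex_profile"))
  if (target$scheme$name != reference$scheme$name)
    stop("profiles use different schemes (", target$scheme$name, " vs ",
         reference$scheme$name, ")")
  if (model$scheme_name != target$scheme$name)
    stop("substitution model is for scheme ", model$scheme_name,
         ", profiles for ", target$scheme$name)
  per_helix <- lapply(1:7, function(k)
    align_helix(target$helices[[k]], reference$helices[[k]], model,
                scheme = target$scheme, scope = scope))
  total <- sum(vapply(per_helix, `[[`, 0, "score"))
  if (is.null(ref_self))
    ref_self <- sum(vapply(1:7, function(k)
      align_helix(reference$helices[[k]], reference$helices[[k]], model,
                  scheme = reference$scheme, scope = scope)$score, 0))
  if (ref_self <= 0)
    stop("degenerate reference: self-alignment total R = ", ref_self,
         "; normalized score undefined")
  structure(list(target_id = target$source_id,
                 reference_id = reference$source_id,
                 per_helix = per_helix, total = total, ref_self = ref_self,
                 normalized = total / ref_self, scope = scope),
            class = "alignment_summary")
}

#' Normalized scores in both orientations
#'
#' @param p1,p2 [build_profile()] results under the same scheme.
#' @inheritParams align_complexes
#' @return named numeric vector `c(N_1_as_target, N_2_as_target)`; the two
#'   values generally differ because the self-score denominator changes
#'   with the reference.
#' @export
score_pair_bidirectional <- function(p1, p2, model,
                                     scope = c("helix", "pocket")) {
  scope <- match.arg(scope)
  f <- align_complexes(p1, p2, model, scope = scope)
  r <- align_complexes(p2, p1, model, scope = scope)
  stats::setNames(c(f$normalized, r$normalized),
                  c(p1$source_id, p2$source_id))
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat("alignment:", x$target_id, "(target) vs", x$reference_id,
      "(reference), scope", x$scope, "\n")
  for (h in x$per_helix)
    cat(sprintf("  TM%d score %.3f\n", h$helix_index, h$score))
  cat(sprintf("  total T = %.3f, reference self R = %.3f\n",
              x$total, x$ref_self))
  cat(sprintf("  normalized N = T/R = %.2f\n", x$normalized))
  invisible(x)
}

#' Export an alignment summary as JSON
#'
#' @param x an `alignment_summary`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_json <- function(x, path) {
  stopifnot(inherits(x, "alignment_summary"))
  doc <- list(
    target = x$target_id, reference = x$reference_id, scope = x$scope,
    per_helix = lapply(x$per_helix, function(h) list(
      helix = h$helix_index, score = h$score,
      aligned_target = paste(ifelse(is.na(h$aligned_a), "-", h$aligned_a),
                             collapse = ""),
      aligned_reference = paste(ifelse(is.na(h$aligned_b), "-",
                                       h$aligned_b), collapse = ""))),
    total = x$total, reference_self = x$ref_self,
    normalized = x$normalized)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
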