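# Substitution scoring over the flagged profile alphabets. Group-level
# scores are derived from a 20x20 residue matrix (BLOSUM62 from Biostrings,
# a residue-level matrix read from file, or a custom group matrix) by
# aggregating over all residue pairs of the two groups, then expanded to
# the flagged 8- or 10-symbol alphabet.

#' Scoring parameters
#'
#' @param mode `"blosum62"`, `"gpcrtm"` (residue-level matrix read from a
#'   file, reduced like BLOSUM62), `"identity"` or `"custom"` (group-level
#'   matrix read from a file).
#' @param miss mismatch penalty, must be non-positive (default -2).
#' @param gap linear gap penalty, must be non-positive (default -2).
#' @param flag_policy how a flagged symbol scores against an unflagged one:
#'   `"penalize"` (group score plus `miss`; default), `"miss_only"` (always
#'   `miss`), `"ignore"` (group score, flags invisible).
#' @param match identity-mode self score, must be positive (default 1).
#' @param aggregate group-reduction aggregator over residue pairs:
#'   `"mean"` (default), `"median"` or `"min"`.
#' @return object of class `scoring_params`.
#' @export
scoring_params <- function(mode = c("blosum62", "gpcrtm", "identity",
                                    "custom"),
                           miss = -2, gap = -2,
                           flag_policy = c("penalize", "miss_only", "ignore"),
                           match = 1,
                           aggregate = c("mean", "median", "min")) {
  mode <- match.arg(mode)
  flag_policy <- match.arg(flag_policy)
  aggregate <- match.arg(aggregate)
  if (!is.numeric(miss) || miss > 0)
    stop("miss must be filled with a non-positive value")
  if (!is.numeric(gap) || gap > 0)
    stop("gap must be filled with a non-positive value")
  if (mode == "identity" && (!is.numeric(match) || match <= 0))
    stop("identity match score must be positive")
  structure(list(mode = mode, miss = miss, gap = gap,
                 flag_policy = flag_policy, match = match,
                 aggregate = aggregate),
            class = "scoring_params")
}

#' The canonical BLOSUM62 residue matrix
#'
#' @return 20x20 symmetric integer matrix over the standard residues
#'   (1-letter row/column names), taken from Biostrings.
#' @export
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- names(.default_groups_8)
  m <- e$BLOSUM62[aa, aa]
  storage.mode(m) <- "double"
  m
}

#' Reduce a residue-level matrix to group level
#'
#' Entry (g, h) aggregates the residue-level scores over all ordered
#' residue pairs (a in g, b in h); the default aggregator is the unweighted
#' arithmetic mean, kept as a real number without rounding.
#'
#' @param full symmetric numeric matrix with 1-letter residue row/column
#'   names covering the 20 standard residues.
#' @param scheme a [profile_scheme()].
#' @param aggregate `"mean"`, `"median"` or `"min"`.
#' @return symmetric `n_groups x n_groups` numeric matrix with group-name
#'   dimnames.
#' @export
reduce_matrix <- function(full, scheme, aggregate = c("mean", "median",
                                                      "min")) {
  stopifnot(inherits(scheme, "profile_scheme"))
  aggregate <- match.arg(aggregate)
  aa <- names(scheme$groups)
  missing_aa <- setdiff(aa, rownames(full))
  if (length(missing_aa))
    stop("residue(s) missing from the matrix: ",
         paste(missing_aa, collapse = ", "))
  full <- full[aa, aa]
  if (max(abs(full - t(full))) > 1e-9)
    stop("residue matrix is not symmetric")
  f <- switch(aggregate, mean = mean, median = stats::median, min = min)
  ng <- scheme$n_groups
  gm <- matrix(NA_real_, ng, ng,
               dimnames = list(scheme$group_names, scheme$group_names))
  for (g in 0:(ng - 1)) for (h in 0:(ng - 1)) {
    ra <- aa[scheme$groups == g]
    rb <- aa[scheme$groups == h]
    gm[g + 1, h + 1] <- f(full[ra, rb, drop = FALSE])
  }
  (gm + t(gm)) / 2  # numerically symmetrize (exact for mean/median)
}

#' Expand a group matrix to the flagged alphabet
#'
#' Symbols `0 .. n_groups-1` are unflagged, `n_groups .. 2*n_groups-1`
#' flagged. Same-flag pairs score the group entry; mixed-flag pairs score
#' according to `flag_policy` (see [scoring_params()]).
#'
#' @param group_matrix `n_groups x n_groups` symmetric matrix.
#' @param params a [scoring_params()].
#' @param scheme a [profile_scheme()].
#' @return object of class `substitution_model`: `scheme_name`, `table`
#'   (flagged-alphabet matrix with digit dimnames), `params`.
#' @export
expand_to_flagged <- function(group_matrix, params, scheme) {
  stopifnot(inherits(params, "scoring_params"),
            inherits(scheme, "profile_scheme"))
  ng <- scheme$n_groups
  stopifnot(nrow(group_matrix) == ng, ncol(group_matrix) == ng)
  na <- 2L * ng
  tab <- matrix(NA_real_, na, na,
                dimnames = list(0:(na - 1), 0:(na - 1)))
  for (x in 0:(na - 1)) for (y in 0:(na - 1)) {
    gx <- x %% ng; gy <- y %% ng
    fx <- x >= ng; fy <- y >= ng
    base <- group_matrix[gx + 1, gy + 1]
    tab[x + 1, y + 1] <- if (fx == fy) base
    else switch(params$flag_policy,
                penalize = base + params$miss,
                miss_only = params$miss,
                ignore = base)
  }
  structure(list(scheme_name = scheme$name, table = tab, params = params),
            class = "substitution_model")
}

#' Identity substitution model
#'
#' `s(x, x) = match`, `s(x, y != x) = miss`, over the full flagged
#' alphabet.
#'
#' @param params a [scoring_params()] with `mode = "identity"`.
#' @param scheme a [profile_scheme()].
#' @return a `substitution_model`.
#' @export
identity_model <- function(params, scheme) {
  stopifnot(inherits(params, "scoring_params"),
            inherits(scheme, "profile_scheme"))
  if (params$match <= 0) stop("identity match score must be positive")
  na <- 2L * scheme$n_groups
  tab <- matrix(params$miss, na, na,
                dimnames = list(0:(na - 1), 0:(na - 1)))
  diag(tab) <- params$match
  structure(list(scheme_name = scheme$name, table = tab, params = params),
            class = "substitution_model")
}

#' Load a labeled square matrix from a file
#'
#' Whitespace-separated, PAM/BLOSUM-style layout: a header row of labels,
#' then one labeled row per line; `#` starts a comment. Used both for
#' custom group-level matrices (labels = group names or digit symbols) and
#' for residue-level matrices (labels = 1-letter codes).
#'
#' @param path matrix file.
#' @param expect_labels optional character vector the labels must equal
#'   (order-insensitive).
#' @return symmetric numeric matrix with the file's labels as dimnames.
#' @export
load_custom_matrix <- function(path, expect_labels = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^[[:space:]]*#", ln)]
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) < 2) stop("malformed matrix file: ", path)
  header <- strsplit(trimws(ln[1]), "[[:space:]]+")[[1]]
  nlab <- length(header)
  if (length(ln) - 1 != nlab)
    stop("matrix dimension error in '", path, "': ", nlab,
         " column labels but ", length(ln) - 1, " data rows")
  m <- matrix(NA_real_, nlab, nlab, dimnames = list(header, header))
  for (i in seq_len(nlab)) {
    p <- strsplit(trimws(ln[i + 1]), "[[:space:]]+")[[1]]
    if (length(p) != nlab + 1)
      stop("matrix row '", p[1], "' has ", length(p) - 1, " values, expected ",
           nlab)
    if (p[1] != header[i])
      stop("row label '", p[1], "' does not match column label '",
           header[i], "'")
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v)) stop("non-numeric entry in row '", p[1], "'")
    m[i, ] <- v
  }
  asym <- abs(m - t(m))
  if (max(asym) > 1e-9) {
    ij <- which(asym == max(asym), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    stop("matrix is asymmetric at cell (", rownames(m)[ij[1]], ", ",
         colnames(m)[ij[2]], ")")
  }
  if (!is.null(expect_labels) && !setequal(rownames(m), expect_labels))
    stop("matrix labels {", paste(rownames(m), collapse = ","),
         "} do not match expected {", paste(expect_labels, collapse = ","),
         "}")
  m
}

#' Build a substitution model for a scheme
#'
#' One-stop constructor dispatching on the scoring mode: reduces BLOSUM62
#' (or a residue-level matrix file, e.g. a transmembrane-specific matrix
#' for `mode = "gpcrtm"`) to group level and expands it to the flagged
#' alphabet, builds the identity model, or expands a custom group matrix.
#'
#' @param scheme a [profile_scheme()].
#' @param params a [scoring_params()].
#' @param matrix_file required for modes `"gpcrtm"` (20x20 residue-level
#'   matrix, 1-letter labels) and `"custom"` (group-level matrix labeled
#'   with the scheme's group names).
#' @return a `substitution_model`.
#' @export
substitution_model <- function(scheme, params = scoring_params(),
                               matrix_file = NULL) {
  stopifnot(inherits(scheme, "profile_scheme"),
            inherits(params, "scoring_params"))
  if (params$mode == "identity") return(identity_model(params, scheme))
  gm <- switch(params$mode,
    blosum62 = reduce_matrix(blosum62_matrix(), scheme, params$aggregate),
    gpcrtm = {
      if (is.null(matrix_file))
        stop("mode 'gpcrtm' needs a residue-level matrix file ",
             "(matrix_file); no transmembrane substitution matrix is ",
             "bundled with the package")
      m <- load_custom_matrix(matrix_file,
                              expect_labels = names(scheme$groups))
      reduce_matrix(m, scheme, params$aggregate)
    },
    custom = {
      if (is.null(matrix_file))
        stop("mode 'custom' needs a group-level matrix file (matrix_file)")
      m <- load_custom_matrix(matrix_file,
                              expect_labels = scheme$group_names)
      m[scheme$group_names, scheme$group_names]
    })
  expand_to_flagged(gm, params, scheme)
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("substitution_model:", x$params$mode, "for", x$scheme_name,
      "| miss", x$params$miss, "gap", x$params$gap,
      "| flag policy", x$params$flag_policy, "\n")
  print(round(x$table, 3))
  invisible(x)
}
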