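# Shared fixtures: generated once per test run and cached on disk under a
# session temp directory. All fixtures are built in code; nothing binary is
# stored in the repository.

.fx_cache <- new.env(parent = emptyenv())

# default bundle fixture written to disk, with annotation file
cached_fixture <- function(name = "default", spec = fixture_spec()) {
  if (!is.null(.fx_cache[[name]])) return(.fx_cache[[name]])
  fx <- make_complex(spec)
  pdb <- file.path(tempdir(), paste0("fx_", name, ".pdb"))
  ann <- file.path(tempdir(), paste0("fx_", name, "_helices.txt"))
  write_fixture(fx, pdb, annotation_path = ann)
  out <- list(fx = fx, pdb = pdb, ann = ann)
  .fx_cache[[name]] <- out
  out
}

cached_complex <- function(name = "default", spec = fixture_spec()) {
  key <- paste0("cx_", name)
  if (!is.null(.fx_cache[[key]])) return(.fx_cache[[key]])
  f <- cached_fixture(name, spec)
  cx <- read_complex(f$pdb)
  .fx_cache[[key]] <- cx
  cx
}

# brute-force binding-site oracle: O(residues x atoms x ligand atoms)
# double loop, independent of find_binding_site()
brute_force_site <- function(cx, cutoff = 4.0) {
  keys <- character()
  la <- cx$ligand_atoms[!cx$ligand_atoms$hydrogen, , drop = FALSE]
  for (key in cx$residues$key) {
    at <- cx$atoms[cx$atoms$key == key & !cx$atoms$hydrogen, , drop = FALSE]
    hit <- FALSE
    for (i in seq_len(nrow(at))) {
      for (j in seq_len(nrow(la))) {
        d <- sqrt((at$x[i] - la$x[j])^2 + (at$y[i] - la$y[j])^2 +
                    (at$z[i] - la$z[j])^2)
        if (d <= cutoff) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) keys <- c(keys, key)
  }
  keys
}

# independent local-alignment oracle: best global (Needleman-Wunsch style,
# no zero clamping) alignment score over all pairs of contiguous
# substrings; the empty-empty pair contributes 0
brute_force_local <- function(a, b, tab, gap) {
  nw <- function(x, y) {
    n <- length(x); m <- length(y)
    G <- matrix(0, n + 1, m + 1)
    if (n) G[-1, 1] <- gap * seq_len(n)
    if (m) G[1, -1] <- gap * seq_len(m)
    for (i in seq_len(n)) for (j in seq_len(m))
      G[i + 1, j + 1] <- max(G[i, j] + tab[x[i] + 1, y[j] + 1],
                             G[i, j + 1] + gap, G[i + 1, j] + gap)
    G[n + 1, m + 1]
  }
  best <- 0
  n <- length(a); m <- length(b)
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      s <- nw(a[i1:i2], b[j1:j2])
      if (s > best) best <- s
    }
  }
  best
}

# random symmetric substitution model over a flagged alphabet, for
# property tests
random_model <- function(scheme, seed) {
  set.seed(seed)
  na <- 2L * scheme$n_groups
  m <- matrix(sample(-3:3, na * na, replace = TRUE), na, na)
  m <- (m + t(m)) / 2
  diag(m) <- abs(diag(m)) + 1  # positive self scores
  dimnames(m) <- list(0:(na - 1), 0:(na - 1))
  params <- scoring_params("custom", miss = -2,
                           gap = sample(c(-1, -2, -3), 1))
  structure(list(scheme_name = scheme$name, table = m, params = params),
            class = "substitution_model")
}

# substitution of a residue string with a same-group partner at given
# 1-based positions (sequence surgery for engineered pockets)
force_residues <- function(sequences, helix, position, code) {
  for (i in seq_along(helix)) {
    s <- strsplit(sequences[helix[i]], "")[[1]]
    s[position[i]] <- code
    sequences[helix[i]] <- paste(s, collapse = "")
  }
  sequences
}

path_standin_matrix <- function() {
  system.file("extdata", "matrices", "gpcrtm_synthetic_standin.mat",
              package = "gpcrprofile")
}

# group-level custom matrix file written on the fly
write_custom_group_matrix <- function(scheme, values = NULL) {
  ng <- scheme$n_groups
  if (is.null(values)) {
    values <- reduce_matrix(blosum62_matrix(), scheme)
  }
  path <- tempfile(fileext = ".mat")
  lines <- c(paste(" ", paste(scheme$group_names, collapse = " ")),
             vapply(seq_len(ng), function(i)
               paste(scheme$group_names[i],
                     paste(sprintf("%.12f", values[i, ]), collapse = " ")),
               ""))
  writeLines(lines, path)
  path
}
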