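# Local alignment dynamic program, totals and normalization.

toy_profile <- function(id, symbol_lists, scheme) {
  structure(list(
    source_id = id, ligand_code = "LIG", scheme = scheme,
    helices = lapply(1:7, function(k) list(
      helix_index = k, symbols = symbol_lists[[k]],
      keys = paste0("A:", seq_along(symbol_lists[[k]])))),
    pocket_keys = character(), dropped_pocket_keys = character()),
    class = "complex_profile")
}

id_model <- function(scheme = profile_scheme("8DP"), match = 1, miss = -2,
                     gap = -2) {
  identity_model(scoring_params("identity", match = match, miss = miss,
                                gap = gap), scheme)
}

test_that("elementary local alignments score as expected", {
  m <- id_model()
  one <- align_symbols(4L, 4L, m)
  expect_equal(one$score, 1)
  expect_equal(one$aligned_a, 4L)
  s <- align_symbols(c(6L, 0L, 3L, 7L), c(6L, 0L, 3L, 7L), m)
  expect_equal(s$score, 4)
  expect_equal(s$aligned_a, c(6L, 0L, 3L, 7L))
  # all-mismatch pair gives the empty alignment, never a negative score
  z <- align_symbols(c(0L, 0L), c(1L, 1L), m)
  expect_equal(z$score, 0)
  expect_length(z$aligned_a, 0)
  expect_error(align_symbols(c(0L, 99L), 1L, m), "out of alphabet")
})

test_that("the DP equals the exhaustive substring-pair oracle on random inputs", {
  set.seed(202)
  s8 <- profile_scheme("8DP")
  for (case in 1:80) {
    model <- random_model(s8, seed = 7000 + case)
    na <- nrow(model$table)
    la <- sample(0:7, 1); lb <- sample(0:7, 1)
    a <- if (la) sample(0:(na - 1), la, replace = TRUE) else integer()
    b <- if (lb) sample(0:(na - 1), lb, replace = TRUE) else integer()
    got <- align_symbols(a, b, model)$score
    want <- brute_force_local(a, b, model$table, model$params$gap)
    expect_equal(got, want,
                 info = sprintf("case %d: a=%s b=%s gap=%s", case,
                                paste(a, collapse = ""),
                                paste(b, collapse = ""),
                                model$params$gap))
  }
})

test_that("re-scoring the traceback reproduces the DP score", {
  set.seed(99)
  s8 <- profile_scheme("8DP")
  for (case in 1:40) {
    model <- random_model(s8, seed = 300 + case)
    na <- nrow(model$table)
    a <- sample(0:(na - 1), sample(1:12, 1), replace = TRUE)
    b <- sample(0:(na - 1), sample(1:12, 1), replace = TRUE)
    al <- align_symbols(a, b, model)
    if (al$score == 0) next
    rescore <- 0
    for (i in seq_along(al$aligned_a)) {
      x <- al$aligned_a[i]; y <- al$aligned_b[i]
      rescore <- rescore + if (is.na(x) || is.na(y)) model$params$gap
      else model$table[x + 1, y + 1]
    }
    expect_equal(rescore, al$score)
    # alignment occupies the reported windows
    expect_equal(sum(!is.na(al$aligned_a)), al$a_end - al$a_start + 1)
    expect_equal(sum(!is.na(al$aligned_b)), al$b_end - al$b_start + 1)
  }
})

test_that("scores are symmetric under input swap and monotone in the gap penalty", {
  set.seed(17)
  s10 <- profile_scheme("10DP")
  g <- reduce_matrix(blosum62_matrix(), s10)
  for (case in 1:25) {
    a <- sample(0:9, sample(3:15, 1), replace = TRUE)
    b <- sample(0:9, sample(3:15, 1), replace = TRUE)
    prev <- Inf
    for (gp in c(-1, -2, -4)) {
      m <- expand_to_flagged(g, scoring_params("blosum62", gap = gp), s10)
      s_ab <- align_symbols(a, b, m)$score
      s_ba <- align_symbols(b, a, m)$score
      expect_equal(s_ab, s_ba)
      expect_true(s_ab >= 0)
      expect_true(s_ab <= prev)
      prev <- s_ab
    }
  }
})

test_that("self-alignment normalizes to exactly 1 and degenerate references error", {
  f <- cached_fixture()
  pr <- build_profile(cached_complex(), read_helix_annotation(f$ann),
                      find_binding_site(cached_complex()),
                      profile_scheme("8DP"))
  s8 <- profile_scheme("8DP")
  model <- substitution_model(s8, scoring_params("blosum62"))
  out <- align_complexes(pr, pr, model)
  expect_equal(out$normalized, 1.0)
  expect_equal(out$total, out$ref_self)
  expect_equal(sum(vapply(out$per_helix, `[[`, 0, "score")), out$total)

  # empty-pocket reference still self-normalizes to 1
  pr0 <- build_profile(cached_complex(), read_helix_annotation(f$ann),
                       character(), s8)
  expect_equal(align_complexes(pr0, pr0, id_model())$normalized, 1.0)

  # all-negative self scores make R = 0: explicit error, not NaN
  neg <- structure(list(scheme_name = "8DP",
                        table = matrix(-1, 8, 8,
                                       dimnames = list(0:7, 0:7)),
                        params = scoring_params("custom")),
                   class = "substitution_model")
  expect_error(align_complexes(pr, pr, neg), "degenerate reference")
})

test_that("substring targets score as the length ratio under identity scoring", {
  set.seed(5)
  s8 <- profile_scheme("8DP")
  ref_syms <- lapply(1:7, function(k) sample(0:7, 12, replace = TRUE))
  tgt_syms <- lapply(ref_syms, function(s) s[3:7])
  ref <- toy_profile("ref", ref_syms, s8)
  tgt <- toy_profile("tgt", tgt_syms, s8)
  m <- id_model(match = 2)
  out <- align_complexes(tgt, ref, m)
  expect_equal(out$total, 2 * sum(lengths(tgt_syms)))
  expect_equal(out$normalized,
               sum(lengths(tgt_syms)) / sum(lengths(ref_syms)))
})

test_that("bidirectional scoring shares T under a symmetric model but not R", {
  set.seed(31)
  s8 <- profile_scheme("8DP")
  p1 <- toy_profile("p1", lapply(1:7, function(k)
    sample(0:7, sample(6:12, 1), replace = TRUE)), s8)
  p2 <- toy_profile("p2", lapply(1:7, function(k)
    sample(0:7, sample(6:12, 1), replace = TRUE)), s8)
  model <- substitution_model(s8, scoring_params("blosum62"))
  f <- align_complexes(p1, p2, model)
  r <- align_complexes(p2, p1, model)
  expect_equal(f$total, r$total)
  both <- score_pair_bidirectional(p1, p2, model)
  expect_equal(unname(both), c(f$normalized, r$normalized))
  same <- score_pair_bidirectional(p1, p1, model)
  expect_equal(unname(same), c(1, 1))
})

test_that("cross-helix alignment and scheme mixing are refused", {
  s8 <- profile_scheme("8DP")
  p <- toy_profile("p", lapply(1:7, function(k) c(0L, 1L)), s8)
  expect_error(align_helix(p$helices[[1]], p$helices[[2]], id_model()),
               "counterpart")
  p10 <- toy_profile("q", lapply(1:7, function(k) c(0L, 1L)),
                     profile_scheme("10DP"))
  m <- substitution_model(s8, scoring_params("blosum62"))
  expect_error(align_complexes(p, p10, m), "different schemes")
})

test_that("pocket scope aligns only the flagged positions", {
  s8 <- profile_scheme("8DP")
  # helix strings share unflagged context but have different flagged cores
  a_syms <- lapply(1:7, function(k) c(0L, 1L, 6L, 4L, 2L, 3L))
  b_syms <- lapply(1:7, function(k) c(0L, 1L, 6L, 5L, 2L, 3L))
  a <- toy_profile("a", a_syms, s8)
  b <- toy_profile("b", b_syms, s8)
  m <- id_model()
  full <- align_complexes(a, b, m, scope = "helix")
  pock <- align_complexes(a, b, m, scope = "pocket")
  # pocket strings: a = (6,4), b = (6,5): only the 6 matches
  expect_equal(pock$total, 7 * 1)
  expect_equal(pock$ref_self, 7 * 2)
  expect_equal(pock$normalized, 0.5)
  expect_true(full$total > pock$total)
})
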