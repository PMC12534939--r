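# Independent oracles and small fixture builders shared across tests.

# Minimal blueprint with given charges (and optional elements); enough for
# the aligner, scoring and reinsertion machinery.
fake_blueprint <- function(charges, elements = rep("C", length(charges)),
                           id = "fake") {
  n <- length(charges)
  structure(list(
    molecule_id = id,
    canonical_smiles = paste(elements, collapse = ""),
    tokens = data.frame(symbol = elements, element = elements,
                        atom_index = seq_len(n) - 1L,
                        start = seq_len(n) - 1L, end = seq_len(n),
                        stringsAsFactors = FALSE),
    charges = charges,
    skeleton = rep("", n + 1L)),
    class = "charge_blueprint")
}

# Scoring matrix with prescribed per-bin scores (bypasses corpus building).
fake_matrix <- function(scores) {
  stopifnot(length(scores) == 30L)
  structure(list(bin_width = 0.1, bin_lower_edges = (0:29) / 10,
                 raw_scores = scores, mean_diff = NA_real_,
                 mean_bin = NA_integer_, scores = scores,
                 floor = min(scores), n_observations = NA_integer_),
            class = "scoring_matrix")
}

# Reference Levenshtein distance: classical O(nm) dynamic program, written
# independently of utils::adist.
lev_dp <- function(s1, s2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n; D[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    D[i + 1L, j + 1L] <- min(D[i, j] + (a[i] != b[j]),
                             D[i, j + 1L] + 1L, D[i + 1L, j] + 1L)
  }
  D[n + 1L, m + 1L]
}

# Brute-force survival fraction: count of differences >= edge over total,
# recomputed with an explicit loop (numeric tolerance as in the package).
brute_survival <- function(diffs, edge) {
  cnt <- 0L
  for (d in diffs) if (d >= edge - 1e-9) cnt <- cnt + 1L
  cnt / length(diffs)
}

# --- exhaustive affine-gap global alignment oracle ------------------------
#
# Enumerates every global alignment path under the move grammar of the
# M/X/Y recurrences (a gap in one sequence never directly follows a gap in
# the other, no gap-vs-gap column). Paths depend only on the shape (n, m),
# so they are cached per shape; each path is summarized by its matched
# (i, j) pairs, the number of gap runs and the total gap count, from which
# the score under any (S, g_open, g_extend) follows directly.
.path_cache <- new.env(parent = emptyenv())

enumerate_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  paths <- list()
  walk <- function(i, j, last, pairs, runs, gaps) {
    if (i == n && j == m) {
      paths[[length(paths) + 1L]] <<-
        list(pairs = pairs, runs = runs, gaps = gaps)
      return(invisible())
    }
    if (i < n && j < m)
      walk(i + 1L, j + 1L, "M", rbind(pairs, c(i + 1L, j + 1L)), runs, gaps)
    if (i < n && last != "Y")
      walk(i + 1L, j, "X", pairs, runs + (last != "X"), gaps + 1L)
    if (j < m && last != "X")
      walk(i, j + 1L, "Y", pairs, runs + (last != "Y"), gaps + 1L)
    invisible()
  }
  walk(0L, 0L, "M", matrix(integer(0), 0L, 2L), 0L, 0L)
  .path_cache[[key]] <- paths
  paths
}

# Per-path statistics for one substitution matrix: enough to score every
# enumerated alignment under any penalty pair with one vectorized max.
oracle_path_stats <- function(S, n, m) {
  paths <- enumerate_paths(n, m)
  list(subst = vapply(paths, function(p)
         if (nrow(p$pairs)) sum(S[p$pairs]) else 0, numeric(1)),
       runs = vapply(paths, `[[`, numeric(1), "runs"),
       gaps = vapply(paths, `[[`, numeric(1), "gaps"))
}

# Best alignment score over exhaustive enumeration.
oracle_align_score <- function(S, n, m, g_open, g_extend) {
  st <- oracle_path_stats(S, n, m)
  max(st$subst - st$runs * g_open - (st$gaps - st$runs) * g_extend)
}

# Column-wise rescoring of an emitted alignment with affine gap accounting;
# independent of the DP lattices.
rescore_alignment <- function(a_idx, b_idx, S, g_open, g_extend) {
  stopifnot(length(a_idx) == length(b_idx))
  total <- 0
  in_gap_a <- FALSE; in_gap_b <- FALSE
  for (k in seq_along(a_idx)) {
    if (!is.na(a_idx[k]) && !is.na(b_idx[k])) {
      total <- total + S[a_idx[k], b_idx[k]]
      in_gap_a <- in_gap_b <- FALSE
    } else if (is.na(b_idx[k])) {
      total <- total - if (in_gap_b) g_extend else g_open
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      total <- total - if (in_gap_a) g_extend else g_open
      in_gap_a <- TRUE; in_gap_b <- FALSE
    }
  }
  total
}

# Fixed scorer for alignment tests: identity-friendly synthetic matrix with
# a strong reward for near-zero charge differences.
toy_scorer <- function() fake_matrix(c(5, 3, 1, rep(-1, 9), rep(-4, 18)))
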