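# Affine-gap Needleman-Wunsch global alignment of charge blueprints.
#
# Three lattices: M (atoms aligned), X (gap in the second molecule, i.e. an
# atom of the first aligned to a gap), Y (gap in the first molecule).
# Following the recurrences
#   M(i,j) = max{M(i-1,j-1), X(i-1,j-1), Y(i-1,j-1)} + s(a_i, b_j)
#   X(i,j) = max{M(i-1,j) - g_open, X(i-1,j) - g_extend}
#   Y(i,j) = max{M(i,j-1) - g_open, Y(i,j-1) - g_extend}
#   F(i,j) = max{M(i,j), X(i,j), Y(i,j)}
# a gap in one molecule can never directly follow a gap in the other
# (there is no X <-> Y transition), and no column is ever gap-vs-gap.
# Penalties are subtracted as written, so negative values act as rewards;
# the validation sweep deliberately spans both signs.

# Finite sentinel standing in for -Inf: far beyond any reachable score
# (|scores| and |penalties| are O(10), molecule lengths O(10^2)) but safe
# under addition, keeping all lattice arithmetic total.
.NEG_SENTINEL <- -1e12

#' Affine gap penalties
#'
#' @param g_open penalty subtracted when a gap is opened.
#' @param g_extend penalty subtracted when an existing gap is lengthened.
#' @return an object of class \code{gap_penalties}.
#' @export
gap_penalties <- function(g_open, g_extend) {
  stopifnot(is.finite(g_open), is.finite(g_extend))
  structure(list(g_open = g_open, g_extend = g_extend),
            class = "gap_penalties")
}

#' Fill the affine-gap dynamic-programming lattices
#'
#' Computes the M, X and Y score lattices for two blueprints under a
#' substitution scorer and gap penalties, with standard Gotoh
#' initialization: \code{M[0,0] = 0}, first row/column of M impossible,
#' \code{X[i,0] = -g_open - (i-1) g_extend} (and symmetrically for Y).
#' Traceback pointers are recorded during the fill with the deterministic
#' tie preference M > X > Y, so repeated runs give identical alignments.
#'
#' @param blueprint_a,blueprint_b \code{charge_blueprint} objects.
#' @param scorer a \code{scoring_matrix} or \code{paired_scoring_set}.
#' @param penalties a [gap_penalties()] object.
#' @param S optional precomputed substitution matrix (rows = atoms of a,
#'   columns = atoms of b); computed from \code{scorer} when \code{NULL}.
#'   Passing it explicitly lets a parameter sweep reuse one matrix across
#'   many penalty settings.
#' @return an object of class \code{dp_state} with the three lattices, the
#'   cellwise maximum \code{F}, pointer arrays and dimensions.
#' @export
align_fill <- function(blueprint_a, blueprint_b, scorer, penalties,
                       S = NULL) {
  stopifnot(inherits(penalties, "gap_penalties"))
  n <- length(blueprint_a$charges); m <- length(blueprint_b$charges)
  if (is.null(S) && n > 0L && m > 0L)
    S <- .substitution_matrix(scorer, blueprint_a, blueprint_b)
  go <- penalties$g_open; ge <- penalties$g_extend
  NEG <- .NEG_SENTINEL
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  # pointers: 1 = from M, 2 = from X, 3 = from Y, NA = boundary
  Mp <- matrix(NA_integer_, n + 1L, m + 1L)
  Xp <- matrix(NA_integer_, n + 1L, m + 1L)
  Yp <- matrix(NA_integer_, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n > 0L) {
    X[2L:(n + 1L), 1L] <- -go - (seq_len(n) - 1L) * ge
    Xp[2L:(n + 1L), 1L] <- rep(2L, n); Xp[2L, 1L] <- 1L
  }
  if (m > 0L) {
    Y[1L, 2L:(m + 1L)] <- -go - (seq_len(m) - 1L) * ge
    Yp[1L, 2L:(m + 1L)] <- rep(3L, m); Yp[1L, 2L] <- 1L
  }
  if (n > 0L && m > 0L) {
    for (i in 2L:(n + 1L)) {
      for (j in 2L:(m + 1L)) {
        cand <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
        w <- which.max(cand)
        M[i, j] <- cand[w] + S[i - 1L, j - 1L]
        Mp[i, j] <- w
        xo <- M[i - 1L, j] - go; xe <- X[i - 1L, j] - ge
        if (xo >= xe) { X[i, j] <- xo; Xp[i, j] <- 1L }
        else { X[i, j] <- xe; Xp[i, j] <- 2L }
        yo <- M[i, j - 1L] - go; ye <- Y[i, j - 1L] - ge
        if (yo >= ye) { Y[i, j] <- yo; Yp[i, j] <- 1L }
        else { Y[i, j] <- ye; Yp[i, j] <- 3L }
      }
    }
  }
  structure(list(M = M, X = X, Y = Y, F = pmax(M, X, Y),
                 Mp = Mp, Xp = Xp, Yp = Yp, n = n, m = m, S = S,
                 penalties = penalties),
            class = "dp_state")
}

#' Trace back the optimal alignment
#'
#' Starting from the bottom-right corner, follows the recorded pointers
#' (tie preference M > X > Y) back to the origin, emitting a diagonal step
#' for each aligned pair and vertical/horizontal steps for gaps.
#'
#' @param state a filled \code{dp_state}.
#' @return list with \code{a_idx} and \code{b_idx}: integer vectors of the
#'   same length, giving for each alignment column the (1-based) atom index
#'   in each molecule, or \code{NA} for a gap.
#' @export
align_traceback <- function(state) {
  stopifnot(inherits(state, "dp_state"))
  n <- state$n; m <- state$m
  i <- n + 1L; j <- m + 1L
  if (n == 0L && m == 0L)
    return(list(a_idx = integer(0), b_idx = integer(0)))
  cand <- c(state$M[i, j], state$X[i, j], state$Y[i, j])
  layer <- which.max(cand)
  a_idx <- integer(0); b_idx <- integer(0)
  while (i > 1L || j > 1L) {
    if (layer == 1L) {
      if (i <= 1L || j <= 1L)
        stop("internal error: inconsistent DP lattice during traceback")
      a_idx <- c(i - 1L, a_idx); b_idx <- c(j - 1L, b_idx)
      layer <- state$Mp[i, j]
      i <- i - 1L; j <- j - 1L
    } else if (layer == 2L) {
      a_idx <- c(i - 1L, a_idx); b_idx <- c(NA_integer_, b_idx)
      layer <- state$Xp[i, j]
      i <- i - 1L
    } else {
      a_idx <- c(NA_integer_, a_idx); b_idx <- c(j - 1L, b_idx)
      layer <- state$Yp[i, j]
      j <- j - 1L
    }
  }
  list(a_idx = a_idx, b_idx = b_idx)
}

#' Globally align two molecules by their partial charges
#'
#' Composes blueprint computation, the affine-gap dynamic program, the
#' deterministic traceback and skeleton reinsertion. The alignment operates
#' purely on the charge blueprints (atom tokens and their charges); the
#' returned display strings have the stripped SMILES characters put back
#' with gaps rendered as \code{gap_symbol}.
#'
#' @param smiles_a,smiles_b the two molecules (SMILES strings or
#'   precomputed \code{charge_blueprint} objects). An empty string aligns
#'   as an empty blueprint, yielding an all-gap alignment.
#' @param scorer a \code{scoring_matrix} (all-vs-all mode) or
#'   \code{paired_scoring_set} (paired mode).
#' @param penalties a [gap_penalties()] object.
#' @param gap_symbol character used when rendering gaps.
#' @param charge_provider passed to [compute_blueprint()].
#' @return an object of class \code{mol_alignment}: list with
#'   \code{aligned_a}/\code{aligned_b} (token symbols with \code{NA} gaps),
#'   \code{score}, \code{aligned_smiles_a}/\code{aligned_smiles_b}
#'   (reinserted display strings), \code{mode}, \code{penalties} and the
#'   two blueprints.
#' @examples
#' \dontrun{
#' corpus <- builtin_corpus("demo")
#' bps <- compute_blueprints(corpus$smiles, corpus$id)
#' mat <- build_all_vs_all(bps)
#' align_molecules("OC(=O)CCC(=O)O", "OC(=O)C=CC(=O)O", mat,
#'                 gap_penalties(0, 0))
#' }
#' @export
align_molecules <- function(smiles_a, smiles_b, scorer,
                            penalties = gap_penalties(0, 0),
                            gap_symbol = "-",
                            charge_provider = gasteiger_charges) {
  bp_a <- if (inherits(smiles_a, "charge_blueprint")) smiles_a
    else compute_blueprint(smiles_a, charge_provider)
  bp_b <- if (inherits(smiles_b, "charge_blueprint")) smiles_b
    else compute_blueprint(smiles_b, charge_provider)
  state <- align_fill(bp_a, bp_b, scorer, penalties)
  tb <- align_traceback(state)
  aligned_a <- ifelse(is.na(tb$a_idx), NA_character_,
                      bp_a$tokens$symbol[tb$a_idx])
  aligned_b <- ifelse(is.na(tb$b_idx), NA_character_,
                      bp_b$tokens$symbol[tb$b_idx])
  score <- if (state$n == 0L && state$m == 0L) 0
    else max(state$M[state$n + 1L, state$m + 1L],
             state$X[state$n + 1L, state$m + 1L],
             state$Y[state$n + 1L, state$m + 1L])
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score,
                 aligned_smiles_a = reinsert(aligned_a, bp_a, gap_symbol),
                 aligned_smiles_b = reinsert(aligned_b, bp_b, gap_symbol),
                 mode = if (inherits(scorer, "paired_scoring_set"))
                   "paired" else "all_vs_all",
                 penalties = penalties,
                 blueprint_a = bp_a, blueprint_b = bp_b,
                 gap_symbol = gap_symbol),
            class = "mol_alignment")
}

#' Collapse aligned tokens to a gapped token string
#'
#' The string form of an aligned molecule used by the validation metrics:
#' token symbols concatenated in alignment order with gaps rendered as
#' \code{gap_symbol} (the "SMILES without characters" representation).
#'
#' @param aligned character vector of token symbols with \code{NA} gaps, or
#'   a \code{mol_alignment} (in which case both strings are returned).
#' @param gap_symbol gap character.
#' @return a character scalar, or a length-2 vector for an alignment.
#' @export
aligned_token_string <- function(aligned, gap_symbol = "-") {
  if (inherits(aligned, "mol_alignment"))
    return(c(aligned_token_string(aligned$aligned_a, gap_symbol),
             aligned_token_string(aligned$aligned_b, gap_symbol)))
  paste(ifelse(is.na(aligned), gap_symbol, aligned), collapse = "")
}

#' @export
print.mol_alignment <- function(x, ...) {
  cat("mol_alignment (", x$mode, " mode, g_open = ", x$penalties$g_open,
      ", g_extend = ", x$penalties$g_extend, ")\n", sep = "")
  cat("  ", x$aligned_smiles_a, "\n", sep = "")
  cat("  ", x$aligned_smiles_b, "\n", sep = "")
  cat("  score: ", format(x$score), "\n", sep = "")
  invisible(x)
}
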