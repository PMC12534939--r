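# Empirical scoring matrices over binned Gasteiger-charge differences.
#
# The score of a bin is the log2 survival probability of observing a charge
# difference at least as large as the bin's lower edge, shifted so the bin
# containing the mean difference scores exactly zero: sub-mean differences
# are rewarded, super-mean differences penalized (a BLOSUM-like log-odds
# construction over charge space).

.N_BINS <- 30L
.BIN_WIDTH <- 0.1
.BIN_EPS <- 1e-9  # guards binary-double edge effects at bin boundaries

#' Pool the charges of a molecule corpus
#'
#' Aggregates the per-atom partial charges of a set of blueprints into a
#' master list, partitioned by element.
#'
#' @param blueprints a non-empty list of \code{charge_blueprint} objects.
#' @return an object of class \code{charge_pool}: list with \code{charges}
#'   (all charges), \code{per_element} (named list of charge vectors) and
#'   \code{n_molecules}.
#' @export
build_charge_pool <- function(blueprints) {
  if (length(blueprints) == 0L) stop("empty corpus: no blueprints supplied")
  stopifnot(all(vapply(blueprints, inherits, logical(1), "charge_blueprint")))
  charges <- unlist(lapply(blueprints, `[[`, "charges"), use.names = FALSE)
  elements <- unlist(lapply(blueprints, function(b) b$tokens$element),
                     use.names = FALSE)
  structure(list(charges = charges,
                 per_element = split(charges, elements),
                 n_molecules = length(blueprints)),
            class = "charge_pool")
}

#' Exhaustive absolute charge differences
#'
#' Single-list mode returns \eqn{|q_i - q_j|} for all unordered pairs
#' \eqn{i < j} (used for the all-vs-all matrix and same-element pairs);
#' two-list mode returns the full cross product (used for paired matrices of
#' two distinct elements).
#'
#' @param values_a numeric vector of charges.
#' @param values_b optional second vector; when supplied, all cross pairs
#'   are formed.
#' @return numeric vector of absolute differences.
#' @export
pairwise_abs_differences <- function(values_a, values_b = NULL) {
  if (length(values_a) == 0L) stop("empty charge list")
  if (is.null(values_b)) {
    if (length(values_a) < 2L) return(numeric(0))
    return(as.numeric(stats::dist(values_a)))
  }
  if (length(values_b) == 0L) stop("empty charge list")
  as.numeric(abs(outer(values_a, values_b, "-")))
}

# Bin index (1-based) of an absolute difference; >= 3 clamps to the last bin.
.bin_index <- function(d) {
  pmin(as.integer(floor(d / .BIN_WIDTH + .BIN_EPS)), .N_BINS - 1L) + 1L
}

#' Build a scoring matrix from a set of charge differences
#'
#' Differences are binned in 0.1 intervals from 0 to 3 (differences of 3 or
#' more fall in the last bin). The raw score of bin \eqn{k} is
#' \eqn{\log_2} of the survival fraction: the proportion of differences
#' greater than or equal to the bin's lower edge. Where that count is zero
#' a pseudo-count of one observation is substituted, giving a flat
#' largest-penalty plateau of \eqn{\log_2(1/N)}. Final scores are the raw
#' scores shifted by the raw score of the bin containing the mean
#' difference, so that bin scores exactly 0, sub-mean bins score >= 0 and
#' super-mean bins <= 0.
#'
#' @param diffs non-empty numeric vector of absolute charge differences.
#' @return an object of class \code{scoring_matrix}: list with
#'   \code{bin_width}, \code{bin_lower_edges}, \code{raw_scores},
#'   \code{mean_diff}, \code{mean_bin}, \code{scores}, \code{floor} and
#'   \code{n_observations}.
#' @examples
#' m <- build_scoring_matrix(c(0.1, 0.2, 0.3))
#' m$raw_scores[1:4]  # 0, 0, log2(2/3), log2(1/3)
#' @export
build_scoring_matrix <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  if (length(diffs) == 0L) stop("cannot build a scoring matrix from no differences")
  n <- length(diffs)
  edges <- (seq_len(.N_BINS) - 1L) / 10
  surv <- vapply(edges, function(e) sum(diffs >= e - .BIN_EPS), numeric(1))
  raw <- log2(pmax(surv, 1) / n)
  mu <- mean(diffs)
  mu_bin <- .bin_index(mu)
  scores <- raw - raw[mu_bin]
  structure(list(bin_width = .BIN_WIDTH, bin_lower_edges = edges,
                 raw_scores = raw, mean_diff = mu, mean_bin = mu_bin,
                 scores = scores, floor = min(scores),
                 n_observations = n),
            class = "scoring_matrix")
}

#' Build the all-vs-all scoring matrix from a corpus
#'
#' Pools every charge in every molecule, forms all pairwise absolute
#' differences, and builds the survival scoring matrix.
#'
#' @inheritParams build_charge_pool
#' @return a \code{scoring_matrix}.
#' @export
build_all_vs_all <- function(blueprints) {
  pool <- build_charge_pool(blueprints)
  if (length(pool$charges) < 2L)
    stop("need at least two charges in the corpus to form differences")
  build_scoring_matrix(pairwise_abs_differences(pool$charges))
}

#' Build element-pair scoring matrices from a corpus
#'
#' For each unordered element pair observed in the corpus (C-C, C-O, O-O,
#' ...), builds a scoring matrix from that pair's charge differences. By
#' default charges are pooled across the whole corpus (all charges of
#' element A against all charges of element B, mirroring the all-vs-all
#' construction); \code{within_molecules = TRUE} restricts pairing to atoms
#' of the same molecule. Pairs with fewer than \code{min_pair_observations}
#' differences are not stored and resolve to the all-vs-all fallback, since
#' survival estimates from tiny samples are degenerate.
#'
#' @inheritParams build_charge_pool
#' @param min_pair_observations minimum number of differences required to
#'   store a pair-specific matrix.
#' @param within_molecules if \code{TRUE}, only pair atoms within the same
#'   molecule.
#' @return an object of class \code{paired_scoring_set}: list with
#'   \code{matrices} (named by sorted element pair, e.g. \code{"C|O"}),
#'   \code{fallback} (the all-vs-all matrix) and
#'   \code{min_pair_observations}.
#' @export
build_paired <- function(blueprints, min_pair_observations = 100,
                         within_molecules = FALSE) {
  fallback <- build_all_vs_all(blueprints)
  pool <- build_charge_pool(blueprints)
  elements <- sort(names(pool$per_element))
  pairs <- list()
  for (i in seq_along(elements)) for (j in i:length(elements)) {
    ea <- elements[i]; eb <- elements[j]
    diffs <- if (within_molecules) {
      unlist(lapply(blueprints, function(b) {
        qa <- b$charges[b$tokens$element == ea]
        qb <- b$charges[b$tokens$element == eb]
        if (ea == eb) {
          if (length(qa) < 2L) numeric(0) else pairwise_abs_differences(qa)
        } else if (length(qa) && length(qb)) {
          pairwise_abs_differences(qa, qb)
        } else numeric(0)
      }), use.names = FALSE)
    } else if (ea == eb) {
      if (length(pool$per_element[[ea]]) < 2L) numeric(0)
      else pairwise_abs_differences(pool$per_element[[ea]])
    } else {
      pairwise_abs_differences(pool$per_element[[ea]],
                               pool$per_element[[eb]])
    }
    if (length(diffs) >= min_pair_observations)
      pairs[[paste(ea, eb, sep = "|")]] <- build_scoring_matrix(diffs)
  }
  structure(list(matrices = pairs, fallback = fallback,
                 min_pair_observations = min_pair_observations),
            class = "paired_scoring_set")
}

.pair_key <- function(element_a, element_b) {
  paste(sort(c(element_a, element_b)), collapse = "|")
}

# Resolve the scoring_matrix used for an element pair (totality guaranteed
# by the fallback).
.resolve_matrix <- function(scorer, element_a, element_b) {
  if (inherits(scorer, "scoring_matrix")) return(scorer)
  if (inherits(scorer, "paired_scoring_set")) {
    m <- scorer$matrices[[.pair_key(element_a, element_b)]]
    return(if (is.null(m)) scorer$fallback else m)
  }
  stop("scorer must be a scoring_matrix or paired_scoring_set")
}

#' Score for aligning two atoms
#'
#' Looks up the score of the bin containing \eqn{|q_a - q_b|} (differences
#' of 3 or more clamp to the last bin). With a \code{paired_scoring_set},
#' the matrix for the unordered element pair is used, falling back to the
#' all-vs-all matrix for pairs without a stored matrix. Symmetric in its
#' arguments.
#'
#' @param scorer a \code{scoring_matrix} or \code{paired_scoring_set}.
#' @param element_a,element_b element symbols of the two atoms.
#' @param q_a,q_b their partial charges.
#' @return the substitution score (numeric scalar).
#' @export
score_lookup <- function(scorer, element_a, q_a, element_b, q_b) {
  m <- .resolve_matrix(scorer, element_a, element_b)
  m$scores[.bin_index(abs(q_a - q_b))]
}

# n x m substitution-score matrix for two blueprints (vectorized per
# element-pair block); this is what the aligner consumes.
.substitution_matrix <- function(scorer, bp_a, bp_b) {
  n <- length(bp_a$charges); m <- length(bp_b$charges)
  bins <- matrix(.bin_index(abs(outer(bp_a$charges, bp_b$charges, "-"))),
                 n, m)
  if (inherits(scorer, "scoring_matrix")) {
    return(matrix(scorer$scores[bins], n, m))
  }
  S <- matrix(NA_real_, n, m)
  ea <- bp_a$tokens$element; eb <- bp_b$tokens$element
  for (key_a in unique(ea)) for (key_b in unique(eb)) {
    mx <- .resolve_matrix(scorer, key_a, key_b)
    sel_a <- ea == key_a; sel_b <- eb == key_b
    S[sel_a, sel_b] <- mx$scores[bins[sel_a, sel_b, drop = FALSE]]
  }
  S
}

#' Serialize a scoring matrix to CSV plus JSON metadata
#'
#' Writes \code{<prefix>.csv} with columns \code{bin_lower_edge},
#' \code{raw_score}, \code{score}, and \code{<prefix>.json} with the scalar
#' metadata (mean difference, observation count, floor) needed to rebuild
#' the object.
#'
#' @param matrix a \code{scoring_matrix}.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_scoring_matrix <- function(matrix, prefix) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  csv <- paste0(prefix, ".csv"); json <- paste0(prefix, ".json")
  utils::write.csv(data.frame(bin_lower_edge = matrix$bin_lower_edges,
                              raw_score = matrix$raw_scores,
                              score = matrix$scores),
                   csv, row.names = FALSE)
  jsonlite::write_json(list(bin_width = matrix$bin_width,
                            mean_diff = matrix$mean_diff,
                            mean_bin = matrix$mean_bin,
                            floor = matrix$floor,
                            n_observations = matrix$n_observations),
                       json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Read a scoring matrix written by [write_scoring_matrix()]
#'
#' @param prefix path prefix used at write time.
#' @return a \code{scoring_matrix}.
#' @export
read_scoring_matrix <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(list(bin_width = meta$bin_width,
                 bin_lower_edges = df$bin_lower_edge,
                 raw_scores = df$raw_score, mean_diff = meta$mean_diff,
                 mean_bin = meta$mean_bin, scores = df$score,
                 floor = meta$floor, n_observations = meta$n_observations),
            class = "scoring_matrix")
}

#' Serialize a paired scoring set to a directory
#'
#' Each pair matrix is written as \code{<element>-<element>.csv/.json}; the
#' all-vs-all fallback as \code{fallback.csv/.json}.
#'
#' @param set a \code{paired_scoring_set}.
#' @param dir output directory (created if missing).
#' @return invisibly, \code{dir}.
#' @export
write_paired_set <- function(set, dir) {
  stopifnot(inherits(set, "paired_scoring_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(set$matrices))
    write_scoring_matrix(set$matrices[[key]],
                         file.path(dir, gsub("|", "-", key, fixed = TRUE)))
  write_scoring_matrix(set$fallback, file.path(dir, "fallback"))
  jsonlite::write_json(list(min_pair_observations = set$min_pair_observations,
                            pairs = as.list(names(set$matrices))),
                       file.path(dir, "set.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a paired scoring set written by [write_paired_set()]
#'
#' @param dir directory written by [write_paired_set()].
#' @return a \code{paired_scoring_set}.
#' @export
read_paired_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "set.json"),
                              simplifyVector = TRUE)
  keys <- as.character(meta$pairs)
  matrices <- lapply(keys, function(key)
    read_scoring_matrix(file.path(dir, gsub("|", "-", key, fixed = TRUE))))
  names(matrices) <- keys
  structure(list(matrices = matrices,
                 fallback = read_scoring_matrix(file.path(dir, "fallback")),
                 min_pair_observations = meta$min_pair_observations),
            class = "paired_scoring_set")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("scoring_matrix: 30 bins of width 0.1 over |charge difference| 0-3\n")
  cat(sprintf("  n_observations: %d   mean difference: %.4f (bin %d)\n",
              x$n_observations, x$mean_diff, x$mean_bin - 1L))
  cat(sprintf("  score range: [%.3f, %.3f]\n", x$floor, max(x$scores)))
  invisible(x)
}

#' @export
print.paired_scoring_set <- function(x, ...) {
  cat("paired_scoring_set with", length(x$matrices), "pair matrices:",
      paste(names(x$matrices), collapse = " "), "\n")
  cat("  fallback: all-vs-all matrix (n =", x$fallback$n_observations, ")\n")
  cat("  min_pair_observations:", x$min_pair_observations, "\n")
  invisible(x)
}
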