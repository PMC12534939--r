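# Per-distance alignment-score profiles over metabolic pathways.
#
# A cyclic pathway of n steps is scored at distances 0..floor(n/2) (the
# minimum step count in either direction around the cycle); a linear one at
# distances 0..n-1. Distance 0 holds the self-alignments. Each unordered
# molecule pair contributes once to its distance group; the reported spread
# is the population (divide-by-N) standard deviation.

#' Construct a pathway
#'
#' @param ids unique molecule identifiers, in pathway order.
#' @param smiles SMILES strings, parallel to \code{ids}.
#' @param cyclic whether the pathway closes on itself (last step feeds the
#'   first), as in the Krebs cycle.
#' @param name pathway name.
#' @return an object of class \code{pathway}.
#' @export
pathway <- function(ids, smiles, cyclic = FALSE, name = "pathway") {
  stopifnot(length(ids) == length(smiles))
  if (length(ids) < 2L) stop("a pathway needs at least 2 molecules")
  if (anyDuplicated(ids)) stop("pathway ids must be unique")
  structure(list(name = name,
                 molecules = data.frame(id = as.character(ids),
                                        smiles = as.character(smiles),
                                        stringsAsFactors = FALSE),
                 cyclic = isTRUE(cyclic)),
            class = "pathway")
}

#' Read a pathway from a TSV file
#'
#' Tab-separated columns \code{order}, \code{id}, \code{smiles}; rows are
#' sorted by \code{order}.
#'
#' @param path TSV file path.
#' @param cyclic whether to treat the pathway as cyclic.
#' @param name pathway name (defaults to the file name).
#' @return a [pathway()] object.
#' @export
read_pathway <- function(path, cyclic = FALSE,
                         name = tools::file_path_sans_ext(basename(path))) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("order", "id", "smiles") %in% names(df)))
    stop("pathway file must have columns order, id, smiles: ", path)
  df <- df[order(df$order), ]
  pathway(df$id, df$smiles, cyclic = cyclic, name = name)
}

#' Minimum cyclic distance between two pathway positions
#'
#' For positions \code{i} and \code{j} (1-based) on a cycle of length
#' \code{n}: \code{min(|i - j|, n - |i - j|)}, the shortest step count in
#' either direction.
#'
#' @param i,j positions (1-based).
#' @param n cycle length.
#' @return integer distance.
#' @export
min_cyclic_distance <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

.profile_from_pairs <- function(per_pair, max_distance) {
  dist_levels <- 0:max_distance
  rows <- lapply(dist_levels, function(d) {
    sel <- per_pair$distance == d
    data.frame(distance = d,
               mean_score = if (any(sel)) mean(per_pair$score[sel]) else NA_real_,
               std = if (any(sel)) .pop_sd(per_pair$score[sel]) else NA_real_,
               n_pairs = sum(sel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-distance alignment-score profile of a pathway
#'
#' Aligns every unordered molecule pair of the pathway (plus each molecule
#' with itself for distance 0), groups the scores by pathway distance
#' (minimum cyclic distance for cyclic pathways, index difference for
#' linear ones) and reports the mean, population standard deviation and
#' pair count per distance. The per-pair score table is attached as
#' attribute \code{"pairs"}.
#'
#' @param pw a [pathway()] object.
#' @param scorer a \code{scoring_matrix} or \code{paired_scoring_set}.
#' @param penalties a [gap_penalties()] object.
#' @param mode \code{"pairs"} (default): every unordered pair, grouped by
#'   pathway distance. \code{"from_start"} (linear pathways only): each
#'   molecule aligned with the starting molecule, one pair per distance.
#' @param charge_provider passed to [compute_blueprints()].
#' @return data.frame with columns \code{distance}, \code{mean_score},
#'   \code{std}, \code{n_pairs}.
#' @export
distance_profile <- function(pw, scorer, penalties = gap_penalties(0, 0),
                             mode = c("pairs", "from_start"),
                             charge_provider = gasteiger_charges) {
  stopifnot(inherits(pw, "pathway"))
  mode <- match.arg(mode)
  mols <- pw$molecules
  n <- nrow(mols)
  bps <- compute_blueprints(mols$smiles, mols$id,
                            charge_provider = charge_provider)
  pair_score <- function(i, j) {
    st <- align_fill(bps[[i]], bps[[j]], scorer, penalties)
    max(st$M[st$n + 1L, st$m + 1L], st$X[st$n + 1L, st$m + 1L],
        st$Y[st$n + 1L, st$m + 1L])
  }
  if (mode == "from_start") {
    if (pw$cyclic)
      stop("from_start mode is defined for linear pathways only")
    per_pair <- data.frame(id_a = mols$id[1], id_b = mols$id,
                           distance = seq_len(n) - 1L,
                           score = vapply(seq_len(n), function(j)
                             pair_score(1L, j), numeric(1)),
                           stringsAsFactors = FALSE)
    out <- .profile_from_pairs(per_pair, n - 1L)
    attr(out, "pairs") <- per_pair
    attr(out, "pathway") <- pw$name
    return(out)
  }
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <-
      data.frame(id_a = mols$id[i], id_b = mols$id[i], distance = 0L,
                 score = pair_score(i, i), stringsAsFactors = FALSE)
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- if (pw$cyclic) min_cyclic_distance(i, j, n) else j - i
    rows[[length(rows) + 1L]] <-
      data.frame(id_a = mols$id[i], id_b = mols$id[j], distance = d,
                 score = pair_score(i, j), stringsAsFactors = FALSE)
  }
  per_pair <- do.call(rbind, rows)
  max_d <- if (pw$cyclic) n %/% 2L else n - 1L
  out <- .profile_from_pairs(per_pair, max_d)
  attr(out, "pairs") <- per_pair
  attr(out, "pathway") <- pw$name
  out
}

#' Per-distance Tanimoto profile of a pathway
#'
#' Same distance grouping as [distance_profile()] but with the Tanimoto
#' coefficient over path fingerprints as the pair score (distance 0 is
#' always 1). For linear pathways, \code{mode = "from_start"} instead
#' reports the Tanimoto similarity of each molecule with the starting
#' molecule, one pair per distance.
#'
#' @param pw a [pathway()] object.
#' @param mode \code{"pairs"} (default, all pairs grouped by distance) or
#'   \code{"from_start"} (linear pathways only).
#' @return data.frame with columns \code{distance}, \code{mean_score},
#'   \code{std}, \code{n_pairs}; per-pair table in attribute \code{"pairs"}.
#' @export
tanimoto_profile <- function(pw, mode = c("pairs", "from_start")) {
  stopifnot(inherits(pw, "pathway"))
  mode <- match.arg(mode)
  mols <- pw$molecules
  n <- nrow(mols)
  fp <- .fingerprints(mols$smiles)
  tani <- function(i, j) {
    union <- sum(fp[i, ] | fp[j, ])
    if (union == 0L) 1 else sum(fp[i, ] & fp[j, ]) / union
  }
  if (mode == "from_start") {
    if (pw$cyclic)
      stop("from_start mode is defined for linear pathways only")
    per_pair <- data.frame(id_a = mols$id[1], id_b = mols$id,
                           distance = seq_len(n) - 1L,
                           score = vapply(seq_len(n), function(j)
                             tani(1L, j), numeric(1)),
                           stringsAsFactors = FALSE)
    out <- .profile_from_pairs(per_pair, n - 1L)
    attr(out, "pairs") <- per_pair
    attr(out, "pathway") <- pw$name
    return(out)
  }
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <-
      data.frame(id_a = mols$id[i], id_b = mols$id[i], distance = 0L,
                 score = 1, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- if (pw$cyclic) min_cyclic_distance(i, j, n) else j - i
    rows[[length(rows) + 1L]] <-
      data.frame(id_a = mols$id[i], id_b = mols$id[j], distance = d,
                 score = tani(i, j), stringsAsFactors = FALSE)
  }
  per_pair <- do.call(rbind, rows)
  max_d <- if (pw$cyclic) n %/% 2L else n - 1L
  out <- .profile_from_pairs(per_pair, max_d)
  attr(out, "pairs") <- per_pair
  attr(out, "pathway") <- pw$name
  out
}

#' @export
print.pathway <- function(x, ...) {
  cat("pathway '", x$name, "' (", if (x$cyclic) "cyclic" else "linear",
      ", ", nrow(x$molecules), " molecules)\n", sep = "")
  print(x$molecules)
  invisible(x)
}
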