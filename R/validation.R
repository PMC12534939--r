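# Alignment validation: string similarity metrics against a curated truth
# set, the Tanimoto baseline, and the exhaustive gap-penalty sweep.

#' Levenshtein similarity between two strings
#'
#' Defined as \eqn{1 - d(s_1, s_2) / \max(|s_1|, |s_2|)} where \eqn{d} is
#' the Levenshtein edit distance; two empty strings have similarity 1.
#'
#' @param s1,s2 character scalars.
#' @return similarity in \[0, 1\].
#' @examples
#' levenshtein_similarity("kitten", "sitting")  # 1 - 3/7
#' @export
levenshtein_similarity <- function(s1, s2) {
  n <- max(nchar(s1), nchar(s2))
  if (n == 0L) return(1)
  1 - as.numeric(utils::adist(s1, s2)) / n
}

#' Exact (positionwise) similarity between two gapped strings
#'
#' The fraction of positions carrying identical characters. Strings of
#' unequal length are right-padded with the gap symbol (with a warning),
#' since truth and produced alignments of the same molecule pair can differ
#' in total gap count.
#'
#' @param g1,g2 gapped strings.
#' @param gap_symbol padding character for unequal lengths.
#' @return similarity in \[0, 1\]; two empty strings give 1.
#' @export
exact_similarity <- function(g1, g2, gap_symbol = "-") {
  n1 <- nchar(g1); n2 <- nchar(g2)
  if (n1 == 0L && n2 == 0L) return(1)
  if (n1 != n2) {
    warning("gapped strings of unequal length (", n1, " vs ", n2,
            "); padding the shorter with '", gap_symbol, "'", call. = FALSE)
    if (n1 < n2) g1 <- paste0(g1, strrep(gap_symbol, n2 - n1))
    else g2 <- paste0(g2, strrep(gap_symbol, n1 - n2))
  }
  c1 <- strsplit(g1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(g2, "", fixed = TRUE)[[1]]
  mean(c1 == c2)
}

# FP2 path fingerprints (1024-bit) for a vector of SMILES, as a 0/1 matrix.
.fingerprints <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES",
                                 paste0(paste(smiles, collapse = "\n"), "\n"),
                                 identity)
  fp <- ChemmineOB::fingerprint_OB(mols, "FP2")
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1L)
  (fp > 0) * 1L
}

#' Tanimoto coefficient between two molecules
#'
#' \eqn{|A \cap B| / |A \cup B|} over the bit sets of hashed path
#' fingerprints (Open Babel FP2, linear fragments up to 7 atoms hashed to
#' 1024 bits). Self-comparison gives 1; two molecules with no fingerprint
#' bits at all (single heavy atoms) are treated as identical feature sets.
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @return similarity in \[0, 1\], symmetric in its arguments.
#' @export
tanimoto_coefficient <- function(smiles_a, smiles_b) {
  .check_smiles_syntax(smiles_a); .check_smiles_syntax(smiles_b)
  fp <- .fingerprints(c(smiles_a, smiles_b))
  inter <- sum(fp[1, ] & fp[2, ])
  union <- sum(fp[1, ] | fp[2, ])
  if (union == 0L) return(1)
  inter / union
}

#' Read a truth set of curated gapped alignments
#'
#' Tab-separated file with columns \code{id_a}, \code{id_b},
#' \code{gapped_a}, \code{gapped_b}: the two molecules' gapped atom-token
#' strings under the reference (biochemically curated) alignment.
#'
#' @param path TSV file path.
#' @return data.frame of truth entries.
#' @export
read_truth_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id_a", "id_b", "gapped_a", "gapped_b")
  if (!all(need %in% names(df)))
    stop("truth set must have columns ", paste(need, collapse = ", "),
         ": ", path)
  bad <- nchar(df$gapped_a) != nchar(df$gapped_b)
  if (any(bad))
    stop("truth entries with unequal gapped lengths: ",
         paste(df$id_a[bad], df$id_b[bad], sep = "~", collapse = ", "))
  df
}

.truth_lookup <- function(truth, id_a, id_b) {
  hit <- which(truth$id_a == id_a & truth$id_b == id_b)
  if (length(hit)) return(list(a = truth$gapped_a[hit[1]],
                               b = truth$gapped_b[hit[1]]))
  hit <- which(truth$id_a == id_b & truth$id_b == id_a)
  if (length(hit)) return(list(a = truth$gapped_b[hit[1]],
                               b = truth$gapped_a[hit[1]]))
  stop("no truth entry for pair '", id_a, "' ~ '", id_b, "'")
}

#' Exhaustive gap-penalty parameter sweep
#'
#' Aligns every supplied molecule pair at every integer combination of
#' \code{(g_open, g_extend)} over the grid (default \eqn{[-5, 5]^2}, 121
#' cells) and scores each cell by the mean similarity between the produced
#' and truth gapped token strings. Per pair, the similarity is the mean of
#' the two molecules' string similarities; per cell, the mean over pairs.
#' Substitution matrices are computed once per pair and reused across the
#' whole grid, so the sweep cost is dominated by the 121 dynamic programs
#' per pair.
#'
#' @param pairs data.frame with columns \code{id_a}, \code{smiles_a},
#'   \code{id_b}, \code{smiles_b}.
#' @param truth truth set (see [read_truth_set()]); must cover all pairs.
#' @param scorer a \code{scoring_matrix} or \code{paired_scoring_set}.
#' @param grid integer penalty values to sweep (applied to both g_open and
#'   g_extend).
#' @param gap_symbol gap character used in the gapped strings.
#' @param charge_provider passed to [compute_blueprint()].
#' @return data.frame with one row per cell, ordered g_open-major:
#'   \code{g_open}, \code{g_extend}, \code{mean_levenshtein_similarity},
#'   \code{mean_exact_similarity}, \code{difference}.
#' @export
parameter_sweep <- function(pairs, truth, scorer, grid = -5:5,
                            gap_symbol = "-",
                            charge_provider = gasteiger_charges) {
  need <- c("id_a", "smiles_a", "id_b", "smiles_b")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns ", paste(need, collapse = ", "))
  uniq <- unique(data.frame(id = c(pairs$id_a, pairs$id_b),
                            smiles = c(pairs$smiles_a, pairs$smiles_b),
                            stringsAsFactors = FALSE))
  bps <- compute_blueprints(uniq$smiles, uniq$id,
                            charge_provider = charge_provider)
  names(bps) <- uniq$id
  prep <- lapply(seq_len(nrow(pairs)), function(k) {
    ta <- .truth_lookup(truth, pairs$id_a[k], pairs$id_b[k])
    bp_a <- bps[[pairs$id_a[k]]]; bp_b <- bps[[pairs$id_b[k]]]
    list(bp_a = bp_a, bp_b = bp_b, truth = ta,
         S = .substitution_matrix(scorer, bp_a, bp_b))
  })
  rows <- vector("list", length(grid)^2)
  r <- 0L
  for (go in grid) for (ge in grid) {
    pen <- gap_penalties(go, ge)
    lev <- numeric(length(prep)); exact <- numeric(length(prep))
    for (k in seq_along(prep)) {
      p <- prep[[k]]
      st <- align_fill(p$bp_a, p$bp_b, scorer, pen, S = p$S)
      tb <- align_traceback(st)
      ga <- aligned_token_string(ifelse(is.na(tb$a_idx), NA_character_,
                                        p$bp_a$tokens$symbol[tb$a_idx]),
                                 gap_symbol)
      gb <- aligned_token_string(ifelse(is.na(tb$b_idx), NA_character_,
                                        p$bp_b$tokens$symbol[tb$b_idx]),
                                 gap_symbol)
      lev[k] <- mean(c(levenshtein_similarity(ga, p$truth$a),
                       levenshtein_similarity(gb, p$truth$b)))
      # produced and truth alignments routinely differ in total gap count;
      # padding is by design here, so the per-call length warning is muted
      exact[k] <- mean(c(suppressWarnings(
                           exact_similarity(ga, p$truth$a, gap_symbol)),
                         suppressWarnings(
                           exact_similarity(gb, p$truth$b, gap_symbol))))
    }
    r <- r + 1L
    rows[[r]] <- data.frame(g_open = go, g_extend = ge,
                            mean_levenshtein_similarity = mean(lev),
                            mean_exact_similarity = mean(exact),
                            difference = mean(lev) - mean(exact))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best parameters of a sweep
#'
#' The cell with the highest mean Levenshtein similarity; ties are broken
#' by the smaller Levenshtein-minus-exact difference, then lexicographically
#' by (g_open, g_extend), so the choice is deterministic.
#'
#' @param cells data.frame as returned by [parameter_sweep()].
#' @return list with elements \code{g_open} and \code{g_extend}.
#' @export
best_parameters <- function(cells) {
  if (nrow(cells) == 0L) stop("empty sweep")
  o <- order(-cells$mean_levenshtein_similarity, cells$difference,
             cells$g_open, cells$g_extend)
  best <- cells[o[1], ]
  list(g_open = best$g_open, g_extend = best$g_extend)
}

#' All unordered pairs of a molecule set
#'
#' Convenience constructor of the \code{pairs} input of
#' [parameter_sweep()] from a corpus data.frame.
#'
#' @param corpus data.frame with columns \code{id} and \code{smiles}.
#' @return data.frame with columns \code{id_a}, \code{smiles_a},
#'   \code{id_b}, \code{smiles_b}, one row per unordered pair (i < j).
#' @export
all_pairs <- function(corpus) {
  n <- nrow(corpus)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  data.frame(id_a = corpus$id[idx[, 1]], smiles_a = corpus$smiles[idx[, 1]],
             id_b = corpus$id[idx[, 2]], smiles_b = corpus$smiles[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Consecutive pairs of an ordered molecule set
#'
#' Pairs each molecule with its successor in pathway order; with
#' \code{cyclic = TRUE} the last molecule is also paired with the first.
#'
#' @param corpus data.frame with columns \code{id} and \code{smiles}, in
#'   pathway order.
#' @param cyclic close the cycle with a last-to-first pair.
#' @return data.frame in the format of [all_pairs()].
#' @export
consecutive_pairs <- function(corpus, cyclic = FALSE) {
  n <- nrow(corpus)
  i <- seq_len(if (cyclic) n else n - 1L)
  j <- c(seq_len(n)[-1L], 1L)[i]
  data.frame(id_a = corpus$id[i], smiles_a = corpus$smiles[i],
             id_b = corpus$id[j], smiles_b = corpus$smiles[j],
             stringsAsFactors = FALSE)
}
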