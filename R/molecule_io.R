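# SMILES ingestion: canonicalization, atom tokenization, charge blueprints.

# Two-letter element symbols of the SMILES organic subset that may appear
# outside brackets. Everything else outside brackets is single-letter.
.ORGANIC_TWO <- c("Cl", "Br")
.ORGANIC_ONE <- c("B", "C", "N", "O", "P", "S", "F", "I")
.AROMATIC_ONE <- c("b", "c", "n", "o", "p", "s")
.SKELETON_CHARS <- c("-", "=", "#", "$", ":", "/", "\\", "(", ")", ".",
                     "%", as.character(0:9))

.VALID_ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn")

.check_smiles_syntax <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stop("SMILES must be a single character string")
  if (!nzchar(smiles))
    stop("empty SMILES string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  if (sum(chars == "(") != sum(chars == ")"))
    stop("malformed SMILES (unmatched parenthesis): ", smiles)
  if (sum(chars == "[") != sum(chars == "]"))
    stop("malformed SMILES (unmatched bracket): ", smiles)
  invisible(TRUE)
}

#' Canonicalize SMILES strings
#'
#' Converts each SMILES string to the canonical form produced by the Open
#' Babel toolkit (via \pkg{ChemmineOB}). Canonicalization is deterministic
#' and idempotent for a fixed toolkit version; all downstream operations
#' (tokenization, charge blueprints, alignment) work on canonical strings so
#' that the same structure always yields the same atom order.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize(c("CCCC", "C(C)CC"))  # same molecule, same output
#' @export
canonicalize <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  for (s in smiles) .check_smiles_syntax(s)
  out <- ChemmineOB::convertFormat(
    "SMI", "CAN", paste0(paste(smiles, collapse = "\n"), "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) | seq_along(lines) <= length(smiles)]
  if (length(lines) != length(smiles) || any(!nzchar(lines))) {
    bad <- if (length(lines) < length(smiles))
      smiles[length(lines) + 1L] else smiles[!nzchar(lines)][1]
    stop("SMILES failed to parse/canonicalize: ", bad)
  }
  lines
}

#' Tokenize the atoms of a canonical SMILES string
#'
#' Splits a SMILES string into its atom tokens and a skeleton of the
#' remaining non-atomic characters (bond symbols, ring-closure digits,
#' parentheses, dots). A bracket atom \code{[...]} is one token whose span
#' covers the whole bracket, so charges, isotopes and explicit H counts
#' travel with the atom rather than the skeleton. Aromatic lowercase atoms
#' are tokens normalized to their uppercase element. Implicit hydrogens are
#' never tokens.
#'
#' @param smiles a SMILES string, normally the output of [canonicalize()].
#' @return a list with components
#'   \describe{
#'     \item{tokens}{data.frame with columns \code{symbol} (the token as it
#'       appears in the string), \code{element} (normalized element symbol),
#'       \code{atom_index} (0-based), \code{start}, \code{end} (half-open
#'       character span, 0-based).}
#'     \item{skeleton}{character vector of \code{n + 1} inter-atom segments;
#'       interleaving \code{skeleton[1], symbol[1], skeleton[2], ...,
#'       symbol[n], skeleton[n+1]} reproduces the input byte-for-byte.}
#'   }
#' @examples
#' tok <- tokenize_atoms("OC(=O)CC(=O)C(=O)O")
#' tok$tokens$element  # nine atoms: O C O C C O C O O
#' @export
tokenize_atoms <- function(smiles) {
  .check_smiles_syntax(smiles)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  nc <- length(chars)
  symbol <- character(0); element <- character(0)
  start <- integer(0); end <- integer(0)
  segments <- character(0)
  seg <- ""
  i <- 1L
  while (i <= nc) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= nc && chars[j] != "]") j <- j + 1L
      if (j > nc) stop("malformed SMILES (unmatched bracket): ", smiles)
      body <- substr(smiles, i, j)
      symbol <- c(symbol, body)
      element <- c(element, .bracket_element(body, smiles))
      start <- c(start, i - 1L); end <- c(end, j)
      segments <- c(segments, seg); seg <- ""
      i <- j + 1L
    } else if (i < nc && paste0(ch, chars[i + 1L]) %in% .ORGANIC_TWO) {
      symbol <- c(symbol, paste0(ch, chars[i + 1L]))
      element <- c(element, paste0(ch, chars[i + 1L]))
      start <- c(start, i - 1L); end <- c(end, i + 1L)
      segments <- c(segments, seg); seg <- ""
      i <- i + 2L
    } else if (ch %in% .ORGANIC_ONE) {
      symbol <- c(symbol, ch); element <- c(element, ch)
      start <- c(start, i - 1L); end <- c(end, i)
      segments <- c(segments, seg); seg <- ""
      i <- i + 1L
    } else if (ch %in% .AROMATIC_ONE) {
      symbol <- c(symbol, ch); element <- c(element, toupper(ch))
      start <- c(start, i - 1L); end <- c(end, i)
      segments <- c(segments, seg); seg <- ""
      i <- i + 1L
    } else if (ch %in% .SKELETON_CHARS) {
      seg <- paste0(seg, ch)
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", smiles)
    }
  }
  segments <- c(segments, seg)
  tokens <- data.frame(symbol = symbol, element = element,
                       atom_index = seq_along(symbol) - 1L,
                       start = start, end = end,
                       stringsAsFactors = FALSE)
  if (nrow(tokens) > 0L && !all(tokens$element %in% .VALID_ELEMENTS))
    stop("unknown element symbol in SMILES: ",
         tokens$element[!tokens$element %in% .VALID_ELEMENTS][1])
  list(tokens = tokens, skeleton = segments)
}

# Element of a bracket atom body such as "[O-]", "[13CH4]", "[nH]".
.bracket_element <- function(body, smiles) {
  inner <- sub("^\\[([0-9]*)(.*)\\]$", "\\2", body)
  m <- regmatches(inner, regexpr("^([A-Z][a-z]?|se|as|[bcnops])", inner))
  if (length(m) == 0L || !nzchar(m))
    stop("cannot parse bracket atom '", body, "' in SMILES: ", smiles)
  el <- m
  if (el %in% c("se", "as") || el %in% .AROMATIC_ONE) {
    el <- paste0(toupper(substr(el, 1, 1)), substring(el, 2))
  }
  # A two-letter match like "Cl" may actually be element + chirality ("C@").
  if (nchar(el) == 2 && !(el %in% .VALID_ELEMENTS))
    el <- substr(el, 1, 1)
  el
}

#' Gasteiger partial charges for SMILES molecules
#'
#' The default charge provider. Charges are computed by the Open Babel
#' toolkit (Gasteiger-Marsili electronegativity equalization) by converting
#' each molecule to MOL2, a format Open Babel annotates with Gasteiger
#' charges, and reading the per-atom charge column. Atom order in the MOL2
#' block follows the order of appearance in the SMILES string, so the i-th
#' charge belongs to the i-th atom token.
#'
#' Alternative charge models can be supplied anywhere a
#' \code{charge_provider} argument is accepted: any function mapping a
#' character vector of SMILES to a list of numeric per-atom charge vectors
#' satisfies the contract.
#'
#' @param smiles character vector of SMILES strings.
#' @return a list of numeric vectors, one per molecule, one charge per
#'   heavy atom (explicit bracket hydrogens included), in SMILES atom order.
#' @examples
#' gasteiger_charges("CCO")[[1]]  # oxygen carries the negative charge
#' @export
gasteiger_charges <- function(smiles) {
  if (length(smiles) == 0L) return(list())
  out <- ChemmineOB::convertFormat(
    "SMI", "MOL2", paste0(paste(smiles, collapse = "\n"), "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  mol_starts <- which(lines == "@<TRIPOS>MOLECULE")
  if (length(mol_starts) != length(smiles))
    stop("charge computation failed: expected ", length(smiles),
         " molecules, toolkit returned ", length(mol_starts))
  bounds <- c(mol_starts, length(lines) + 1L)
  lapply(seq_along(smiles), function(k) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    a <- which(block == "@<TRIPOS>ATOM")
    if (length(a) != 1L)
      stop("charge computation failed for SMILES: ", smiles[k])
    rest <- block[(a + 1L):length(block)]
    stop_at <- grep("^@<TRIPOS>", rest)
    if (length(stop_at)) rest <- rest[seq_len(stop_at[1] - 1L)]
    rest <- rest[nzchar(trimws(rest))]
    if (length(rest) == 0L) return(numeric(0))
    fields <- strsplit(trimws(rest), "[[:space:]]+")
    vapply(fields, function(f) as.numeric(f[9]), numeric(1))
  })
}

#' Compute a charge blueprint for one molecule
#'
#' A charge blueprint is a molecule reduced to its ordered atom tokens, one
#' partial charge per token, and the skeleton of non-atomic characters
#' needed to reassemble the canonical SMILES. Alignment operates on the
#' charge vector alone; the skeleton is used by [reinsert()] to put the
#' stripped characters back after alignment.
#'
#' Atoms whose charge is non-finite (NaN or infinite, which charge models
#' can produce on unusual valence states) are removed from the blueprint
#' with a per-atom warning naming the molecule; their skeleton slots
#' collapse.
#'
#' @param smiles a SMILES string (canonicalized internally).
#' @param charge_provider a function mapping a character vector of SMILES to
#'   a list of per-atom numeric charge vectors; defaults to
#'   [gasteiger_charges()].
#' @param id molecule identifier used in messages and reports.
#' @return an object of class \code{charge_blueprint}: a list with elements
#'   \code{molecule_id}, \code{canonical_smiles}, \code{tokens} (data.frame
#'   as in [tokenize_atoms()]), \code{charges}, and \code{skeleton}.
#' @examples
#' bp <- compute_blueprint("OC(=O)CC(=O)C(=O)O", id = "oxaloacetate")
#' length(bp$charges)  # 9 heavy atoms
#' @export
compute_blueprint <- function(smiles, charge_provider = gasteiger_charges,
                              id = smiles) {
  if (is.character(smiles) && length(smiles) == 1L && !is.na(smiles) &&
      !nzchar(smiles)) {
    return(.empty_blueprint(id))
  }
  can <- canonicalize(smiles)
  tk <- tokenize_atoms(can)
  charges <- tryCatch(charge_provider(can)[[1]],
                      error = function(e) stop("charge computation failed for '",
                                               id, "': ", conditionMessage(e)))
  if (length(charges) != nrow(tk$tokens))
    stop("charge provider returned ", length(charges), " charges for ",
         nrow(tk$tokens), " atom tokens (molecule '", id, "')")
  bad <- !is.finite(charges)
  if (any(bad)) {
    for (k in which(bad))
      warning("molecule '", id, "': atom ", k - 1L, " (",
              tk$tokens$element[k], ") has non-finite charge; removed",
              call. = FALSE)
    tk <- .drop_atoms(tk, which(bad))
    charges <- charges[!bad]
  }
  if (length(charges) == 0L)
    stop("all atoms of molecule '", id, "' were filtered out (empty blueprint)")
  structure(list(molecule_id = id, canonical_smiles = can,
                 tokens = tk$tokens, charges = charges,
                 skeleton = tk$skeleton),
            class = "charge_blueprint")
}

.empty_blueprint <- function(id) {
  structure(list(molecule_id = id, canonical_smiles = "",
                 tokens = data.frame(symbol = character(0),
                                     element = character(0),
                                     atom_index = integer(0),
                                     start = integer(0), end = integer(0),
                                     stringsAsFactors = FALSE),
                 charges = numeric(0), skeleton = ""),
            class = "charge_blueprint")
}

# Remove atom tokens (1-based positions) and collapse their skeleton slots.
.drop_atoms <- function(tk, drop) {
  seg <- tk$skeleton
  for (k in rev(sort(drop))) {
    seg[k] <- paste0(seg[k], seg[k + 1L])
    seg <- seg[-(k + 1L)]
  }
  tokens <- tk$tokens[-drop, , drop = FALSE]
  if (nrow(tokens)) tokens$atom_index <- seq_len(nrow(tokens)) - 1L
  rownames(tokens) <- NULL
  list(tokens = tokens, skeleton = seg)
}

#' Compute charge blueprints for a set of molecules
#'
#' Batch variant of [compute_blueprint()]; canonicalization and charge
#' computation are performed in single toolkit calls.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids molecule identifiers (defaults to the SMILES themselves).
#' @inheritParams compute_blueprint
#' @return a list of \code{charge_blueprint} objects.
#' @export
compute_blueprints <- function(smiles, ids = smiles,
                               charge_provider = gasteiger_charges) {
  stopifnot(length(smiles) == length(ids))
  cans <- canonicalize(smiles)
  all_charges <- charge_provider(cans)
  lapply(seq_along(smiles), function(k) {
    compute_blueprint(cans[k],
                      charge_provider = function(s) all_charges[k],
                      id = ids[k])
  })
}

#' Reinsert stripped characters into a gapped alignment
#'
#' After alignment, the skeleton characters removed by [tokenize_atoms()]
#' are put back around the aligned atom tokens, and gap columns are rendered
#' as \code{gap_symbol}. Because \code{"-"} is also a SMILES bond character,
#' the result is a display string, not necessarily a parseable SMILES.
#'
#' @param alignment_tokens character vector of aligned token symbols with
#'   \code{NA} at gap positions.
#' @param blueprint the \code{charge_blueprint} the tokens came from.
#' @param gap_symbol single character used to render gaps.
#' @return the canonical SMILES with gap symbols inserted; with zero gaps
#'   the output equals \code{blueprint$canonical_smiles} exactly.
#' @export
reinsert <- function(alignment_tokens, blueprint, gap_symbol = "-") {
  stopifnot(inherits(blueprint, "charge_blueprint"))
  alignment_tokens <- as.character(alignment_tokens)
  real <- alignment_tokens[!is.na(alignment_tokens)]
  if (!identical(unname(real), unname(blueprint$tokens$symbol)))
    stop("inconsistent alignment: tokens with gaps removed do not match ",
         "the blueprint of '", blueprint$molecule_id, "'")
  out <- blueprint$skeleton[1]
  k <- 1L
  for (tok in alignment_tokens) {
    if (is.na(tok)) {
      out <- paste0(out, gap_symbol)
    } else {
      out <- paste0(out, tok, blueprint$skeleton[k + 1L])
      k <- k + 1L
    }
  }
  out
}

#' Oxygen-to-sulfur variants of a molecule
#'
#' Generates one variant per oxygen atom, each with exactly that oxygen
#' replaced by sulfur. Substitution happens on the parent's canonical
#' string; each variant is canonicalized only after the substitution, so
#' the variants probe how stable the canonical form is under a small,
#' chemically valid perturbation.
#'
#' @param smiles the parent SMILES.
#' @return character vector of canonical variant SMILES (empty if the
#'   molecule contains no oxygen).
#' @examples
#' oxygen_to_sulfur_variants("CCO")  # canonical form of "CCS"
#' @export
oxygen_to_sulfur_variants <- function(smiles) {
  can <- canonicalize(smiles)
  tk <- tokenize_atoms(can)
  ox <- which(tk$tokens$element == "O")
  if (length(ox) == 0L) return(character(0))
  vapply(ox, function(k) {
    sym <- tk$tokens$symbol[k]
    sub_sym <- if (sym == "O") "S" else if (sym == "o") "s"
      else sub("O", "S", sub("o", "s", sym))  # bracket atom body
    toks <- tk$tokens$symbol
    toks[k] <- sub_sym
    variant <- paste0(tk$skeleton[1],
                      paste0(toks, tk$skeleton[-1], collapse = ""))
    canonicalize(variant)
  }, character(1))
}

#' Canonicalization stability under oxygen-to-sulfur substitution
#'
#' For each parent molecule, generates its oxygen-to-sulfur variants and
#' summarizes how far the canonical SMILES strings move: the mean and
#' standard deviation (population) of the Levenshtein distance between the
#' parent's canonical string and each variant's, and of the Tanimoto
#' distance (1 - Tanimoto coefficient over FP2 path fingerprints). Large
#' Levenshtein jumps indicate that the canonicalizer reorders atoms under
#' small structural changes, which is exactly the failure mode that hurts
#' string-order-based alignment.
#'
#' @param parents character vector of parent SMILES (each with at least one
#'   oxygen; parents without oxygen are excluded with a warning).
#' @param ids parent identifiers.
#' @return a data.frame with columns \code{parent_id}, \code{n_variants},
#'   \code{mean_levenshtein}, \code{std_levenshtein},
#'   \code{mean_tanimoto_distance}, \code{std_tanimoto_distance}.
#' @export
canonization_stability <- function(parents, ids = parents) {
  stopifnot(length(parents) == length(ids))
  rows <- lapply(seq_along(parents), function(k) {
    variants <- oxygen_to_sulfur_variants(parents[k])
    if (length(variants) == 0L) {
      warning("parent '", ids[k], "' has no oxygen; excluded from report",
              call. = FALSE)
      return(NULL)
    }
    can <- canonicalize(parents[k])
    lev <- as.numeric(utils::adist(can, variants))
    tani <- vapply(variants, function(v)
      1 - tanimoto_coefficient(can, v), numeric(1))
    data.frame(parent_id = ids[k], n_variants = length(variants),
               mean_levenshtein = mean(lev), std_levenshtein = .pop_sd(lev),
               mean_tanimoto_distance = mean(tani),
               std_tanimoto_distance = .pop_sd(tani),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(parent_id = character(0), n_variants = integer(0),
                      mean_levenshtein = numeric(0),
                      std_levenshtein = numeric(0),
                      mean_tanimoto_distance = numeric(0),
                      std_tanimoto_distance = numeric(0))
  rownames(out) <- NULL
  out
}

# Population (divide-by-N) standard deviation; single values give 0.
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Read molecules from a file
#'
#' Accepts either a plain-text file with one SMILES per line (optionally
#' followed by a tab-separated id column, the \code{.smi} convention) or a
#' CSV file with header columns \code{id,smiles}.
#'
#' @param path file path.
#' @return data.frame with columns \code{id} and \code{smiles}.
#' @export
read_smiles_file <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(df)))
      stop("CSV molecule file must have header columns id,smiles: ", path)
    return(df[, c("id", "smiles")])
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, character(1), 1)
  id <- vapply(parts, function(p) if (length(p) >= 2L) p[2] else p[1],
               character(1))
  data.frame(id = id, smiles = smi, stringsAsFactors = FALSE)
}

#' @export
print.charge_blueprint <- function(x, ...) {
  cat("charge_blueprint '", x$molecule_id, "'\n", sep = "")
  cat("  canonical SMILES: ", x$canonical_smiles, "\n", sep = "")
  cat("  atoms: ", nrow(x$tokens), " (",
      paste(x$tokens$element, collapse = " "), ")\n", sep = "")
  cat("  charges: ", paste(sprintf("%.3f", x$charges), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
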