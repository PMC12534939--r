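# Bundled molecule sets and a seeded random-SMILES generator, so every
# other module is testable offline.

.CORPORA <- list(
  krebs      = list(file = "krebs.tsv",      cyclic = TRUE),
  glycolysis = list(file = "glycolysis.tsv", cyclic = FALSE),
  ppp        = list(file = "ppp.tsv",        cyclic = TRUE),
  demo       = list(file = "demo.tsv",       cyclic = FALSE))

#' Bundled molecule corpora
#'
#' Versioned small-molecule sets shipped with the package:
#' \describe{
#'   \item{krebs}{the seven primary metabolites of the Krebs cycle
#'     (coenzymes excluded), in cycle order starting at oxaloacetate.}
#'   \item{glycolysis}{the ten glycolytic metabolites in order from glucose
#'     to pyruvate.}
#'   \item{ppp}{eight pentose-phosphate-pathway metabolites, treated as a
#'     cycle.}
#'   \item{demo}{ten small common molecules for examples and tests.}
#' }
#' The pathway SMILES are reconstructions of standard textbook metabolite
#' structures (neutral protonation states, no stereo descriptors), not
#' copies of any external pathway database export; the provenance note in
#' each file records this.
#'
#' @param name one of \code{"krebs"}, \code{"glycolysis"}, \code{"ppp"},
#'   \code{"demo"}.
#' @return data.frame with columns \code{id} and \code{smiles}, in pathway
#'   order, with attributes \code{name} and \code{cyclic}.
#' @export
builtin_corpus <- function(name) {
  if (!name %in% names(.CORPORA))
    stop("unknown corpus '", name, "'; available: ",
         paste(names(.CORPORA), collapse = ", "))
  info <- .CORPORA[[name]]
  path <- system.file("extdata", info$file, package = "smialign",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  df <- df[order(df$order), c("id", "smiles")]
  rownames(df) <- NULL
  attr(df, "name") <- name
  attr(df, "cyclic") <- info$cyclic
  df
}

#' Bundled pathway objects
#'
#' [builtin_corpus()] wrapped into a [pathway()] with the appropriate
#' cyclic/linear flag.
#'
#' @inheritParams builtin_corpus
#' @return a [pathway()] object.
#' @export
builtin_pathway <- function(name) {
  df <- builtin_corpus(name)
  pathway(df$id, df$smiles, cyclic = attr(df, "cyclic"), name = name)
}

.GEN_ELEMENTS <- c("C", "O", "N", "S")
.GEN_WEIGHTS <- c(0.6, 0.16, 0.14, 0.1)
.GEN_VALENCE <- c(C = 4L, O = 2L, N = 3L, S = 2L)

# One random atom subtree; bond_used is the valence consumed by the bond to
# the parent (1 or 2). Returns list(smiles, used).
.gen_subtree <- function(budget, bond_used) {
  ok <- .GEN_VALENCE[.GEN_ELEMENTS] >= bond_used
  el <- sample(.GEN_ELEMENTS[ok], 1L, prob = .GEN_WEIGHTS[ok])
  spare <- .GEN_VALENCE[[el]] - bond_used
  used <- 1L
  kids <- character(0)
  while (spare >= 1L && used < budget && stats::runif(1) < 0.65) {
    dbl <- spare >= 2L && stats::runif(1) < 0.2
    bond <- if (dbl) 2L else 1L
    child <- .gen_subtree(budget - used, bond)
    kids <- c(kids, paste0(if (dbl) "=" else "", child$smiles))
    used <- used + child$used
    spare <- spare - bond
  }
  body <- if (length(kids) == 0L) el
    else paste0(el,
                paste0(vapply(kids[-length(kids)],
                              function(k) paste0("(", k, ")"), character(1)),
                       collapse = ""),
                kids[length(kids)])
  list(smiles = body, used = used)
}

# One random monocycle of r atoms (all single bonds, at most one
# heteroatom so the ring stays chemically tame).
.gen_ring <- function(r) {
  els <- rep("C", r)
  if (stats::runif(1) < 0.5)
    els[sample(r, 1L)] <- sample(c("O", "N", "S"), 1L)
  paste0(els[1], "1", paste(els[-1], collapse = ""), "1")
}

#' Seeded random SMILES generator
#'
#' Grammar-based generator of valid small molecules over C, O, N and S with
#' single/double bonds and branches (acyclic trees) and, optionally,
#' plain monocycles. Valence is tracked during generation, so every output
#' is a legal SMILES by construction; the generator never emits charged or
#' bracket atoms. Deterministic for a fixed seed (the caller's RNG state is
#' saved and restored).
#'
#' @param seed integer seed.
#' @param n number of molecules.
#' @param max_heavy_atoms largest molecule size.
#' @param allow_rings permit monocyclic outputs.
#' @return character vector of \code{n} SMILES strings.
#' @examples
#' random_smiles(1, 5, max_heavy_atoms = 6)
#' @export
random_smiles <- function(seed, n, max_heavy_atoms = 8, allow_rings = TRUE) {
  stopifnot(n >= 1, max_heavy_atoms >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  vapply(seq_len(n), function(k) {
    size <- sample.int(max_heavy_atoms, 1L)
    if (allow_rings && size >= 3L && stats::runif(1) < 0.3) {
      .gen_ring(2L + sample.int(min(size, 6L) - 2L, 1L))
    } else {
      .gen_subtree(size, 0L)$smiles
    }
  }, character(1))
}
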