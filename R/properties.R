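# Physicochemical scales, distance matrices and codon counts backing the
# TPAAC, APAAC, SOCNumber and QSOrder encoders. All tables live as
# plain-text TSV under inst/extdata with residues in the fixed
# alphabetical order A,C,D,...,Y and are cached after first read.

.tables <- new.env(parent = emptyenv())

extdata <- function(file) {
  p <- system.file("extdata", file, package = "bitterpep")
  if (p == "") stop("shipped table not found: ", file)
  p
}

#' Raw per-residue physicochemical scales
#'
#' The three scales underlying the pseudo-amino-acid compositions:
#' hydrophobicity, hydrophilicity (Hopp-Woods) and side-chain mass, as
#' used throughout the classic PseAAC lineage. Values are read from the
#' shipped TSV so encoder outputs are reproducible bit-for-bit against the
#' packaged files; a different published variant of a scale can be
#' supplied to the encoders via [normalize_scale()].
#'
#' @param normalized if `TRUE` (default) each scale is centred to mean 0
#'   and divided by the root mean squared deviation over the 20 residues
#'   (see [normalize_scale()]).
#' @return Named list with numeric vectors `hydrophobicity`,
#'   `hydrophilicity`, `side_chain_mass`, each of length 20 named by
#'   residue.
#' @export
aa_scales <- function(normalized = TRUE) {
  key <- if (normalized) "scales_norm" else "scales_raw"
  if (!is.null(.tables[[key]])) return(.tables[[key]])
  tab <- read.delim(extdata("aa_scales.tsv"), stringsAsFactors = FALSE)
  out <- lapply(tab[-1], function(v) stats::setNames(v, tab$residue))
  if (normalized) out <- lapply(out, normalize_scale)
  .tables[[key]] <- out
  out
}

#' Standard-normal scale normalization
#'
#' Centres a 20-residue property scale to mean zero and scales it by the
#' root of the mean squared deviation, so that the normalized values have
#' mean 0 and unit mean-square. The transform is idempotent and invariant
#' under positive affine changes of the raw scale.
#'
#' @param raw named numeric vector with one value per standard residue.
#' @return Normalized vector in the same residue order.
#' @export
normalize_scale <- function(raw) {
  if (length(raw) != 20 || !all(sort(names(raw)) == AA_ALPHABET))
    stop("a residue scale needs exactly the 20 standard residues as names")
  d <- raw - mean(raw)
  denom <- sqrt(mean(d^2))
  if (denom == 0) stop("constant scale cannot be normalized (zero denominator)")
  d / denom
}

#' Three-property residue correlation
#'
#' The type-1 pseudo-amino-acid correlation between residues `r_i` and
#' `r_j`: the mean of the squared differences of normalized
#' hydrophobicity, hydrophilicity and side-chain mass. Symmetric,
#' nonnegative and zero exactly on identical residues. `scale_subset`
#' generalises to any subset of the three scales (mean over `k` squared
#' differences), an extension hook not used by the default TPAAC.
#'
#' @param r_i,r_j standard one-letter residue codes (vectorized).
#' @param scales normalized scales as returned by [aa_scales()].
#' @param scale_subset character vector naming which scales enter the mean.
#' @return Numeric vector of correlations.
#' @export
correlation_theta <- function(r_i, r_j, scales = aa_scales(),
                              scale_subset = names(scales)) {
  check_residues(c(r_i, r_j))
  sq <- lapply(scales[scale_subset], function(s) (s[r_i] - s[r_j])^2)
  unname(Reduce(`+`, sq) / length(sq))
}

#' Hydrophobicity and hydrophilicity product correlations
#'
#' The amphiphilic correlation pair: products of the normalized
#' hydrophobicity values and of the normalized hydrophilicity values of
#' two residues.
#'
#' @inheritParams correlation_theta
#' @return For scalar input, a named vector `c(H1 = , H2 = )`; for vector
#'   input a 2-row matrix.
#' @export
hydro_correlations <- function(r_i, r_j, scales = aa_scales()) {
  check_residues(c(r_i, r_j))
  h1 <- unname(scales$hydrophobicity[r_i] * scales$hydrophobicity[r_j])
  h2 <- unname(scales$hydrophilicity[r_i] * scales$hydrophilicity[r_j])
  if (length(h1) == 1) c(H1 = h1, H2 = h2) else rbind(H1 = h1, H2 = h2)
}

check_residues <- function(r) {
  bad <- setdiff(r, AA_ALPHABET)
  if (length(bad)) stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Inter-residue distance matrices
#'
#' The two 20x20 distance matrices consumed by the sequence-order
#' encoders, keyed `SchneiderWrede` and `Grantham`:
#' \itemize{
#' \item `Grantham`: the chemical distance computed from Grantham's
#'   composition/polarity/volume formula with the published constants,
#'   mean-normalized to 100 and rounded to integers (entries may differ by
#'   one unit from some printed versions of the table).
#' \item `SchneiderWrede`: a synthetic physicochemical distance matrix
#'   built from the three shipped normalized scales (root mean squared
#'   scale difference, rescaled to a maximum of 1), shipped as
#'   `schneider_wrede_synthetic.tsv`. It plays the role the
#'   Schneider-Wrede matrix plays in quasi-sequence-order descriptors;
#'   users holding the published matrix can replace the TSV, which uses
#'   the documented residue order.
#' }
#' Both matrices are symmetric with zero diagonals.
#'
#' @param normalize `"none"` (default) returns the matrices on their
#'   shipped scales; `"max"` divides each matrix by its largest entry.
#' @return Named list of two 20x20 numeric matrices.
#' @export
aa_distance_matrices <- function(normalize = c("none", "max")) {
  normalize <- match.arg(normalize)
  key <- paste0("dist_", normalize)
  if (!is.null(.tables[[key]])) return(.tables[[key]])
  read_dist <- function(file) {
    tab <- read.delim(extdata(file), check.names = FALSE,
                      stringsAsFactors = FALSE)
    m <- as.matrix(tab[-1])
    rownames(m) <- tab$residue
    storage.mode(m) <- "double"
    m[AA_ALPHABET, AA_ALPHABET]
  }
  out <- list(SchneiderWrede = read_dist("schneider_wrede_synthetic.tsv"),
              Grantham = read_dist("grantham.tsv"))
  if (normalize == "max") out <- lapply(out, function(m) m / max(m))
  .tables[[key]] <- out
  out
}

#' Sense-codon counts per amino acid
#'
#' Codon multiplicities of the standard genetic code, excluding the three
#' stop codons; the counts sum to 61. Used by the dipeptide deviation
#' from expected mean (DDE) encoder as the background expectation.
#'
#' @return Named integer vector of length 20.
#' @export
codon_counts <- function() {
  c(A = 4L, C = 2L, D = 2L, E = 2L, F = 2L, G = 4L, H = 2L, I = 3L,
    K = 2L, L = 6L, M = 1L, N = 2L, P = 4L, Q = 2L, R = 6L, S = 6L,
    T = 4L, V = 4L, W = 1L, Y = 2L)
}
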