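# The ten descriptor families, each a pure function from one peptide
# sequence to a named numeric feature vector. Component order is fixed:
# residues alphabetical A..Y, dipeptides row-major (first residue outer),
# groups g1..g5, distance-matrix blocks SchneiderWrede then Grantham.

ENCODER_ORDER <- c("AAC", "TPAAC", "APAAC", "ASDC", "DPC", "DDE",
                   "GAAC", "GDPC", "SOCNumber", "QSOrder")

# residue group scheme: aliphatic, aromatic, positive, negative, uncharged
AA_GROUPS <- list(g1 = c("G", "A", "V", "L", "M", "I"),
                  g2 = c("F", "Y", "W"),
                  g3 = c("K", "R", "H"),
                  g4 = c("D", "E"),
                  g5 = c("S", "T", "C", "P", "N", "Q"))

dipeptide_names <- function(alphabet = AA_ALPHABET)
  as.vector(t(outer(alphabet, alphabet, paste0)))

seq_chars <- function(sequence, min_len = 2) {
  if (!is.character(sequence) || length(sequence) != 1)
    stop("`sequence` must be a single character string")
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  check_residues(s)
  if (length(s) < min_len)
    stop("peptide must have at least ", min_len, " residues")
  s
}

#' Encoder parameters
#'
#' Tunable parameters shared by the sequence-order encoders. The defaults
#' are the values used for the 1,337-dimensional fused representation:
#' `lambda = 1` correlation tier for the pseudo-amino-acid compositions
#' (dimensions 21 and 22), weighting factors `omega_tpaac = 0.05`,
#' `w_apaac = 0.5` and `w_qsorder = 0.1`, and `nlag = 1` lag for the
#' sequence-order-coupling descriptors (dimensions 2 and 42). `lambda`
#' and `nlag` must stay below the length of every peptide encoded, which
#' the encoders check at encode time.
#'
#' @param lambda positive integer, number of pseudo-composition tiers.
#' @param omega_tpaac positive weight of the TPAAC pseudo-components.
#' @param w_apaac positive weight of the APAAC amphiphilic components.
#' @param w_qsorder positive weight of the quasi-sequence-order couplings.
#' @param nlag positive integer, maximum sequence-order lag.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(lambda = 1L, omega_tpaac = 0.05, w_apaac = 0.5,
                           w_qsorder = 0.1, nlag = 1L) {
  lambda <- as.integer(lambda); nlag <- as.integer(nlag)
  if (lambda < 1L || nlag < 1L) stop("`lambda` and `nlag` must be >= 1")
  if (omega_tpaac <= 0 || w_apaac <= 0 || w_qsorder <= 0)
    stop("weighting factors must be > 0")
  structure(list(lambda = lambda, omega_tpaac = omega_tpaac,
                 w_apaac = w_apaac, w_qsorder = w_qsorder, nlag = nlag),
            class = "encoder_config")
}

as_feature_vector <- function(values, encoder) {
  stopifnot(!anyDuplicated(names(values)), all(is.finite(values)))
  attr(values, "encoder") <- encoder
  values
}

#' Amino acid composition (AAC)
#'
#' Frequency of each of the 20 residues: `f(t) = N(t) / N`. Components
#' sum to 1 and are invariant under residue permutation.
#'
#' @param sequence a peptide sequence (character scalar).
#' @return Named numeric vector of 20 components.
#' @export
encode_aac <- function(sequence) {
  s <- seq_chars(sequence)
  counts <- table(factor(s, levels = AA_ALPHABET))
  f <- stats::setNames(as.vector(counts) / length(s), AA_ALPHABET)
  as_feature_vector(f, "AAC")
}

# sequence-order correlation factors theta_j, j = 1..lambda
tpaac_thetas <- function(s, lambda, scales) {
  n <- length(s)
  vapply(seq_len(lambda), function(j) {
    i <- seq_len(n - j)
    mean(correlation_theta(s[i], s[i + j], scales))
  }, numeric(1))
}

#' Traditional pseudo-amino-acid composition (TPAAC, type-1 PseAAC)
#'
#' The 20 residue frequencies extended with `lambda` sequence-order
#' correlation factors built from the three-property residue correlation
#' ([correlation_theta()]). All `20 + lambda` components share one
#' denominator `sum(f) + omega * sum(theta)` and therefore sum to 1.
#'
#' @inheritParams encode_aac
#' @param cfg an [encoder_config()].
#' @param scales normalized scales, see [aa_scales()].
#' @return Named numeric vector of `20 + lambda` components.
#' @export
encode_tpaac <- function(sequence, cfg = encoder_config(),
                         scales = aa_scales()) {
  s <- seq_chars(sequence)
  if (length(s) <= cfg$lambda)
    stop("peptide length must exceed lambda = ", cfg$lambda)
  f <- encode_aac(sequence)
  theta <- tpaac_thetas(s, cfg$lambda, scales)
  denom <- sum(f) + cfg$omega_tpaac * sum(theta)
  out <- c(f / denom, cfg$omega_tpaac * theta / denom)
  names(out) <- c(AA_ALPHABET, paste0("lambda", seq_len(cfg$lambda)))
  as_feature_vector(out, "TPAAC")
}

#' Amphiphilic pseudo-amino-acid composition (APAAC)
#'
#' The 20 residue frequencies extended with `2 * lambda` amphiphilic
#' correlation factors: for each lag, the mean hydrophobicity product and
#' the mean hydrophilicity product of residue pairs at that lag
#' (interleaved: hydrophobicity lag 1, hydrophilicity lag 1, ...). All
#' components share one denominator and sum to 1; amphiphilic components
#' can be negative since the products are signed.
#'
#' @inheritParams encode_tpaac
#' @return Named numeric vector of `20 + 2 * lambda` components.
#' @export
encode_apaac <- function(sequence, cfg = encoder_config(),
                         scales = aa_scales()) {
  s <- seq_chars(sequence)
  n <- length(s)
  if (n <= cfg$lambda)
    stop("peptide length must exceed lambda = ", cfg$lambda)
  f <- encode_aac(sequence)
  tau <- numeric(2 * cfg$lambda)
  nm <- character(2 * cfg$lambda)
  for (a in seq_len(cfg$lambda)) {
    i <- seq_len(n - a)
    hh <- hydro_correlations(s[i], s[i + a], scales)
    hh <- if (is.matrix(hh)) rowMeans(hh) else hh
    tau[2 * a - 1] <- hh[["H1"]]
    tau[2 * a]     <- hh[["H2"]]
    nm[2 * a - 1] <- paste0("H1.lag", a)
    nm[2 * a]     <- paste0("H2.lag", a)
  }
  denom <- sum(f) + cfg$w_apaac * sum(tau)
  out <- c(f / denom, cfg$w_apaac * tau / denom)
  names(out) <- c(AA_ALPHABET, nm)
  as_feature_vector(out, "APAAC")
}

#' Adaptive skip dipeptide composition (ASDC)
#'
#' Frequencies of ordered residue pairs at every gap: for a peptide of
#' length N, component (a, b) counts the index pairs i < j with residue a
#' at i and b at j, divided by the total pair count N(N-1)/2. Components
#' sum to 1.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of 400 components.
#' @export
encode_asdc <- function(sequence) {
  s <- seq_chars(sequence)
  n <- length(s)
  counts <- stats::setNames(numeric(400), dipeptide_names())
  for (g in seq_len(n - 1)) {
    i <- seq_len(n - g)
    tab <- table(paste0(s[i], s[i + g]))
    counts[names(tab)] <- counts[names(tab)] + as.vector(tab)
  }
  as_feature_vector(counts / (n * (n - 1) / 2), "ASDC")
}

dipeptide_freq <- function(s, alphabet = AA_ALPHABET) {
  n <- length(s)
  nm <- dipeptide_names(alphabet)
  counts <- stats::setNames(numeric(length(nm)), nm)
  tab <- table(paste0(s[-n], s[-1]))
  counts[names(tab)] <- as.vector(tab)
  counts / (n - 1)
}

#' Dipeptide composition (DPC)
#'
#' Frequencies of the 400 adjacent residue pairs: `D(r, s) = N_rs / (N - 1)`.
#' Components sum to 1.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of 400 components.
#' @export
encode_dpc <- function(sequence) {
  s <- seq_chars(sequence)
  as_feature_vector(dipeptide_freq(s), "DPC")
}

#' Dipeptide deviation from expected mean (DDE)
#'
#' Standardizes each adjacent-dipeptide frequency against its expectation
#' under the standard genetic code: with codon counts `C_r` out of the
#' `C_N = 61` sense codons, the theoretical mean of pair (r, s) is
#' `T_m = (C_r / C_N)(C_s / C_N)` and its variance `T_v = T_m (1 - T_m) / (N - 1)`;
#' the component is `(D_c - T_m) / sqrt(T_v)`. Dipeptides absent from the
#' peptide get strictly negative components.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of 400 components.
#' @export
encode_dde <- function(sequence) {
  s <- seq_chars(sequence)
  n <- length(s)
  dc <- dipeptide_freq(s)
  cc <- codon_counts()
  cn <- sum(cc)
  first <- substr(names(dc), 1, 1)
  second <- substr(names(dc), 2, 2)
  tm <- (cc[first] / cn) * (cc[second] / cn)
  tv <- tm * (1 - tm) / (n - 1)
  as_feature_vector(stats::setNames((dc - tm) / sqrt(tv), names(dc)), "DDE")
}

residue_groups <- function(s) {
  map <- stats::setNames(rep(names(AA_GROUPS), lengths(AA_GROUPS)),
                         unlist(AA_GROUPS))
  unname(map[s])
}

#' Grouped amino acid composition (GAAC)
#'
#' Frequencies of five physicochemical residue groups: aliphatic
#' (g1 = GAVLMI), aromatic (g2 = FYW), positively charged (g3 = KRH),
#' negatively charged (g4 = DE) and uncharged polar (g5 = STCPNQ).
#' Components sum to 1.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of 5 components.
#' @export
encode_gaac <- function(sequence) {
  s <- seq_chars(sequence)
  g <- residue_groups(s)
  counts <- table(factor(g, levels = names(AA_GROUPS)))
  as_feature_vector(stats::setNames(as.vector(counts) / length(s),
                                    names(AA_GROUPS)), "GAAC")
}

#' Grouped dipeptide composition (GDPC)
#'
#' Adjacent dipeptide composition over the five-group alphabet of
#' [encode_gaac()]: 25 components summing to 1.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of 25 components.
#' @export
encode_gdpc <- function(sequence) {
  s <- seq_chars(sequence)
  g <- residue_groups(s)
  as_feature_vector(dipeptide_freq(g, names(AA_GROUPS)), "GDPC")
}

soc_taus <- function(s, nlag, dmat) {
  n <- length(s)
  vapply(seq_len(nlag), function(d) {
    i <- seq_len(n - d)
    sum(dmat[cbind(s[i], s[i + d])]^2)
  }, numeric(1))
}

#' Sequence-order-coupling numbers (SOCNumber)
#'
#' For each distance matrix (SchneiderWrede block first, then Grantham)
#' and each lag d = 1..nlag, the coupling number
#' `tau_d = sum_i d(s_i, s_{i+d})^2`. Homopolymers give zero couplings
#' since the matrix diagonals are zero.
#'
#' @inheritParams encode_tpaac
#' @param distances list of distance matrices, see [aa_distance_matrices()].
#' @return Named numeric vector of `2 * nlag` components.
#' @export
encode_socnumber <- function(sequence, cfg = encoder_config(),
                             distances = aa_distance_matrices()) {
  s <- seq_chars(sequence)
  if (length(s) <= cfg$nlag)
    stop("peptide length must exceed nlag = ", cfg$nlag)
  out <- unlist(lapply(names(distances), function(m) {
    stats::setNames(soc_taus(s, cfg$nlag, distances[[m]]),
                    paste0(m, ".lag", seq_len(cfg$nlag)))
  }))
  as_feature_vector(out, "SOCNumber")
}

#' Quasi-sequence-order descriptors (QSOrder)
#'
#' Per distance matrix, a block of 20 residue components followed by
#' `nlag` coupling components, all sharing the denominator
#' `sum(f) + w * sum(tau)`; each block sums to 1. Blocks are ordered
#' SchneiderWrede then Grantham.
#'
#' @inheritParams encode_socnumber
#' @return Named numeric vector of `2 * (20 + nlag)` components.
#' @export
encode_qsorder <- function(sequence, cfg = encoder_config(),
                           distances = aa_distance_matrices()) {
  s <- seq_chars(sequence)
  if (length(s) <= cfg$nlag)
    stop("peptide length must exceed nlag = ", cfg$nlag)
  f <- encode_aac(sequence)
  out <- unlist(lapply(names(distances), function(m) {
    tau <- soc_taus(s, cfg$nlag, distances[[m]])
    denom <- sum(f) + cfg$w_qsorder * sum(tau)
    stats::setNames(c(f / denom, cfg$w_qsorder * tau / denom),
                    paste0(m, ".", c(AA_ALPHABET,
                                     paste0("lag", seq_len(cfg$nlag)))))
  }))
  as_feature_vector(out, "QSOrder")
}

#' Apply all ten encoders
#'
#' Encodes one peptide with the ten descriptor families in the fixed
#' order AAC, TPAAC, APAAC, ASDC, DPC, DDE, GAAC, GDPC, SOCNumber,
#' QSOrder. At the default parameters the per-encoder dimensions are
#' 20, 21, 22, 400, 400, 400, 5, 25, 2, 42 — 1,337 components in total.
#'
#' @inheritParams encode_tpaac
#' @return Named list of ten feature vectors, in encoder order.
#' @export
encode_all <- function(sequence, cfg = encoder_config()) {
  list(AAC = encode_aac(sequence),
       TPAAC = encode_tpaac(sequence, cfg),
       APAAC = encode_apaac(sequence, cfg),
       ASDC = encode_asdc(sequence),
       DPC = encode_dpc(sequence),
       DDE = encode_dde(sequence),
       GAAC = encode_gaac(sequence),
       GDPC = encode_gdpc(sequence),
       SOCNumber = encode_socnumber(sequence, cfg),
       QSOrder = encode_qsorder(sequence, cfg))
}
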