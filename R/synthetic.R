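# Synthetic labeled peptide fixtures with a controllable hydrophobic
# composition shift between classes.

#' Default hydrophobic residue set
#'
#' The aliphatic and aromatic residues driving the synthetic class
#' separation (the aliphatic group plus F and W); 8 of the 20 residues.
#' @export
HYDROPHOBIC_SET <- c("A", "V", "L", "I", "M", "F", "W", "G")

#' Generate a labeled synthetic peptide set
#'
#' Emulates the one structural property the classifier should pick up in
#' bitter peptides — enrichment for hydrophobic residues — while leaving
#' everything else uniform. Negatives draw residues uniformly from the
#' 20-letter alphabet; positives move probability mass `delta` from the
#' non-hydrophobic residues onto the hydrophobic set (uniformly within
#' each set), so the expected hydrophobic fraction of positives exceeds
#' the negatives' (8/20) by exactly `delta`. Lengths are uniform over
#' `length_range`; the default 2-15 covers typical oligopeptides and
#' exercises the short-peptide edge cases down to dipeptides. `delta = 0`
#' makes the classes exchangeable (a null dataset).
#'
#' @param n_per_class peptides per class.
#' @param length_range integer pair, inclusive; lower bound at least 2.
#' @param delta hydrophobic probability-mass shift in `[0, 0.6)`; values
#'   at or above `1 - 8/20 = 0.6` would leave the non-hydrophobic
#'   residues with negative mass and are rejected.
#' @param hydrophobic the enriched residue set.
#' @param seed integer seed; generation is fully deterministic given the
#'   configuration.
#' @return A labeled [peptide_set()], positives (`pos_*`) then negatives
#'   (`neg_*`).
#' @export
generate_peptides <- function(n_per_class = 320, length_range = c(2L, 15L),
                              delta = 0.3, hydrophobic = HYDROPHOBIC_SET,
                              seed = 1) {
  stopifnot(length(length_range) == 2, n_per_class >= 1)
  length_range <- as.integer(length_range)
  if (length_range[1] < 2 || length_range[2] < length_range[1])
    stop("`length_range` must be an increasing pair with lower bound >= 2")
  hydrophobic <- match.arg(hydrophobic, AA_ALPHABET, several.ok = TRUE)
  nh <- length(hydrophobic)
  other <- setdiff(AA_ALPHABET, hydrophobic)
  base_mass <- nh / 20
  if (delta < 0 || delta >= 1 - base_mass)
    stop(sprintf("`delta` must lie in [0, %.2f) for %d hydrophobic residues",
                 1 - base_mass, nh))
  p_pos <- stats::setNames(rep((1 - base_mass - delta) / length(other), 20),
                           AA_ALPHABET)
  p_pos[hydrophobic] <- (base_mass + delta) / nh
  draw <- function(n, prob) {
    len <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    vapply(len, function(l)
      paste(sample(AA_ALPHABET, l, replace = TRUE, prob = prob),
            collapse = ""), character(1))
  }
  with_seed(seed, {
    pos <- draw(n_per_class, p_pos)
    neg <- draw(n_per_class, rep(1 / 20, 20))
    peptide_set(c(paste0("pos_", seq_len(n_per_class)),
                  paste0("neg_", seq_len(n_per_class))),
                c(pos, neg),
                rep(c(1L, 0L), each = n_per_class))
  })
}

#' Write a synthetic benchmark to disk
#'
#' Emits two FASTA files (positives, negatives) and a TSV label file in
#' the layout the command-line interface consumes.
#'
#' @param x a labeled [peptide_set()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the three paths written.
#' @export
write_benchmark <- function(x, dir, prefix = "peptides") {
  stopifnot(inherits(x, "peptide_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sub <- function(i) peptide_set(x$id[i], x$sequence[i], x$label[i])
  paths <- c(
    positives = file.path(dir, paste0(prefix, "_positive.fasta")),
    negatives = file.path(dir, paste0(prefix, "_negative.fasta")),
    labels = file.path(dir, paste0(prefix, "_labels.tsv")))
  write_fasta(sub(which(x$label == 1L)), paths[["positives"]])
  write_fasta(sub(which(x$label == 0L)), paths[["negatives"]])
  write_labels(x, paths[["labels"]])
  invisible(paths)
}
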