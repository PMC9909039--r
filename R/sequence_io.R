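# Peptide container, FASTA I/O and stratified splitting.

#' Construct a peptide set
#'
#' A `peptide_set` is a data frame with columns `id`, `sequence` and
#' `label` (integer 1 = bitter/positive, 0 = non-bitter/negative, `NA` =
#' unlabeled). Sequences are uppercased and validated against the 20
#' standard one-letter residue codes; every peptide must be at least two
#' residues long, since the dipeptide descriptors and the lag-1
#' correlation factors are undefined for single residues.
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of peptide sequences.
#' @param label optional vector of binary labels (0/1, or `NA`).
#' @param on_invalid `"error"` (default) rejects any sequence containing a
#'   non-standard residue (B, Z, X, U, ...); `"drop"` silently removes the
#'   offending records instead.
#' @return An object of class `peptide_set`.
#' @export
peptide_set <- function(id, sequence, label = NULL,
                        on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("`id` and `sequence` must have equal length")
  if (anyDuplicated(id))
    stop("duplicate peptide ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (is.null(label)) label <- rep(NA_integer_, length(id))
  label <- as.integer(label)
  if (length(label) != length(id))
    stop("`label` must match the number of peptides")
  if (any(!is.na(label) & !label %in% c(0L, 1L)))
    stop("labels must be 0, 1 or NA")

  bad <- find_invalid_residue(sequence)
  short <- !is.na(sequence) & nchar(sequence) < 2
  if (any(!is.na(bad))) {
    if (on_invalid == "error") {
      k <- which(!is.na(bad))[1]
      stop(sprintf("invalid residue '%s' in record '%s'", bad[k], id[k]))
    }
    keep <- is.na(bad)
    id <- id[keep]; sequence <- sequence[keep]; label <- label[keep]
    short <- short[keep]
  }
  if (any(short)) {
    if (on_invalid == "error")
      stop(sprintf("sequence of record '%s' is shorter than 2 residues",
                   id[which(short)[1]]))
    keep <- !short
    id <- id[keep]; sequence <- sequence[keep]; label <- label[keep]
  }
  structure(
    data.frame(id = id, sequence = sequence, label = label,
               stringsAsFactors = FALSE),
    class = c("peptide_set", "data.frame"))
}

# first offending character per sequence, NA where clean
find_invalid_residue <- function(sequence) {
  vapply(sequence, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- ch[!ch %in% AA_ALPHABET]
    if (length(hit)) hit[1] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.peptide_set <- function(x, ...) {
  n <- nrow(x)
  npos <- sum(x$label == 1L, na.rm = TRUE)
  nneg <- sum(x$label == 0L, na.rm = TRUE)
  cat(sprintf("peptide_set: %d peptides (%d positive, %d negative, %d unlabeled)\n",
              n, npos, nneg, n - npos - nneg))
  if (n) {
    lens <- nchar(x$sequence)
    cat(sprintf("lengths %d-%d\n", min(lens), max(lens)))
  }
  invisible(x)
}

#' Read peptides from a FASTA file
#'
#' Multi-record FASTA, with wrapped or unwrapped sequence lines. Records
#' are returned in file order with sequences uppercased. A residue outside
#' the 20 standard codes raises an error naming the record and the
#' offending character.
#'
#' @param path path to a FASTA file.
#' @param label optional: a single 0/1 applied to every record, or the
#'   path to a TSV label file with columns `id` and `label`.
#' @param on_invalid see [peptide_set()].
#' @return A [peptide_set()]. An empty file yields an empty set.
#' @export
read_fasta <- function(path, label = NULL, on_invalid = c("error", "drop")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    return(peptide_set(character(0), character(0)))
  recs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(recs))
  seqs <- as.character(recs)
  lab <- NULL
  if (!is.null(label)) {
    if (is.character(label) && length(label) == 1 && file.exists(label)) {
      tab <- read.delim(label, header = TRUE, stringsAsFactors = FALSE)
      if (!all(c("id", "label") %in% names(tab)))
        stop("label file must have columns 'id' and 'label'")
      lab <- tab$label[match(ids, tab$id)]
    } else if (length(label) == 1) {
      lab <- rep(as.integer(label), length(ids))
    } else stop("`label` must be a single 0/1 or a TSV path")
  }
  peptide_set(ids, seqs, lab, on_invalid = match.arg(on_invalid))
}

#' Read a labeled benchmark from two FASTA files
#'
#' The primary labeled-input form: one FASTA of positive (bitter) peptides
#' and one of negative (non-bitter) peptides, as such benchmarks are
#' usually distributed.
#'
#' @param positives,negatives FASTA paths.
#' @inheritParams read_fasta
#' @return A labeled [peptide_set()]; positives first, in file order.
#' @export
read_fasta_pair <- function(positives, negatives,
                            on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  pos <- read_fasta(positives, label = 1L, on_invalid = on_invalid)
  neg <- read_fasta(negatives, label = 0L, on_invalid = on_invalid)
  bind_peptides(pos, neg)
}

bind_peptides <- function(...) {
  d <- do.call(rbind, lapply(list(...), as.data.frame))
  peptide_set(d$id, d$sequence, d$label)
}

#' Write peptides to FASTA
#'
#' Sequences are written unwrapped, one line per record.
#'
#' @param x a [peptide_set()].
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "peptide_set"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(x))
    writeLines(paste0(">", x$id, "\n", x$sequence), con)
  invisible(path)
}

#' Write a TSV label file
#'
#' Columns `id` and `label`, consumable by [read_fasta()].
#'
#' @param x a labeled [peptide_set()].
#' @param path output path.
#' @export
write_labels <- function(x, path) {
  stopifnot(inherits(x, "peptide_set"))
  write.table(x[, c("id", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stratified train/independent split
#'
#' Shuffles each class with a seeded generator and assigns the first
#' `round(train_fraction * n)` members of each class to the training
#' partition, so per-class training counts are exact up to rounding.
#' With 320 positives and 320 negatives at `train_fraction = 0.8` this
#' reproduces the canonical 256 + 256 training / 64 + 64 independent
#' benchmark split.
#'
#' @param x a fully labeled [peptide_set()] with both classes present.
#' @param train_fraction proportion assigned to training, in (0, 1).
#' @param seed integer seed; the same seed always yields the same split.
#' @return `list(train = , test = )` of disjoint peptide sets whose union
#'   is the input.
#' @export
stratified_split <- function(x, train_fraction = 0.8, seed = 1) {
  stopifnot(inherits(x, "peptide_set"))
  if (any(is.na(x$label)))
    stop("all peptides must be labeled for splitting")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be strictly between 0 and 1")
  counts <- table(factor(x$label, levels = c(0L, 1L)))
  if (any(counts < 2))
    stop("each class needs at least 2 members; got ",
         paste(counts, collapse = "/"))
  train_idx <- with_seed(seed, {
    unlist(lapply(c(1L, 0L), function(cl) {
      idx <- which(x$label == cl)
      idx <- sample(idx)
      idx[seq_len(round(train_fraction * length(idx)))]
    }))
  })
  train_idx <- sort(train_idx)
  sub <- function(i) peptide_set(x$id[i], x$sequence[i], x$label[i])
  list(train = sub(train_idx), test = sub(setdiff(seq_len(nrow(x)), train_idx)))
}
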