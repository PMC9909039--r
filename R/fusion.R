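# Fusion of the ten per-encoder vectors into one feature matrix, and the
# zero-column filter fitted on a reference matrix and re-applied to any
# compatible matrix (train-fitted by default to avoid leakage into the
# independent set).

#' Fuse the ten encoders into a feature matrix
#'
#' Encodes every peptide with [encode_all()] and concatenates the ten
#' vectors in fixed encoder order. Column names are qualified as
#' `encoder.component` (e.g. `AAC.A`, `DPC.AA`, `QSOrder.Grantham.lag1`),
#' so matrices are column-stable across runs. At default parameters the
#' matrix has exactly 1,337 columns.
#'
#' @param x a [peptide_set()].
#' @param cfg an [encoder_config()].
#' @return Numeric matrix, one row per peptide (rownames = ids), with a
#'   `labels` attribute carrying the peptide labels.
#' @export
fuse <- function(x, cfg = encoder_config()) {
  stopifnot(inherits(x, "peptide_set"))
  if (!nrow(x)) stop("cannot fuse an empty peptide set")
  rows <- lapply(seq_len(nrow(x)), function(i) {
    vecs <- tryCatch(encode_all(x$sequence[i], cfg),
                     error = function(e)
                       stop(sprintf("encoding failed for peptide '%s': %s",
                                    x$id[i], conditionMessage(e)),
                            call. = FALSE))
    unlist(lapply(names(vecs), function(e)
      stats::setNames(as.vector(vecs[[e]]),
                      paste0(e, ".", names(vecs[[e]])))))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- x$id
  attr(m, "labels") <- stats::setNames(x$label, x$id)
  m
}

#' Labels attached to a fused matrix
#' @param m a matrix produced by [fuse()].
#' @return Named integer vector of labels.
#' @export
fusion_labels <- function(m) attr(m, "labels")

#' Fit the zero-column filter
#'
#' Records which columns of a fitting matrix contain at least one nonzero
#' entry; all-zero columns carry no discriminative information and are
#' dropped when the schema is applied. Columns that are constant but
#' nonzero are kept.
#'
#' @param m numeric feature matrix with column names.
#' @param fitted_on optional character tag recording what the schema was
#'   fitted on (e.g. `"train"` or `"all"`).
#' @return A `fusion_schema` with the kept column names in original order.
#' @export
fit_zero_filter <- function(m, fitted_on = "train") {
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0)
    stop("need a nonempty feature matrix")
  if (is.null(colnames(m))) stop("feature matrix must have column names")
  keep <- colSums(m != 0) > 0
  structure(list(kept_columns = colnames(m)[keep],
                 n_input_columns = ncol(m),
                 n_fitting_rows = nrow(m),
                 fitted_on = fitted_on),
            class = "fusion_schema")
}

#' @export
print.fusion_schema <- function(x, ...) {
  cat(sprintf("fusion_schema: %d of %d columns kept (fitted on %s, %d rows)\n",
              length(x$kept_columns), x$n_input_columns, x$fitted_on,
              x$n_fitting_rows))
  invisible(x)
}

#' Apply a fusion schema
#'
#' Subsets a feature matrix to the schema's kept columns, in schema
#' order. A schema fitted on training data keeps the same columns when
#' applied to test data even if some are all-zero there, so train and
#' test matrices stay column-consistent.
#'
#' @param m numeric feature matrix whose columns are a superset of the
#'   schema's kept columns.
#' @param schema a [fit_zero_filter()] schema.
#' @return The filtered matrix; the `labels` attribute, if any, is kept.
#' @export
apply_schema <- function(m, schema) {
  stopifnot(inherits(schema, "fusion_schema"))
  missing <- setdiff(schema$kept_columns, colnames(m))
  if (length(missing))
    stop("schema mismatch: matrix lacks column(s) ",
         paste(utils::head(missing, 5), collapse = ", "))
  out <- m[, schema$kept_columns, drop = FALSE]
  attr(out, "labels") <- attr(m, "labels")
  out
}

#' Serialize / read a fusion schema as JSON
#' @param schema a `fusion_schema`.
#' @param path file path.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "fusion_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("kept_columns", "n_input_columns", "n_fitting_rows",
                "fitted_on")], class = "fusion_schema")
}

#' Write / read a feature matrix as CSV
#'
#' Round-trippable CSV with an `id` column, a `label` column when labels
#' are attached, and one column per qualified feature name.
#'
#' @param m a feature matrix (see [fuse()]).
#' @param path file path.
#' @export
write_feature_matrix <- function(m, path) {
  lab <- attr(m, "labels")
  d <- data.frame(id = rownames(m), check.names = FALSE)
  if (!is.null(lab)) d$label <- as.integer(lab)
  d <- cbind(d, as.data.frame(m, check.names = FALSE))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  has_lab <- "label" %in% names(d)
  feat <- setdiff(names(d), c("id", "label"))
  m <- as.matrix(d[feat])
  rownames(m) <- d$id
  if (has_lab) attr(m, "labels") <- stats::setNames(as.integer(d$label), d$id)
  m
}
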