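#' Construct a feature table
#'
#' A feature table is the dataset all fitness is computed on: a numeric
#' matrix of samples by named features plus a binary label per sample.
#' Labels are stored as a factor with levels `c("negative", "positive")`
#' (negative encodes class 0, positive class 1).
#'
#' @param values numeric matrix (rows = samples) with unique column names,
#'   or a data frame of numeric columns.
#' @param labels per-row labels; anything coercible to the two-level factor.
#' @return An object of class `feature_table` with fields `values` and
#'   `labels`.
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2,
#'                            dimnames = list(NULL, c("f1", "f2"))),
#'                     rep(c("positive", "negative"), 5))
#' ft
#' @export
feature_table <- function(values, labels) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    fsgp_error("values must be a numeric matrix", "fsgp_data_error")
  nm <- colnames(values)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    fsgp_error("values must have unique, non-empty column names",
               "fsgp_data_error")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    fsgp_error(sprintf("non-finite value at row %d, feature '%s'",
                       bad[1], nm[bad[2]]),
               "fsgp_parse_error")
  }
  labels <- encode_labels(labels)
  if (length(labels) != nrow(values))
    fsgp_error("labels length must equal the number of rows",
               "fsgp_data_error")
  structure(list(values = values, labels = labels), class = "feature_table")
}

# Map arbitrary two-valued labels onto factor(negative, positive).
encode_labels <- function(labels, positive_class = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      fsgp_error("numeric labels must be 0/1", "fsgp_data_error")
    labels <- ifelse(labels == 1, "positive", "negative")
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    fsgp_error(sprintf("labels must take exactly 2 values, found %d (%s)",
                       length(classes),
                       paste(utils::head(classes, 4), collapse = ", ")),
               "fsgp_data_error")
  if (is.null(positive_class)) {
    positive_class <- if ("positive" %in% classes) "positive" else classes[2]
  }
  if (!positive_class %in% classes)
    fsgp_error(sprintf("positive_class '%s' not present in labels",
                       positive_class),
               "fsgp_data_error")
  negative_class <- setdiff(classes, positive_class)
  factor(ifelse(labels == positive_class, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("feature table: %d samples x %d features (%d negative / %d positive)\n",
              nrow(x$values), ncol(x$values), tab[["negative"]],
              tab[["positive"]]))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.data.frame.feature_table <- function(x, ...,
                                        label_column = "label") {
  df <- as.data.frame(x$values)
  df[[label_column]] <- as.character(x$labels)
  df
}

#' Default EEG feature names
#'
#' `<channel>_<band>` names for the 14-channel, 5-band layout of the
#' consumer EEG headset the package's motivating data came from. Other
#' shapes get generic `ch<i>_b<j>` names; the algorithm only needs column
#' identity.
#'
#' @param n_channels,n_bands grid shape (defaults 14 x 5 = 70 features).
#' @return Character vector of length `n_channels * n_bands`.
#' @export
default_feature_names <- function(n_channels = 14L, n_bands = 5L) {
  epoc <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
            "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
  bands <- c("theta", "alpha", "betaL", "betaH", "gamma")
  ch <- if (n_channels <= length(epoc)) epoc[seq_len(n_channels)]
        else sprintf("ch%02d", seq_len(n_channels))
  bd <- if (n_bands <= length(bands)) bands[seq_len(n_bands)]
        else sprintf("b%d", seq_len(n_bands))
  as.vector(t(outer(ch, bd, paste, sep = "_")))
}

#' Read / write feature tables as CSV
#'
#' Delimited text with a header row; one column holds the class label, all
#' other columns must be numeric features. Non-numeric or empty feature
#' cells are a parse error naming the offending row and column.
#'
#' @param path file path.
#' @param label_column name of the label column (default `"label"`).
#' @param positive_class which label value encodes the positive class;
#'   `NULL` uses `"positive"` when present, else the alphabetically larger
#'   value.
#' @param sep field separator.
#' @return `read_feature_table()` returns a [feature_table()];
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path, label_column = "label",
                               positive_class = NULL, sep = ",") {
  if (!file.exists(path))
    fsgp_error(sprintf("file not found: %s", path), "fsgp_io_error")
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!label_column %in% names(df))
    fsgp_error(sprintf("label column '%s' missing from %s",
                       label_column, path),
               "fsgp_format_error")
  labels <- df[[label_column]]
  feats <- df[setdiff(names(df), label_column)]
  if (ncol(feats) == 0)
    fsgp_error("no feature columns found", "fsgp_format_error")
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    if (is.character(col) || is.logical(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) | !nzchar(trimws(as.character(col))))
      if (length(bad) == 0 && !anyNA(num)) { feats[[j]] <- num; next }
      fsgp_error(sprintf("non-numeric feature cell at row %d, column '%s'",
                         bad[1], names(feats)[j]),
                 "fsgp_parse_error")
    }
    if (anyNA(col) || any(!is.finite(col)))
      fsgp_error(sprintf("non-finite feature cell at row %d, column '%s'",
                         which(!is.finite(col))[1], names(feats)[j]),
                 "fsgp_parse_error")
  }
  feature_table(as.matrix(feats), encode_labels(labels, positive_class))
}

#' @rdname read_feature_table
#' @param table a [feature_table()].
#' @export
write_feature_table <- function(table, path, label_column = "label",
                                sep = ",") {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table, label_column = label_column)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Hold-out train/test split
#'
#' Partitions a feature table into disjoint train and test tables. The train
#' size is `floor(train_fraction * n + 0.5)`; with `stratified = TRUE`
#' (default) the per-class train counts follow the same rule via largest
#' remainders, so per-class proportions match `train_fraction` to within one
#' sample.
#'
#' @param table a [feature_table()].
#' @param train_fraction fraction of samples assigned to training, in (0,1).
#' @param stratified preserve class proportions?
#' @param seed integer seed; identical seeds give identical splits.
#' @return A list of class `split_pair` with fields `train`, `test`,
#'   `train_fraction`, `train_idx`.
#' @examples
#' ft <- generate_synthetic(synthetic_spec(n_samples = 50, seed = 7))
#' sp <- holdout_split(ft, 0.8, seed = 1)
#' dim(sp$train); dim(sp$test)
#' @export
holdout_split <- function(table, train_fraction = 0.8, stratified = TRUE,
                          seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (!(train_fraction > 0 && train_fraction < 1))
    fsgp_error("train_fraction must lie strictly in (0, 1)",
               "fsgp_argument_error")
  n <- nrow(table$values)
  n_train <- floor(train_fraction * n + 0.5)
  if (n_train < 1 || n_train >= n)
    fsgp_error("split would leave an empty train or test set",
               "fsgp_argument_error")
  idx <- with_preserved_seed(seed, {
    if (stratified) {
      counts <- table(table$labels)
      if (any(counts < 2))
        fsgp_error("stratified split needs at least 2 samples per class",
                   "fsgp_data_error")
      base <- floor(train_fraction * counts)
      rem <- train_fraction * counts - base
      extra <- n_train - sum(base)
      if (extra > 0) {
        give <- order(rem, decreasing = TRUE)[seq_len(extra)]
        base[give] <- base[give] + 1
      } else if (extra < 0) {
        take <- order(rem)[seq_len(-extra)]
        base[take] <- base[take] - 1
      }
      unlist(lapply(names(counts), function(cl) {
        rows <- which(table$labels == cl)
        sample(rows, base[[cl]])
      }), use.names = FALSE)
    } else {
      sample(seq_len(n), n_train)
    }
  })
  idx <- sort(idx)
  subset_table <- function(rows) {
    feature_table(table$values[rows, , drop = FALSE], table$labels[rows])
  }
  structure(list(train = subset_table(idx),
                 test = subset_table(setdiff(seq_len(n), idx)),
                 train_fraction = train_fraction,
                 train_idx = idx),
            class = "split_pair")
}

#' Standardize features by reference statistics
#'
#' Z-scores each column of `table` using the column means and standard
#' deviations of `reference` (normally the training table, so test data is
#' scaled by training statistics). Constant reference columns map to zero.
#'
#' @param table table to transform.
#' @param reference table providing the statistics; defaults to `table`.
#' @return A [feature_table()] with transformed values.
#' @export
standardize <- function(table, reference = table) {
  stopifnot(inherits(table, "feature_table"),
            inherits(reference, "feature_table"))
  if (!identical(colnames(table$values), colnames(reference$values)))
    fsgp_error("table and reference must share the same features in order",
               "fsgp_schema_error")
  mu <- colMeans(reference$values)
  sigma <- apply(reference$values, 2, sd)
  sigma[!is.finite(sigma) | sigma == 0] <- Inf  # constant columns -> 0
  vals <- sweep(sweep(table$values, 2, mu, "-"), 2, sigma, "/")
  feature_table(vals, table$labels)
}
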