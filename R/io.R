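#' @include AllClasses.R
NULL

# CSV dialect: comma separator, "." decimal, UTF-8, mandatory header,
# first column = sample ID.

#' Read a per-source feature table from CSV
#'
#' Reads one instrument's sample-by-feature table. The first row must be a
#' header, the first column holds sample IDs, all remaining cells must be
#' numeric. Row order is preserved from the file.
#'
#' @param path path to a CSV file.
#' @param sourceName short source identifier attached to the block.
#' @return A validated \linkS4class{SourceBlock}.
#' @seealso [writeFeatureTable()], [assembleDataset()]
#' @export
readFeatureTable <- function(path, sourceName) {
  if (!file.exists(path))
    stop("feature table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty feature table: ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  num <- df[, -1L, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric cells in column(s): ",
      paste(names(num)[bad], collapse = ", "), call. = FALSE)
  m <- as.matrix(num)
  if (!all(is.finite(m)))
    stop("non-numeric cells (NA/Inf) in ", path, call. = FALSE)
  rownames(m) <- ids
  SourceBlock(m, sourceName)
}

#' Write a SourceBlock to CSV
#'
#' Inverse of [readFeatureTable()]: a read/write/read round-trip reproduces
#' values bit-exactly for finite decimal inputs (values are written with full
#' precision).
#'
#' @param block a \linkS4class{SourceBlock}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeFeatureTable <- function(block, path) {
  stopifnot(methods::is(block, "SourceBlock"))
  v <- featureValues(block)
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
    fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample-to-class label table
#'
#' @param path CSV with columns \code{sample_id,class}.
#' @return Named character vector of class labels (names are sample IDs).
#' @export
readLabels <- function(path) {
  if (!file.exists(path))
    stop("label file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("sample_id", "class") %in% names(df)))
    stop("label file must have columns sample_id,class", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in label file", call. = FALSE)
  structure(as.character(df$class), names = as.character(df$sample_id))
}

#' Assemble aligned blocks and labels into a dataset
#'
#' Re-orders every block to the sample order of the first block (the canonical
#' order), attaches labels, and validates the result. The class set is
#' first-appearance order along the canonical sample order.
#'
#' @param blockList list of \linkS4class{SourceBlock} objects sharing one
#'   sample-ID set.
#' @param labels either a path to a \code{sample_id,class} CSV or a named
#'   character vector as returned by [readLabels()]. Every sample appearing in
#'   the blocks must be present.
#' @return A \linkS4class{MultiSourceDataset}.
#' @examples
#' m1 <- matrix(1:6, 3, 2, dimnames = list(c("S1", "S2", "S3"), c("a", "b")))
#' m2 <- matrix(1:9, 3, 3, dimnames = list(c("S3", "S1", "S2"), c("x", "y", "z")))
#' ds <- assembleDataset(
#'   list(SourceBlock(m1, "EN"), SourceBlock(m2, "ET")),
#'   c(S1 = "BS", S2 = "GE", S3 = "BS"))
#' sampleIds(ds)
#' @export
assembleDataset <- function(blockList, labels) {
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)))
    labels <- readLabels(labels)
  ref <- sampleIds(blockList[[1L]])
  missing <- setdiff(ref, names(labels))
  if (length(missing))
    stop("samples present in a block but absent from labels: ",
      paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  lab <- labels[ref]
  lab <- factor(lab, levels = unique(lab))
  MultiSourceDataset(blockList, structure(as.character(lab), names = ref))
}

#' Structured-text manifest of a dataset
#'
#' @param dataset a \linkS4class{MultiSourceDataset}.
#' @param path optional path; when given, the manifest is written as JSON.
#' @return The manifest as a list (invisibly when written).
#' @export
datasetManifest <- function(dataset, path = NULL) {
  man <- list(
    n_samples = length(sampleIds(dataset)),
    sources = lapply(blocks(dataset), function(b)
      list(source = sourceName(b), n_features = ncol(featureValues(b)))),
    classes = as.list(table(classLabels(dataset))))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(man))
  }
  man
}

#' Write a whole dataset as per-source CSV tables plus labels
#'
#' Emits one feature table per source (\code{<source>.csv}), a label file
#' (\code{labels.csv}) and a JSON manifest, all in \code{dir}.
#'
#' @param dataset a \linkS4class{MultiSourceDataset}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in blocks(dataset))
    writeFeatureTable(b, file.path(dir, paste0(sourceName(b), ".csv")))
  lab <- data.frame(sample_id = sampleIds(dataset),
    class = as.character(classLabels(dataset)))
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE,
    quote = FALSE)
  datasetManifest(dataset, file.path(dir, "manifest.json"))
  invisible(dir)
}
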