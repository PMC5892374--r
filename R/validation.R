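#' Stratified random sampling of reference sites from rasters
#'
#' Uniform without-replacement sampling within each stratum of a strata
#' raster, returning the classified label at each site. Reproducible for a
#' fixed seed.
#'
#' @param labels integer label raster (e.g. a `landform_map$labels`).
#' @param strata stratum raster (character or integer), same shape.
#' @param counts named vector of site counts per stratum.
#' @param seed RNG seed.
#' @return data frame with `stratum`, `row`, `col`, `label`.
#' @export
stratified_sample <- function(labels, strata, counts, seed = 1) {
  if (!identical(dim(labels), dim(strata)))
    stop("labels and strata rasters must share shape")
  restore <- local_seed(seed)
  on.exit(restore())
  out <- list()
  for (s in names(counts)) {
    k <- counts[[s]]
    if (k == 0) next
    cand <- which(strata == s & !is.na(labels))
    if (length(cand) < k)
      stop(sprintf("stratum '%s' has only %d candidate pixels, %d requested",
                   s, length(cand), k))
    pick <- sample(cand, k)
    rc <- arrayInd(pick, dim(labels))
    out[[s]] <- data.frame(stratum = s, row = rc[, 1], col = rc[, 2],
                           label = labels[pick], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(stratum = character(), row = integer(),
                      col = integer(), label = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Confusion matrix of a thematic map
#'
#' Cross-tabulates classified against reference labels: cell `(r, c)` counts
#' sites classified as class `r` whose reference label is class `c` (rows =
#' classification, columns = reference).
#'
#' @param classified,reference equal-length label vectors.
#' @param classes class order; defaults to the sorted union of labels.
#' @return a `confusion_matrix`: integer matrix with `dimnames`
#'   `classification` x `reference` and attribute `N`.
#' @export
confusion_matrix <- function(classified, reference, classes = NULL) {
  if (length(classified) != length(reference))
    stop("classified and reference must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(classified, reference)))
  bad <- setdiff(unique(c(classified, reference)), classes)
  if (length(bad)) stop("label(s) outside the class order: ",
                        paste(bad, collapse = ", "))
  m <- table(factor(classified, levels = classes),
             factor(reference, levels = classes))
  m <- matrix(as.integer(m), length(classes), length(classes),
              dimnames = list(classification = classes, reference = classes))
  structure(m, N = sum(m), class = c("confusion_matrix", class(m)))
}

as_confusion <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop("confusion matrix must be square")
  cm
}

#' Accuracy statistics from a confusion matrix
#'
#' `overall_accuracy` is `100 * trace / N` (percent). Per-class `user`
#' accuracy is the diagonal over the classification-row total (map
#' precision) and `producer` accuracy the diagonal over the reference-column
#' total (recall); classes with a zero marginal get `NA` and are flagged,
#' not errors. `cohens_kappa` is the chance-corrected agreement
#' `(p0 - pe) / (1 - pe)` with `pe = sum(row_i * col_i) / N^2`. Full
#' precision is retained; round only at the reporting layer.
#'
#' @param cm a `confusion_matrix` (any square count matrix works).
#' @return `overall_accuracy`: percent; `user_producer_accuracies`: data
#'   frame with `class`, `user_pct`, `producer_pct`; `cohens_kappa`: numeric
#'   (NA with a warning when `pe = 1`).
#' @export
#' @examples
#' cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
#' overall_accuracy(cm)  # 66.67
overall_accuracy <- function(cm) {
  cm <- as_confusion(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / n
}

#' @rdname overall_accuracy
#' @export
user_producer_accuracies <- function(cm) {
  cm <- as_confusion(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  data.frame(class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
             user_pct = ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_),
             producer_pct = ifelse(cs > 0, 100 * diag(cm) / cs, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname overall_accuracy
#' @export
cohens_kappa <- function(cm) {
  cm <- as_confusion(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  p0 <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) {
    warning("expected agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (p0 - pe) / (1 - pe)
}

#' Where do a reference class's errors go?
#'
#' Distribution of the misclassified sites of one reference class over the
#' wrong map labels: the off-diagonal of that reference column, as
#' percentages of its misclassified total.
#'
#' @param cm a `confusion_matrix`.
#' @param class reference class name.
#' @return named numeric vector of percentages (empty when the class has no
#'   misclassified sites).
#' @export
misclassification_composition <- function(cm, class) {
  cm <- as_confusion(cm)
  if (!(class %in% colnames(cm))) stop("unknown reference class: ", class)
  col <- cm[, class]
  col[class] <- 0
  tot <- sum(col)
  if (tot == 0) return(stats::setNames(numeric(0), character(0)))
  out <- 100 * col[col > 0] / tot
  sort(out, decreasing = TRUE)
}

#' Read/write a labeled confusion matrix as CSV
#'
#' The CSV stores classification rows against reference columns; the first
#' header cell must literally be `classification` (the loader refuses files
#' that leave the orientation ambiguous).
#'
#' @param cm a `confusion_matrix`.
#' @param path CSV path.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- as.data.frame.matrix(unclass(cm))
  df <- cbind(classification = rownames(cm), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  if (!file.exists(path)) stop("confusion matrix file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "classification")
    stop("ambiguous orientation: first column must be named 'classification'",
         " (rows = classification, columns = reference)")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$classification
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("classification", "reference")
  structure(m, N = sum(m), class = c("confusion_matrix", class(m)))
}

#' The published regional accuracy-assessment counts
#'
#' Loads the packaged copy of the published 13-class confusion matrix (1000
#' stratified reference sites over the Arctic Coastal Plain landform map;
#' rows = classification, columns = reference). From these counts the
#' headline statistics recompute directly: overall accuracy 75.7%, FC
#' producer accuracy 40.5%, and 64% of misclassified flat-center polygons
#' labeled as high-center polygons.
#'
#' @return a `confusion_matrix`.
#' @export
acp_reference_confusion <- function() {
  read_confusion_csv(system.file("extdata", "acp_confusion_matrix.csv",
                                 package = "tundramorph", mustWork = TRUE))
}
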