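# Delimited-text readers/writers and model serialization. Tab-separated
# with header is the native dialect; comma is auto-detected.

.detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (!length(line)) stop("empty file: ", path)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

.find_col <- function(nms, candidates, label, required = TRUE) {
  hit <- which(tolower(nms) %in% tolower(candidates))
  if (!length(hit)) {
    if (required)
      stop(sprintf("no %s column found; available columns: %s", label,
                   paste(nms, collapse = ", ")))
    return(NA_integer_)
  }
  hit[1]
}

#' Read GWAS summary statistics
#'
#' Delimited text with a header; needs a SNP identifier column and a
#' p-value column (or a z-score column, converted via p = 2 (1 - Phi(|z|))).
#' Unparseable p-values are dropped with a warning; p-values are clipped
#' into (0, 1] and the clip count recorded.
#'
#' @param path file path
#' @param snp_col,p_col,z_col optional explicit column names; by default
#'   common names (SNP/rsid/id, P/pval/p_value, Z/zscore) are matched
#'   case-insensitively
#' @return data.frame of class \code{palm_sumstats} with columns snp, p
#'   (and z if present); attributes \code{n_clipped}, \code{n_dropped}
#' @export
read_sumstats <- function(path, snp_col = NULL, p_col = NULL,
                          z_col = NULL) {
  sep <- .detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE, check.names = FALSE)
  nms <- names(df)
  si <- if (is.null(snp_col)) .find_col(nms, c("snp", "rsid", "id", "snpid",
                                               "marker"), "SNP id")
        else .find_col(nms, snp_col, "SNP id")
  pi_ <- if (is.null(p_col)) .find_col(nms, c("p", "pval", "pvalue",
                                              "p_value", "p.value"),
                                       "p-value", required = FALSE)
         else .find_col(nms, p_col, "p-value")
  zi <- if (is.null(z_col)) .find_col(nms, c("z", "zscore", "z_score",
                                             "stat"), "z-score",
                                      required = FALSE)
        else .find_col(nms, z_col, "z-score")
  snp <- as.character(df[[si]])
  if (anyDuplicated(snp)) stop("duplicated SNP identifiers in ", path)
  z <- if (!is.na(zi)) suppressWarnings(as.numeric(df[[zi]])) else NULL
  if (!is.na(pi_)) {
    p <- suppressWarnings(as.numeric(df[[pi_]]))
  } else if (!is.null(z)) {
    p <- 2 * pnorm(-abs(z))
  } else {
    stop(sprintf("no p-value or z-score column found; available columns: %s",
                 paste(nms, collapse = ", ")))
  }
  drop <- !is.finite(p)
  if (any(drop)) {
    warning(sprintf("dropping %d rows with unparseable p-values", sum(drop)))
    snp <- snp[!drop]; p <- p[!drop]
    if (!is.null(z)) z <- z[!drop]
  }
  p <- clip_pvalues(p)
  out <- data.frame(snp = snp, p = as.numeric(p), stringsAsFactors = FALSE)
  if (!is.null(z)) out$z <- z
  attr(out, "n_clipped") <- attr(p, "n_clipped")
  attr(out, "n_dropped") <- sum(drop)
  class(out) <- c("palm_sumstats", "data.frame")
  out
}

#' Read an annotation matrix aligned to the summary statistics
#'
#' First column is the SNP identifier; the remaining columns are numeric
#' annotations (blank or "NA" tokens become missing). Rows are reordered to
#' the supplied SNP order; SNPs absent from the file get all-missing rows
#' (handled downstream by the trees' default directions).
#'
#' @param path file path
#' @param snp_ids character vector giving the target row order
#' @return numeric matrix with rownames \code{snp_ids}; attribute
#'   \code{n_unmatched} counts all-missing rows
#' @export
read_annotations <- function(path, snp_ids) {
  sep <- .detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", "", "nan", "NaN"))
  ids <- as.character(df[[1]])
  Araw <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(Araw) <- "double"
  idx <- match(snp_ids, ids)
  if (all(is.na(idx))) stop("no overlapping SNP identifiers between ",
                            "sumstats and annotations")
  A <- matrix(NA_real_, nrow = length(snp_ids), ncol = ncol(Araw),
              dimnames = list(snp_ids, colnames(Araw)))
  A[!is.na(idx), ] <- Araw[idx[!is.na(idx)], , drop = FALSE]
  n_un <- sum(is.na(idx))
  if (n_un > 0)
    message(sprintf("%d SNPs missing from the annotation file: all-missing rows",
                    n_un))
  attr(A, "n_unmatched") <- n_un
  A
}

#' Serialize a fitted model to JSON
#'
#' The schema mirrors the model fields: intercept f0, shrinkage nu, alpha,
#' depth, column names, and per-tree node arrays (feature index 0-based or
#' -1 for a leaf, threshold, default_left, left/right child index, leaf
#' value, per-feature gain). Numbers are written at full precision so a
#' round trip reproduces predictions exactly.
#'
#' @param model a \code{palm_model}
#' @param path output path
#' @return the path, invisibly
#' @export
palm_save_model <- function(model, path) {
  obj <- list(format = "palm_model", version = 1L,
              f0 = model$f0, nu = model$nu, alpha = model$alpha,
              depth = model$depth, columns = model$columns,
              trees = lapply(model$trees, unclass))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Deserialize a model saved by [palm_save_model()]
#'
#' @param path path to the JSON file
#' @return a \code{palm_model}
#' @export
palm_load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "palm_model")
    stop("not a palm model file: ", path)
  fix <- function(tr) {
    structure(list(
      feature = as.integer(tr$feature),
      threshold = as.numeric(tr$threshold),
      default_left = as.integer(tr$default_left),
      left = as.integer(tr$left), right = as.integer(tr$right),
      value = as.numeric(tr$value), gain = as.numeric(tr$gain)),
      class = "palm_tree")
  }
  trees <- if (length(obj$trees)) {
    if (is.data.frame(obj$trees))
      lapply(seq_len(nrow(obj$trees)), function(i)
        fix(lapply(obj$trees, `[[`, i)))
    else lapply(obj$trees, fix)
  } else list()
  palm_model(obj$f0, trees, obj$nu, obj$alpha,
             columns = as.character(obj$columns),
             depth = as.integer(obj$depth))
}

#' Write a per-SNP results table
#'
#' @param result a \code{palm_result}
#' @param path output TSV path
#' @return the path, invisibly
#' @export
write_results <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
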