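#' Read a protein-protein interaction edge table
#'
#' Accepts either a minimal three-column table (\code{gene_a}, \code{gene_b},
#' integer \code{score} in [0, 1000]) or a raw STRING protein-links file
#' (space-separated, header containing \code{combined_score}); species
#' prefixes such as \code{"9606."} are stripped.  Self-loops are dropped
#' (with a message giving the count) and duplicate undirected pairs keep
#' the maximum score.
#'
#' @param path path to a whitespace- or tab-separated text file, with or
#'   without a header line.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{score}; one row per undirected pair.
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tB\t900", "B\tA\t900", "A\tC\t500"), tf)
#' readEdgeTable(tf)
#' @export
readEdgeTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge table: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) != 3L)
  if (length(bad))
    stop("malformed row (expected 3 columns) at line ", bad[1L], " of ", path)
  m <- do.call(rbind, toks)
  # optional header: first row whose score column is not numeric
  if (is.na(suppressWarnings(as.numeric(m[1L, 3L])))) {
    m <- m[-1L, , drop = FALSE]
    if (!nrow(m)) stop("edge table has a header but no data rows: ", path)
  }
  score <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1L]
    stop("malformed score at data line ", bad, " of ", path)
  }
  if (any(score < 0 | score > 1000))
    stop("score out of range [0, 1000] at data line ",
         which(score < 0 | score > 1000)[1L], " of ", path)
  ga <- sub("^[0-9]+\\.", "", m[, 1L])
  gb <- sub("^[0-9]+\\.", "", m[, 2L])
  self <- ga == gb
  if (any(self))
    message("readEdgeTable: dropped ", sum(self), " self-loop(s)")
  ga <- ga[!self]; gb <- gb[!self]; score <- score[!self]
  if (!length(ga))
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  a <- pmin(ga, gb)
  b <- pmax(ga, gb)
  key <- paste(a, b, sep = "\r")
  score <- vapply(split(score, key), max, numeric(1))
  pair <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
  out <- data.frame(gene_a = pair[, 1L], gene_b = pair[, 2L],
                    score = unname(score), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an edge table
#'
#' @param edges data.frame as returned by [readEdgeTable()]
#' @param path output path (tab-separated, no header)
#' @return \code{path}, invisibly.
#' @export
writeEdgeTable <- function(edges, path) {
  utils::write.table(edges[, c("gene_a", "gene_b", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a TF-to-target edge table
#'
#' Two tab-separated columns (\code{tf}, \code{target}); an optional header
#' row named \code{tf}/\code{target} is skipped.  Duplicate directed pairs
#' are collapsed.
#'
#' @param path input path
#' @return data.frame with columns \code{tf}, \code{target}.
#' @export
readTFTargetTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("tf", "target"),
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) && tolower(df$tf[1L]) == "tf") df <- df[-1L, , drop = FALSE]
  if (!nrow(df)) stop("empty TF-target table: ", path)
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' @rdname readTFTargetTable
#' @param tfTargets data.frame with columns \code{tf}, \code{target}
#' @export
writeTFTargetTable <- function(tfTargets, path) {
  utils::write.table(tfTargets[, c("tf", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' The file must be tab-separated with a header naming at least the columns
#' \code{gene}, \code{log2fc} and \code{padj}.
#'
#' @param path input path
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{padj}.
#' @export
readDETable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("gene", "log2fc", "padj"))
    if (!col %in% names(df))
      stop("DE table ", path, " is missing required column '", col, "'")
  df <- df[, c("gene", "log2fc", "padj")]
  df$gene <- as.character(df$gene)
  if (anyDuplicated(df$gene))
    stop("duplicated gene '", df$gene[duplicated(df$gene)][1L],
         "' in DE table ", path)
  if (!all(is.finite(df$log2fc)))
    stop("non-finite log2fc in DE table ", path)
  if (any(df$padj < 0 | df$padj > 1 | !is.finite(df$padj)))
    stop("padj outside [0, 1] in DE table ", path)
  rownames(df) <- NULL
  df
}

#' @rdname readDETable
#' @param de data.frame with columns \code{gene}, \code{log2fc}, \code{padj}
#' @export
writeDETable <- function(de, path) {
  utils::write.table(de[, c("gene", "log2fc", "padj")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and lines starting with \code{#} are
#' ignored; duplicates are dropped keeping first occurrence.
#'
#' @param path input path
#' @return character vector of unique gene symbols, in file order.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("empty gene list: ", path)
  unique(x)
}

#' @rdname readGeneList
#' @param genes character vector of gene symbols
#' @export
writeGeneList <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read the inhibitor panel table
#'
#' Tab-separated with header; requires columns \code{inhibitor} and
#' \code{target}.  Extra columns (stock concentration, storage, ...) are
#' kept as-is.
#'
#' @param path input path
#' @return data.frame, one row per inhibitor.
#' @export
readInhibitorPanel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  for (col in c("inhibitor", "target"))
    if (!col %in% names(df))
      stop("inhibitor panel ", path, " is missing column '", col, "'")
  if (anyDuplicated(df$inhibitor))
    stop("duplicated inhibitor in panel ", path)
  df
}

#' Read a single-channel microscopy image
#'
#' Supports grayscale TIFF and PNG.  TIFF integer data are kept on their
#' native scale (bit depth recorded in the \code{"bitDepth"} attribute);
#' PNG data arrive in [0, 1] and are rescaled to 8-bit.  Multi-channel
#' images require \code{channel}; z-stacks are rejected.
#'
#' @param path path to a TIFF or PNG file
#' @param channel integer channel index for multi-channel images
#' @return numeric matrix of non-negative intensities with attribute
#'   \code{bitDepth}.
#' @export
readImageFile <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    if (length(img) > 1L)
      stop("multi-page TIFF requires a z-projection policy; ",
           "supply single-plane images")
    img <- img[[1L]]
    depth <- if (max(img) > 255) 16L else 8L
  } else if (ext == "png") {
    img <- png::readPNG(path)
    img <- img * 255
    depth <- 8L
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3L) {
    if (is.null(channel))
      stop("multi-channel image; supply 'channel'")
    if (channel < 1L || channel > dim(img)[3L])
      stop("channel ", channel, " out of range")
    img <- img[, , channel]
  }
  if (length(dim(img)) != 2L) stop("expected a 2-D image")
  storage.mode(img) <- "double"
  attr(img, "bitDepth") <- depth
  img
}

#' Write a 2-D intensity matrix as a 16-bit TIFF
#'
#' @param img numeric matrix (values on a 16-bit scale)
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
writeImageFile <- function(img, path) {
  tiff::writeTIFF(pmax(pmin(img / 65535, 1), 0), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read / write the flat key-value pipeline configuration
#'
#' The configuration is a plain-text file of \code{key = value} lines.
#' Numeric-looking values are converted to numeric on read; the round trip
#' write-then-read is lossless.
#'
#' @param path config file path
#' @return named list of configuration values.
#' @export
readConfig <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  kv <- regmatches(x, regexec("^([^=]+)=(.*)$", x))
  if (any(lengths(kv) != 3L)) stop("malformed config line in ", path)
  keys <- trimws(vapply(kv, `[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(out) <- keys
  out
}

#' @rdname readConfig
#' @param config named list of scalar values
#' @export
writeConfig <- function(config, path) {
  vals <- vapply(config, function(v) format(v, digits = 17), character(1))
  writeLines(paste(names(config), vals, sep = " = "), path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Central record of the tunable parameters shared across the pipeline:
#' cost-transform log base, PCST solver settings, the percentile convention
#' used for every quantile in the package, image-analysis sizes in pixels,
#' and significance thresholds.
#'
#' @return named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    log_base = 10,
    beta = 1,
    num_components = 1,
    seed = 1,
    padj_threshold = 0.05,
    lfc_threshold = 0,
    percentile_convention = "linear",  # R quantile type 7
    min_nucleus_area = 100,
    min_focus_area = 5,
    shell_width = 3,
    alpha = 0.05
  )
}
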