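#' Derive CAD group from percent stenosis
#'
#' Angiographic grouping: stenosis <= 20\% is LOW, > 20\% and < 70\% is MID,
#' >= 70\% is HIGH. Total on [0, 100]; values outside error out.
#'
#' @param percent_stenosis numeric vector of percent luminal stenosis.
#' @return character vector of group labels (`LOW`, `MID`, `HIGH`).
#' @examples
#' groupFromStenosis(c(0, 20, 21, 69.9, 70, 100))
#' @export
groupFromStenosis <- function(percent_stenosis) {
  x <- as.numeric(percent_stenosis)
  bad <- !is.na(x) & (x < 0 | x > 100)
  if (any(bad))
    stop("percent_stenosis outside [0, 100]: ",
         paste(utils::head(x[bad], 5), collapse = ", "))
  out <- rep(NA_character_, length(x))
  out[!is.na(x) & x <= 20] <- "LOW"
  out[!is.na(x) & x > 20 & x < 70] <- "MID"
  out[!is.na(x) & x >= 70] <- "HIGH"
  out
}

.checkRectangular <- function(path, sep = "\t") {
  nf <- utils::count.fields(path, sep = sep, quote = "\"",
                            comment.char = "")
  if (length(nf) == 0L) stop("no transcripts: file '", path, "' is empty")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("malformed row in '%s': line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1L]))
  }
  invisible(nf[1L])
}

#' Read and write a counts (or RPKM) matrix
#'
#' Dense format is a TSV with `transcript_id` as the first header cell and
#' one column per sample. The sparse `triplet` format is three sibling
#' files: `<prefix>.triplet.tsv` (row, col, value; 1-based indices),
#' `<prefix>.rownames.txt` and `<prefix>.colnames.txt`.
#'
#' @param path file path (dense TSV) or path prefix (triplet).
#' @param format `"tsv"` or `"triplet"`.
#' @param unit expression unit to stamp on the result.
#' @return [readCounts()] returns a [BloodExprSet-class];
#'   [writeCounts()] returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' writeCounts(BloodExprSet(m), f)
#' exprValues(readCounts(f))
#' @export
readCounts <- function(path, format = c("tsv", "triplet"),
                       unit = c("counts", "RPKM", "log2RPKM")) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  if (format == "triplet") return(.readTriplet(path, unit))
  if (!file.exists(path)) stop("file not found: ", path)
  .checkRectangular(path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts TSV needs an id column plus >= 1 sample")
  if (nrow(df) == 0L) stop("no transcripts in '", path, "'")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate transcript ids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric or missing values in counts matrix")
  if (unit != "log2RPKM" && any(m < 0)) stop("negative expression values")
  rownames(m) <- ids
  BloodExprSet(m, unit = unit)
}

.readTriplet <- function(prefix, unit) {
  tf <- paste0(prefix, ".triplet.tsv")
  rf <- paste0(prefix, ".rownames.txt")
  cf <- paste0(prefix, ".colnames.txt")
  for (f in c(tf, rf, cf))
    if (!file.exists(f)) stop("file not found: ", f)
  rn <- readLines(rf)
  cn <- readLines(cf)
  if (length(rn) == 0L) stop("no transcripts in '", rf, "'")
  if (anyDuplicated(rn)) stop("duplicate transcript ids in '", rf, "'")
  tr <- utils::read.delim(tf, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("row", "col", "value") %in% names(tr)))
    stop("triplet file needs columns row, col, value")
  if (any(tr$row < 1 | tr$row > length(rn) | tr$col < 1 | tr$col > length(cn)))
    stop("triplet indices out of range")
  m <- matrix(0, length(rn), length(cn), dimnames = list(rn, cn))
  m[cbind(tr$row, tr$col)] <- tr$value
  if (unit != "log2RPKM" && any(m < 0)) stop("negative expression values")
  BloodExprSet(m, unit = unit)
}

#' @param object a [BloodExprSet-class] (or bare matrix) to write.
#' @rdname readCounts
#' @export
writeCounts <- function(object, path, format = c("tsv", "triplet")) {
  format <- match.arg(format)
  m <- if (is(object, "BloodExprSet")) exprValues(object) else as.matrix(object)
  if (format == "triplet") {
    nz <- which(m != 0, arr.ind = TRUE)
    utils::write.table(
      data.frame(row = nz[, 1L], col = nz[, 2L], value = m[nz]),
      paste0(path, ".triplet.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    writeLines(rownames(m), paste0(path, ".rownames.txt"))
    writeLines(colnames(m), paste0(path, ".colnames.txt"))
    return(invisible(path))
  }
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write gene sets in GMT format
#'
#' One set per tab-separated line: name, description, then member symbols.
#' Symbols are upper-cased, trimmed and deduplicated on load; empty member
#' fields are skipped.
#'
#' @param path GMT file path.
#' @return [readGeneSets()] returns a named list of [GeneSet-class] objects.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no gene sets in '", path, "'")
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: need name, description and >= 1 member",
                   i))
    GeneSet(f[1L], f[-(1:2)], description = f[2L])
  })
  names(sets) <- vapply(sets, geneSetName, character(1))
  sets
}

#' @param sets list of [GeneSet-class] objects.
#' @rdname readGeneSets
#' @export
writeGeneSets <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s@name, s@description, s@members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write the sample metadata table
#'
#' CSV with required column `sample_id` and either `group` (LOW/MID/HIGH) or
#' `percent_stenosis` (from which the group is derived, see
#' [groupFromStenosis()]). All other columns are carried along as clinical
#' covariates; empty cells become `NA`, never zero.
#'
#' @param path CSV file path.
#' @return data.frame of sample records.
#' @export
readSampleTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df)) stop("sample table needs a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id values")
  if (!"group" %in% names(df)) {
    if (!"percent_stenosis" %in% names(df))
      stop("sample table needs 'group' or 'percent_stenosis'")
    df$group <- groupFromStenosis(df$percent_stenosis)
  }
  bad <- !df$group %in% c("LOW", "MID", "HIGH") & !is.na(df$group)
  if (any(bad))
    stop("unknown group label: ",
         paste(unique(df$group[bad]), collapse = ", "))
  if ("total_mapped_reads" %in% names(df) &&
      any(df$total_mapped_reads < 1, na.rm = TRUE))
    stop("total_mapped_reads must be >= 1")
  df
}

#' @param samples data.frame of sample records.
#' @rdname readSampleTable
#' @export
writeSampleTable <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write the transcript annotation table
#'
#' TSV with columns `transcript_id`, `gene_symbol`, `length_bp`.
#'
#' @param path TSV file path.
#' @return data.frame of transcript records.
#' @export
readTranscriptTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_symbol", "length_bp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("transcript table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$transcript_id)) stop("duplicate transcript_id values")
  if (any(df$length_bp < 1)) stop("length_bp must be >= 1")
  df$gene_symbol <- toupper(trimws(df$gene_symbol))
  df
}

#' @param transcripts data.frame of transcript records.
#' @rdname readTranscriptTable
#' @export
writeTranscriptTable <- function(transcripts, path) {
  utils::write.table(transcripts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Is a sample in the MID+ (diseased) stratum?
#'
#' @param group character vector of group labels.
#' @return logical, TRUE for MID or HIGH.
#' @export
isMidPlus <- function(group) group %in% c("MID", "HIGH")
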