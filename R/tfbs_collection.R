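#' Construct a TFBS collection
#'
#' A `tfbs_collection` holds the pooled set of transcription factor binding
#' sites (TFBSs) across all TFs in a dataset: one genomic interval per site,
#' tagged with the TF it belongs to.  Coordinates follow the BED convention
#' (0-based, half-open).  Records are kept sorted by (chrom, start, end);
#' duplicate records are retained, since identical peaks may legitimately be
#' reported by independent experiments.
#'
#' @param records data.frame with columns `chrom` (character), `start`
#'   (integer, 0-based inclusive), `end` (integer, exclusive) and `tf`
#'   (character, non-empty).
#' @return An object of class `tfbs_collection`: a list with elements
#'   `records` (the sorted data.frame), `tf_names` (sorted distinct TF
#'   identifiers, defining the node/index order used by every downstream
#'   matrix), `m` (named integer vector of per-TF site counts) and `w`
#'   (total site count).
#' @examples
#' df <- data.frame(chrom = "chr1", start = c(100, 0, 500),
#'                  end = c(300, 200, 700), tf = c("A", "A", "B"))
#' x <- tfbs_collection(df)
#' x$tf_names  # "A" "B"
#' x$m         # A=2, B=1
#' @export
tfbs_collection <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("chrom", "start", "end", "tf")
  if (!all(need %in% names(records)))
    stop("records must have columns chrom, start, end, tf")
  records <- records[need]
  records$chrom <- as.character(records$chrom)
  records$tf <- as.character(records$tf)
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  bad <- which(!is.finite(records$start) | !is.finite(records$end) |
                 records$end <= records$start | records$start < 0)
  if (length(bad))
    stop("invalid coordinates (end <= start, negative, or non-integer) in record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(is.na(records$tf) | records$tf == ""))
    stop("empty TF identifier")
  ord <- order(records$chrom, records$start, records$end, records$tf,
               method = "radix")
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  tf_names <- sort(unique(records$tf))
  m <- vapply(tf_names, function(t) sum(records$tf == t), integer(1))
  structure(
    list(records = records, tf_names = tf_names, m = m, w = nrow(records)),
    class = "tfbs_collection"
  )
}

#' @export
print.tfbs_collection <- function(x, ...) {
  cat(sprintf("TFBS collection: %d sites, %d TFs, %d chromosome(s)\n",
              x$w, length(x$tf_names), length(unique(x$records$chrom))))
  cat(sprintf("  sites per TF: median %.0f, range %d-%d\n",
              stats::median(x$m), min(x$m), max(x$m)))
  invisible(x)
}

#' Read a BED-like TFBS file
#'
#' Reads a tab-separated file with at least four columns, the first three
#' being chrom, start, end (BED: 0-based half-open) and the TF identifier in
#' `tf_column` (default 4, the BED name column).  Malformed coordinate rows
#' are reported with their line number.
#'
#' @param path file path.
#' @param tf_column 1-based index of the column holding the TF name.
#' @return A [tfbs_collection()].
#' @export
read_tfbs <- function(path, tf_column = 4L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty TFBS file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < max(4L, tf_column)))
    stop("line ", which(ncols < max(4L, tf_column))[1],
         ": fewer than ", max(4L, tf_column), " tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start_chr <- vapply(fields, `[[`, "", 2L)
  end_chr <- vapply(fields, `[[`, "", 3L)
  tf <- vapply(fields, `[[`, "", tf_column)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
  if (length(bad))
    stop("line ", bad[1], ": malformed coordinates (", start_chr[bad[1]],
         ", ", end_chr[bad[1]], ")")
  tfbs_collection(data.frame(chrom = chrom, start = start, end = end, tf = tf,
                             stringsAsFactors = FALSE))
}

#' Subset a TFBS collection to one TF
#'
#' @param collection a [tfbs_collection()].
#' @param tf TF identifier.
#' @return A `tfbs_collection` containing only that TF's sites.
#' @export
tfbs_subset <- function(collection, tf) {
  stopifnot(inherits(collection, "tfbs_collection"))
  if (!tf %in% collection$tf_names) stop("unknown TF: ", tf)
  tfbs_collection(collection$records[collection$records$tf == tf, ,
                                     drop = FALSE])
}

#' @export
as.data.frame.tfbs_collection <- function(x, ...) x$records

# For every site (row index into the sorted records), the indices of all
# *other* sites whose interval intersects the focal interval extended by
# window_bp on each side (half-open arithmetic).  The focal site never hits
# itself; other sites of the same TF do.  Returned as a two-column integer
# data.frame (focal, hit).
.site_hits <- function(records, window_bp) {
  stopifnot(window_bp > 0)
  out <- vector("list", 0L)
  for (chr in unique(records$chrom)) {
    idx <- which(records$chrom == chr)
    # BED [start,end) maps to 1-based closed [start+1, end]
    ir <- IRanges::IRanges(start = records$start[idx] + 1L,
                           end = records$end[idx])
    win <- IRanges::IRanges(start = records$start[idx] + 1L - window_bp,
                            end = records$end[idx] + window_bp)
    h <- IRanges::findOverlaps(win, ir)
    q <- S4Vectors::queryHits(h)
    s <- S4Vectors::subjectHits(h)
    keep <- q != s
    out[[length(out) + 1L]] <-
      data.frame(focal = idx[q[keep]], hit = idx[s[keep]])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(focal = integer(0), hit = integer(0))
  res
}
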