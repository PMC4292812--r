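#' @importFrom data.table fread fwrite
NULL

#' Read a numeric probe-by-sample matrix from TSV
#'
#' Expects a header row and the probe id in the first column. Every cell
#' must parse as a number inside `range`; duplicate probe ids and empty
#' files are rejected. Row order is preserved.
#'
#' @param path TSV path.
#' @param range Allowed value range (default \[0, 1\]; use
#'   `c(0, Inf)` for bead counts).
#' @param what Label used in error messages.
#' @return A numeric matrix with probe ids as rownames.
#' @export
read_matrix_tsv <- function(path, range = c(0, 1), what = "value") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0 || ncol(dt) < 2)
    stop("empty or column-less matrix file: ", path)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("duplicate probe id '", ids[duplicated(ids)][1], "' in ", path)
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    for (j in seq_len(ncol(m))) {
      bad <- which(is.na(suppressWarnings(as.numeric(m[, j]))))
      if (length(bad))
        stop(sprintf("non-numeric %s at probe %s, column %s in %s",
                     what, ids[bad[1]], colnames(m)[j], path))
    }
    m <- apply(m, 2, as.numeric)
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("missing %s at probe %s, column %s in %s", what,
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]], path))
  }
  bad <- which(m < range[1] | m > range[2], arr.ind = TRUE)
  if (length(bad))
    stop(sprintf("%s %g out of [%g, %g] at probe %s, column %s in %s",
                 what, m[bad[1, , drop = FALSE]], range[1], range[2],
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]], path))
  rownames(m) <- ids
  m
}

#' @rdname read_matrix_tsv
#' @export
read_beta_tsv <- function(path) read_matrix_tsv(path, c(0, 1), "beta value")

#' Write a probe-by-sample matrix as TSV
#'
#' First column `probe_id`, one column per sample, header row, no missing
#' values. Round-trips through [read_matrix_tsv()].
#'
#' @param m Numeric matrix with rownames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (anyNA(m)) stop("missing values are forbidden in matrix output")
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   row.names = NULL)
  fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
write_beta_tsv <- write_matrix_tsv

ANNOTATION_COLS <- c("probe_id", "chrom", "pos", "feature",
                     "island_relation")

#' Read / write the probe annotation manifest
#'
#' TSV with columns `probe_id`, `chrom` (chr1..chr22, chrX, chrY), `pos`
#' (1-based), `feature` and `island_relation`; labels are validated against
#' the allowed vocabularies.
#'
#' @param path TSV path.
#' @return A data.frame manifest.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  missing <- setdiff(ANNOTATION_COLS, names(ann))
  if (length(missing))
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(ann$probe_id)) stop("duplicate probe ids in annotation")
  ok_chrom <- c(paste0("chr", 1:22), "chrX", "chrY")
  bad <- setdiff(unique(ann$chrom), ok_chrom)
  if (length(bad)) stop("invalid chromosome(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(ann$feature), GENOMIC_FEATURES)
  if (length(bad)) stop("invalid feature(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(ann$island_relation), ISLAND_RELATIONS)
  if (length(bad))
    stop("invalid island relation(s): ", paste(bad, collapse = ", "))
  if (any(ann$pos < 1 | ann$pos != round(ann$pos)))
    stop("'pos' must be positive 1-based integers")
  ann
}

#' @rdname read_annotation_tsv
#' @param annotation Manifest data.frame.
#' @export
write_annotation_tsv <- function(annotation, path) {
  stopifnot(all(ANNOTATION_COLS %in% names(annotation)))
  fwrite(annotation[, ANNOTATION_COLS], path, sep = "\t")
  invisible(path)
}

#' Export a probe set as BED
#'
#' Manifest positions are 1-based; BED is 0-based half-open, so a CpG at
#' position `pos` becomes the 2-base interval `[pos - 1, pos + 1)`. Records
#' carry the probe id as name and, optionally, `round(1000 * |delta-beta|)`
#' as score, and are sorted by chromosome then start.
#'
#' @param probe_ids Probes to export.
#' @param annotation Manifest covering them.
#' @param path Output BED path.
#' @param delta Optional named delta-beta vector used for the score.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(probe_ids, annotation, path, delta = NULL) {
  i <- match(probe_ids, annotation$probe_id)
  if (anyNA(i))
    stop("probe(s) missing coordinates: ",
         paste(head(probe_ids[is.na(i)], 3), collapse = ", "))
  ord <- order(annotation$chrom[i], annotation$pos[i])
  i <- i[ord]
  probe_ids <- probe_ids[ord]
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom[i],
    ranges = IRanges::IRanges(start = annotation$pos[i],
                              end = annotation$pos[i] + 1L),
    name = probe_ids)
  if (!is.null(delta)) {
    sc <- round(1000 * abs(delta[probe_ids]))
    if (anyNA(sc)) stop("delta does not cover all exported probes")
    gr$score <- pmin(1000, sc)
  } else gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
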