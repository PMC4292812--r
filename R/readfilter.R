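#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag
NULL

# Per-genome pair status from one SAM file. Returns a data.frame
# (read_id, status) with status in {aligned, unaligned, duplicate,
# unpaired}. "aligned" in strict mode requires exactly two primary records
# that are mapped, mate-mapped and flagged properly paired; in "any" mode a
# pair with at least one mapped primary mate counts.
sam_pair_status <- function(sam_path, mate_mode = c("strict", "any")) {
  mate_mode <- match.arg(mate_mode)
  if (!file.exists(sam_path)) stop("SAM file not found: ", sam_path)
  bam <- suppressWarnings(
    asBam(sam_path, destination = tempfile(), overwrite = TRUE,
          indexDestination = FALSE))
  on.exit(unlink(bam), add = TRUE)
  rec <- scanBam(bam, param = ScanBamParam(what = c("qname", "flag")))[[1]]
  fl <- rec$flag
  primary <- bitwAnd(fl, 0x100) == 0 & bitwAnd(fl, 0x800) == 0
  qn <- rec$qname[primary]
  fl <- fl[primary]
  info <- data.frame(
    qname = qn,
    dup = bitwAnd(fl, 0x400) != 0,
    mapped = bitwAnd(fl, 0x4) == 0,
    mate_mapped = bitwAnd(fl, 0x8) == 0,
    proper = bitwAnd(fl, 0x2) != 0,
    paired = bitwAnd(fl, 0x1) != 0)
  spl <- split(info, info$qname)
  status <- vapply(spl, function(d) {
    if (nrow(d) > 2)
      stop("read name '", d$qname[1],
           "' has more than two primary records", call. = FALSE)
    if (any(d$dup)) return("duplicate")
    if (nrow(d) != 2 || !all(d$paired)) return("unpaired")
    ok <- if (mate_mode == "strict")
      all(d$mapped & d$mate_mapped & d$proper)
    else any(d$mapped)
    if (ok) "aligned" else "unaligned"
  }, character(1))
  data.frame(read_id = names(spl), status = unname(status),
             stringsAsFactors = FALSE)
}

#' Ingest name-matched dual-genome alignments
#'
#' Reads two SAM files containing the same read pairs aligned separately
#' against the graft (human) and host (mouse) genomes and produces one
#' record per read-pair name. A pair counts as aligned to a genome when both
#' mates map to it as primary alignments flagged properly paired
#' (`mate_mode = "strict"`, the default; `"any"` accepts one mapped mate).
#' Pairs marked duplicate ("redundant") or lacking a complete mate pair in
#' either file are removed before classification, as are their records in
#' the other genome. Secondary and supplementary alignments are ignored —
#' the primary alignment decides. A name absent from one file counts as not
#' aligned to that genome.
#'
#' @param sam_graft,sam_host Paths to the two SAM (or BAM) files.
#' @param mate_mode `"strict"` or `"any"`.
#' @return A data.frame (`read_id`, `human_aligned`, `mouse_aligned`),
#'   sorted by read id — the result is independent of record order in the
#'   inputs.
#' @export
ingest_alignments <- function(sam_graft, sam_host,
                              mate_mode = c("strict", "any")) {
  mate_mode <- match.arg(mate_mode)
  g <- sam_pair_status(sam_graft, mate_mode)
  h <- sam_pair_status(sam_host, mate_mode)
  ids <- sort(union(g$read_id, h$read_id))
  gs <- g$status[match(ids, g$read_id)]
  hs <- h$status[match(ids, h$read_id)]
  gs[is.na(gs)] <- "unaligned"
  hs[is.na(hs)] <- "unaligned"
  drop <- gs %in% c("duplicate", "unpaired") |
    hs %in% c("duplicate", "unpaired")
  data.frame(read_id = ids[!drop],
             human_aligned = gs[!drop] == "aligned",
             mouse_aligned = hs[!drop] == "aligned",
             stringsAsFactors = FALSE)
}

#' Classify read pairs and apply the xenograft keep rule
#'
#' Assigns each record to one of four classes — human-only, mouse-only,
#' both genomes, neither — and keeps for downstream analysis the reads
#' aligning only to human or to both human and mouse; mouse-only pairs are
#' host contamination and neither-class pairs carry no usable signal.
#'
#' @param records Data.frame as from [ingest_alignments()] or
#'   [generate_read_records()].
#' @return A list with `kept` (read-id vector) and `summary`, a list of
#'   per-class counts plus `kept`/`discarded` totals (class
#'   `read_class_summary`).
#' @export
classify_read_pairs <- function(records) {
  stopifnot(all(c("read_id", "human_aligned", "mouse_aligned") %in%
                  names(records)))
  if (anyDuplicated(records$read_id))
    stop("duplicated read ids in the record set")
  cls <- ifelse(records$human_aligned & records$mouse_aligned, "both",
         ifelse(records$human_aligned, "human_only",
         ifelse(records$mouse_aligned, "mouse_only", "neither")))
  counts <- vapply(READ_CLASSES, function(k) sum(cls == k), integer(1))
  kept <- records$read_id[cls %in% c("human_only", "both")]
  summary <- structure(
    c(as.list(counts),
      list(kept = length(kept),
           discarded = nrow(records) - length(kept),
           total = nrow(records))),
    class = "read_class_summary")
  list(kept = kept, class = cls, summary = summary)
}

#' @export
print.read_class_summary <- function(x, ...) {
  cat("Read-pair classification\n")
  for (k in READ_CLASSES) cat(sprintf("  %-10s %d\n", k, x[[k]]))
  cat(sprintf("  kept %d / %d (human_only + both)\n", x$kept, x$total))
  invisible(x)
}

#' Concordance between two kept-read sets
#'
#' Compares the read set kept by this filter with one produced by an
#' alternative protocol (e.g. a k-mer based xenograft classifier) on the
#' same reads: Jaccard overlap |A n B| / |A u B| plus the two containment
#' fractions.
#'
#' @param kept_a,kept_b Read-id vectors.
#' @return A list with `jaccard`, `containment_a`, `containment_b`,
#'   `shared`; all `NA` when both sets are empty.
#' @export
keepset_concordance <- function(kept_a, kept_b) {
  if (!length(kept_a) && !length(kept_b))
    return(list(jaccard = NA_real_, containment_a = NA_real_,
                containment_b = NA_real_, shared = 0L))
  shared <- length(intersect(kept_a, kept_b))
  list(jaccard = shared / length(union(kept_a, kept_b)),
       containment_a = if (length(kept_a)) shared / length(kept_a)
                       else NA_real_,
       containment_b = if (length(kept_b)) shared / length(kept_b)
                       else NA_real_,
       shared = shared)
}
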