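## GTF input/output. Parsing is delegated to rtracklayer; a cheap line scan
## beforehand gives file/line-accurate errors for malformed attribute blocks,
## which the generic importer cannot report.

validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GTF record at line ", i, " of ", path,
           ": expected 9 tab-separated fields", call. = FALSE)
    if (f[3] == "exon" &&
        (!grepl("gene_id\\s+\"[^\"]*\"", f[9]) ||
         !grepl("transcript_id\\s+\"[^\"]*\"", f[9])))
      stop("malformed attribute block at line ", i, " of ", path,
           ": exon feature lacks gene_id/transcript_id", call. = FALSE)
  }
  invisible(lines)
}

## collapse duplicate exon records, merge touching intervals, reject overlaps
clean_exons <- function(ex, transcript_id) {
  ex <- unique(ex)
  ex <- ex[order(ex[, 1L], ex[, 2L]), , drop = FALSE]
  if (nrow(ex) > 1L) {
    if (any(ex[-nrow(ex), 2L] > ex[-1L, 1L]))
      stop("overlapping exons within transcript ", transcript_id,
           call. = FALSE)
    keep <- logical(nrow(ex)); keep[1] <- TRUE
    out <- ex[1L, , drop = FALSE]
    for (i in 2L:nrow(ex)) {
      j <- nrow(out)
      if (ex[i, 1L] == out[j, 2L]) out[j, 2L] <- ex[i, 2L]
      else out <- rbind(out, ex[i, , drop = FALSE])
    }
    ex <- out
  }
  ex
}

gtf_to_transcripts <- function(path) {
  lines <- validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  is_exon <- as.character(mc$type) == "exon"
  ## transcripts declared but with zero exon records are rejected by id
  declared <- unique(as.character(mc$transcript_id[
    as.character(mc$type) %in% c("transcript", "mRNA")]))
  with_exons <- unique(as.character(mc$transcript_id[is_exon]))
  orphan <- setdiff(declared, with_exons)
  if (length(orphan))
    stop("transcript with zero exon records: ", orphan[1], call. = FALSE)
  if (!any(is_exon))
    return(list())
  gr <- gr[is_exon]
  mc <- S4Vectors::mcols(gr)
  tid <- as.character(mc$transcript_id)
  gid <- as.character(mc$gene_id)
  coding <- if ("coding" %in% colnames(mc)) {
    tolower(as.character(mc$coding)) %in% c("true", "1", "yes")
  } else if ("transcript_biotype" %in% colnames(mc)) {
    as.character(mc$transcript_biotype) == "protein_coding"
  } else rep(TRUE, length(gr))
  ## GTF is 1-based inclusive; internal representation 0-based half-open
  start0 <- BiocGenerics::start(gr) - 1
  end0 <- BiocGenerics::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("exon with undefined strand for transcript ",
         tid[!strand %in% c("+", "-")][1], call. = FALSE)
  out <- lapply(split(seq_along(gr), tid), function(ii) {
    if (length(unique(chrom[ii])) > 1L || length(unique(strand[ii])) > 1L)
      stop("transcript ", tid[ii[1]], " spans multiple chromosomes/strands",
           call. = FALSE)
    ex <- clean_exons(cbind(start0[ii], end0[ii]), tid[ii[1]])
    transcript_model(tid[ii[1]], gid[ii[1]], chrom[ii[1]], strand[ii[1]],
                     ex, coding = any(coding[ii]))
  })
  unname(out)
}

#' Read a reference annotation from GTF
#'
#' Only `exon` features are used; coordinates are converted from GTF's
#' 1-based inclusive convention to the internal 0-based half-open one, exon
#' records per transcript are sorted and duplicate records collapsed, and
#' all classifier indexes are built.
#'
#' @param path Path to a GTF file whose exon features carry `gene_id` and
#'   `transcript_id` attributes.
#' @return An [build_annotation()] object.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  build_annotation(gtf_to_transcripts(path))
}

#' Read observed transcript models from GTF (no gene indexing)
#'
#' @param path Path to a GTF file.
#' @return List of [transcript_model()] objects.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gtf_to_transcripts(path)
}

#' Read observed transcript models from BED12
#'
#' `blockStarts`/`blockSizes` become exons. BED carries no gene attribution,
#' so `gene_id` is set to the record name; a record is flagged coding when it
#' has a non-empty thick (CDS) region.
#'
#' @param path Path to a BED12 file.
#' @return List of [transcript_model()] objects.
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- S4Vectors::mcols(gr)$blocks
  thick <- S4Vectors::mcols(gr)$thick
  lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    off <- BiocGenerics::start(gr)[i] - 1   # back to 0-based
    ex <- cbind(off + BiocGenerics::start(b) - 1,
                off + BiocGenerics::end(b))
    nm <- as.character(S4Vectors::mcols(gr)$name[i])
    transcript_model(nm, nm,
                     as.character(GenomicRanges::seqnames(gr))[i],
                     as.character(BiocGenerics::strand(gr))[i],
                     ex,
                     coding = !is.null(thick) && IRanges::width(thick)[i] > 0)
  })
}

#' Write transcript models to GTF
#'
#' Emits one `transcript` and per-exon `exon` records per isoform, 1-based
#' inclusive. Round-trips exactly with [read_annotation()] on
#' (chrom, strand, exon list, ids, coding flag).
#'
#' @param ts List of [transcript_model()] objects or an `annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(ts, path) {
  if (inherits(ts, "annotation")) ts <- unname(ts$tx)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 2\n##source isoformshift", con)
  for (t in ts) {
    attr0 <- sprintf('gene_id "%s"; transcript_id "%s"; coding "%s";',
                     t$gene_id, t$transcript_id,
                     if (t$coding) "true" else "false")
    n <- nrow(t$exons)
    writeLines(sprintf("%s\tisoformshift\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       t$chrom, as.integer(t$exons[1, 1] + 1),
                       as.integer(t$exons[n, 2]), t$strand, attr0), con)
    writeLines(sprintf(
      '%s\tisoformshift\texon\t%d\t%d\t.\t%s\t.\t%s exon_number "%d";',
      t$chrom, as.integer(t$exons[, 1] + 1), as.integer(t$exons[, 2]),
      t$strand, attr0, seq_len(n)), con)
  }
  invisible(path)
}
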