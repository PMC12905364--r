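#' Transcript model
#'
#' An isoform is represented by its exon chain on the genome: an ordered set
#' of non-overlapping `[start, end)` intervals (0-based half-open), a
#' chromosome, a strand and the gene it belongs to. All downstream logic
#' (structural classification, splice-event enumeration) operates on this
#' representation; no sequence is kept.
#'
#' @param transcript_id,gene_id Character identifiers (treated as opaque).
#' @param chrom Chromosome name (exact-string semantics).
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix (start, end), 0-based half-open.
#'   Rows are sorted by start; intervals must be disjoint
#'   (`end_i < start_{i+1}`).
#' @param coding Logical flag carried through from the input annotation;
#'   never computed.
#' @return An object of class `transcript_model`.
#' @examples
#' t1 <- transcript_model("tx1", "g1", "chr1", "+",
#'                        cbind(c(0, 200), c(100, 300)))
#' transcript_length(t1)  # 200
#' junction_chain(t1)
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             coding = TRUE) {
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", transcript_id,
         call. = FALSE)
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L)
    stop("transcript ", transcript_id, " has no exons", call. = FALSE)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("empty exon interval in transcript ", transcript_id, call. = FALSE)
  if (nrow(exons) > 1L &&
      any(exons[-nrow(exons), 2L] >= exons[-1L, 1L]))
    stop("overlapping or adjacent exons in transcript ", transcript_id,
         call. = FALSE)
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom),
         strand = strand,
         exons = exons,
         coding = isTRUE(coding)),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s), %d bp\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), transcript_length(x)))
  invisible(x)
}

#' Mature transcript length in bp
#' @param t A `transcript_model`.
#' @return Sum of exon lengths.
#' @export
transcript_length <- function(t) sum(t$exons[, 2L] - t$exons[, 1L])

#' Splice-junction chain of a transcript
#'
#' Returns the introns of a transcript in genomic order. Each junction has a
#' donor (the exon boundary at the 5' end of the intron in transcript
#' orientation) and an acceptor (3' end): on `+` the donor is the left
#' boundary (`donor < acceptor`), on `-` the right one (`donor > acceptor`).
#'
#' @param t A `transcript_model`.
#' @return A data frame with one row per junction (k exons yield k-1 rows):
#'   `chrom`, `strand`, `left`, `right` (genomic boundaries), `donor`,
#'   `acceptor`. Mono-exonic transcripts yield zero rows.
#' @export
junction_chain <- function(t) {
  k <- nrow(t$exons)
  if (k < 2L)
    return(data.frame(chrom = character(), strand = character(),
                      left = numeric(), right = numeric(),
                      donor = numeric(), acceptor = numeric()))
  left <- t$exons[-k, 2L]
  right <- t$exons[-1L, 1L]
  if (t$strand == "+") {
    donor <- left; acceptor <- right
  } else {
    donor <- right; acceptor <- left
  }
  data.frame(chrom = t$chrom, strand = t$strand, left = left, right = right,
             donor = donor, acceptor = acceptor)
}

## junction chain as a delimited string; substring containment on these
## strings is exactly the consecutive-sub-chain relation.
chain_string <- function(t) {
  k <- nrow(t$exons)
  if (k < 2L) return("")
  paste0("|", paste(t$exons[-k, 2L], t$exons[-1L, 1L], sep = ":",
                    collapse = "|"), "|")
}

strand_key <- function(chrom, strand) paste0(chrom, "|", strand)

## merge sorted intervals (matrix start,end) into a disjoint cover
merge_intervals <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  for (i in 2L:nrow(m)) {
    j <- nrow(out)
    if (m[i, 1L] <= out[j, 2L]) out[j, 2L] <- max(out[j, 2L], m[i, 2L])
    else out <- rbind(out, m[i, , drop = FALSE])
  }
  out
}

#' Build an indexed annotation from transcript models
#'
#' Groups transcripts by gene and derives the indexes the classifier and
#' event enumerator need: per chromosome/strand donor, acceptor and junction
#' sets, per-transcript junction-chain keys, gene genomic spans, and merged
#' per-gene exon and intron intervals.
#'
#' @param transcripts List of [transcript_model()] objects.
#' @return An object of class `annotation` with elements `tx` (named list of
#'   transcripts), `genes` (data frame of spans) and internal indexes.
#' @export
build_annotation <- function(transcripts) {
  if (length(transcripts) == 0L)
    stop("annotation must contain at least one transcript", call. = FALSE)
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids))
    stop("duplicate transcript_id: ", ids[duplicated(ids)][1], call. = FALSE)
  names(transcripts) <- ids

  gene_id <- vapply(transcripts, `[[`, character(1), "gene_id")
  chrom <- vapply(transcripts, `[[`, character(1), "chrom")
  strand <- vapply(transcripts, `[[`, character(1), "strand")
  start <- vapply(transcripts, function(t) t$exons[1L, 1L], numeric(1))
  end <- vapply(transcripts, function(t) t$exons[nrow(t$exons), 2L], numeric(1))

  ## gene spans; a gene must live on one chrom/strand
  genes <- do.call(rbind, lapply(split(seq_along(transcripts), gene_id),
    function(ii) {
      if (length(unique(chrom[ii])) > 1L || length(unique(strand[ii])) > 1L)
        stop("gene ", gene_id[ii[1]],
             " has transcripts on multiple chromosomes/strands",
             call. = FALSE)
      data.frame(gene_id = gene_id[ii[1]], chrom = chrom[ii[1]],
                 strand = strand[ii[1]],
                 start = min(start[ii]), end = max(end[ii]))
    }))
  rownames(genes) <- genes$gene_id

  gene_exons <- lapply(split(seq_along(transcripts), gene_id), function(ii) {
    merge_intervals(do.call(rbind, lapply(transcripts[ii], `[[`, "exons")))
  })
  gene_introns <- lapply(names(gene_exons), function(g) {
    ex <- gene_exons[[g]]
    if (nrow(ex) < 2L) return(matrix(numeric(0), ncol = 2))
    cbind(ex[-nrow(ex), 2L], ex[-1L, 1L])
  })
  names(gene_introns) <- names(gene_exons)

  ## per chrom|strand indexes
  skey <- strand_key(chrom, strand)
  idx <- lapply(split(seq_along(transcripts), skey), function(ii) {
    donors <- numeric(0); acceptors <- numeric(0); jkeys <- character(0)
    chains <- character(0)
    for (i in ii) {
      jc <- junction_chain(transcripts[[i]])
      donors <- c(donors, jc$donor)
      acceptors <- c(acceptors, jc$acceptor)
      jkeys <- c(jkeys, paste(jc$left, jc$right, sep = ":"))
      chains[[transcripts[[i]]$transcript_id]] <- chain_string(transcripts[[i]])
    }
    chains <- chains[chains != ""]
    chain_to_tx <- split(names(chains), unname(chains))
    chain_to_tx <- lapply(chain_to_tx, sort)
    list(donors = unique(donors), acceptors = unique(acceptors),
         junctions = unique(jkeys), chains = chains,
         chain_to_tx = chain_to_tx,
         tx_ids = names(transcripts)[ii])
  })

  structure(list(tx = transcripts, tx_gene = stats::setNames(gene_id, ids),
                 genes = genes, gene_exons = gene_exons,
                 gene_introns = gene_introns, idx = idx),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %d transcript(s), %d gene(s) on %d chromosome(s)\n",
              length(x$tx), nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Number of isoforms per gene
#' @param ann An `annotation`.
#' @return Named integer vector, one entry per gene.
#' @export
isoforms_per_gene <- function(ann) {
  tab <- table(ann$tx_gene)
  stats::setNames(as.integer(tab), names(tab))
}
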