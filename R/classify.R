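## SQANTI-style structural classification of observed transcripts against a
## reference annotation. The decision procedure is an ordered rule list; every
## query receives exactly one category.

CLASS_LEVELS <- c("FSM", "ISM", "NIC", "NNC", "fusion", "genic", "antisense",
                  "intergenic", "genic_intron")

## any interval of a overlaps any interval of b (half-open)
intervals_overlap <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(FALSE)
  for (i in seq_len(nrow(a)))
    if (any(a[i, 1L] < b[, 2L] & a[i, 2L] > b[, 1L])) return(TRUE)
  FALSE
}

interval_contained <- function(s, e, b) {
  nrow(b) > 0L && any(b[, 1L] <= s & e <= b[, 2L])
}

#' Structurally classify one transcript against a reference annotation
#'
#' Assigns exactly one of `FSM`, `ISM`, `NIC`, `NNC`, `fusion`, `genic`,
#' `antisense`, `intergenic`, `genic_intron`, evaluating an ordered rule
#' list: exact junction-chain match (FSM, terminal exon ends ignored),
#' consecutive sub-chain (ISM), multi-gene bridging chain (fusion), novel
#' chain over annotated junctions or sites (NIC), unannotated donor/acceptor
#' (NNC), then the mono-exonic and locus-position rules. Mono-exonic queries
#' match a mono-exonic reference within `mono_tol` bp at each terminus or
#' must be contained in a reference exon to be FSM.
#'
#' @param q A [transcript_model()] (the observed transcript; its strand is
#'   trusted as given).
#' @param ann An indexed [build_annotation()] reference.
#' @param mono_tol Terminal tolerance (bp) for mono-exonic FSM matching.
#' @return One-row data frame: `transcript_id`, `category`,
#'   `matched_gene_id`, `matched_transcript_id`, `length`, `n_exons`, and
#'   known/novel donor, acceptor and junction counts.
#' @export
classify_transcript <- function(q, ann, mono_tol = 50) {
  key <- strand_key(q$chrom, q$strand)
  idx <- ann$idx[[key]]
  jc <- junction_chain(q)
  nj <- nrow(jc)

  g <- ann$genes
  same <- g$gene_id[g$chrom == q$chrom & g$strand == q$strand &
                    g$start < q$exons[nrow(q$exons), 2L] &
                    g$end > q$exons[1L, 1L]]
  opp <- g$gene_id[g$chrom == q$chrom & g$strand != q$strand &
                   g$start < q$exons[nrow(q$exons), 2L] &
                   g$end > q$exons[1L, 1L]]

  known_d <- known_a <- known_j <- 0L
  if (nj > 0L && !is.null(idx)) {
    known_d <- sum(jc$donor %in% idx$donors)
    known_a <- sum(jc$acceptor %in% idx$acceptors)
    known_j <- sum(paste(jc$left, jc$right, sep = ":") %in% idx$junctions)
  }
  res <- function(category, gene = NA_character_, tx = NA_character_) {
    data.frame(transcript_id = q$transcript_id, category = category,
               matched_gene_id = gene, matched_transcript_id = tx,
               length = transcript_length(q), n_exons = nrow(q$exons),
               known_donors = known_d, novel_donors = nj - known_d,
               known_acceptors = known_a, novel_acceptors = nj - known_a,
               known_junctions = known_j, novel_junctions = nj - known_j,
               stringsAsFactors = FALSE)
  }

  ## gene with largest exonic overlap, for gene attribution of novel classes
  best_gene <- function(cands) {
    if (length(cands) == 0L) return(NA_character_)
    ov <- vapply(cands, function(gg) {
      ge <- ann$gene_exons[[gg]]
      tot <- 0
      for (i in seq_len(nrow(q$exons))) {
        o <- pmin(q$exons[i, 2L], ge[, 2L]) - pmax(q$exons[i, 1L], ge[, 1L])
        tot <- tot + sum(o[o > 0])
      }
      tot
    }, numeric(1))
    cands[order(-ov, cands)][1L]
  }

  if (length(same) > 0L && nj > 0L) {
    qchain <- chain_string(q)
    ## (1) FSM: identical junction chain
    hit <- idx$chain_to_tx[[qchain]]
    if (!is.null(hit))
      return(res("FSM", gene = ann$tx_gene[[hit[1L]]], tx = hit[1L]))
    ## (2) ISM: consecutive sub-chain of a reference chain
    sub <- names(idx$chains)[grepl(qchain, idx$chains, fixed = TRUE)]
    if (length(sub) > 0L) {
      tx <- sort(sub)[1L]
      return(res("ISM", gene = ann$tx_gene[[tx]], tx = tx))
    }
    ## (3) fusion: exonic overlap with >= 2 same-strand genes, bridged
    ex_ov <- same[vapply(same, function(gg)
      intervals_overlap(q$exons, ann$gene_exons[[gg]]), logical(1))]
    if (length(ex_ov) >= 2L) {
      gs <- g[ex_ov, , drop = FALSE]
      bridges <- FALSE
      for (i in seq_len(nj)) {
        inl <- gs$gene_id[gs$start <= jc$left[i] & jc$left[i] <= gs$end]
        inr <- gs$gene_id[gs$start <= jc$right[i] & jc$right[i] <= gs$end]
        if (length(inl) && length(inr) &&
            length(setdiff(inr, inl)) > 0L) { bridges <- TRUE; break }
      }
      if (bridges)
        return(res("fusion", gene = paste(sort(ex_ov), collapse = ",")))
    }
    ## (4) NIC / (5) NNC
    gene <- best_gene(if (length(ex_ov)) ex_ov else same)
    if (known_j == nj) return(res("NIC", gene = gene))
    if (known_d == nj && known_a == nj) return(res("NIC", gene = gene))
    return(res("NNC", gene = gene))
  }

  if (length(same) > 0L && nj == 0L) {
    qs <- q$exons[1L, 1L]; qe <- q$exons[1L, 2L]
    ## (6) mono-exonic FSM: inside a reference exon, or matching a
    ## mono-exonic reference within the end tolerance
    for (gg in sort(same)) {
      for (tt in sort(names(ann$tx_gene)[ann$tx_gene == gg])) {
        ex <- ann$tx[[tt]]$exons
        if (any(ex[, 1L] <= qs & qe <= ex[, 2L]))
          return(res("FSM", gene = gg, tx = tt))
      }
    }
    mono_ref <- Filter(function(t) nrow(t$exons) == 1L &&
                         t$chrom == q$chrom && t$strand == q$strand &&
                         abs(t$exons[1L, 1L] - qs) <= mono_tol &&
                         abs(t$exons[1L, 2L] - qe) <= mono_tol,
                       ann$tx[ann$tx_gene %in% same])
    if (length(mono_ref) > 0L) {
      tx <- sort(vapply(mono_ref, `[[`, character(1), "transcript_id"))[1L]
      return(res("FSM", gene = ann$tx_gene[[tx]], tx = tx))
    }
    ## (7) entirely within one annotated intron
    for (gg in sort(same))
      if (interval_contained(qs, qe, ann$gene_introns[[gg]]))
        return(res("genic_intron", gene = gg))
    ## (6b)/(10) same-strand overlap touching exon and intron -> genic
    return(res("genic", gene = best_gene(same)))
  }

  ## no same-strand gene overlap
  if (length(opp) > 0L) return(res("antisense", gene = sort(opp)[1L]))
  res("intergenic")
}

#' Classify a batch of transcripts and summarise lengths per category
#'
#' @param ts List of [transcript_model()] objects.
#' @param ann Reference [build_annotation()].
#' @param mono_tol Passed to [classify_transcript()].
#' @return A list with `calls` (one row per transcript) and `summary`
#'   (per observed category: n, min, q1, median, q3, p95, max of mature
#'   transcript length; empty categories are absent).
#' @export
classify_batch <- function(ts, ann, mono_tol = 50) {
  if (inherits(ts, "transcript_model")) ts <- list(ts)
  calls <- do.call(rbind, lapply(ts, classify_transcript, ann = ann,
                                 mono_tol = mono_tol))
  summ <- do.call(rbind, lapply(split(calls$length, calls$category),
                                length_summary))
  summ <- cbind(data.frame(category = rownames(summ)), summ)
  rownames(summ) <- NULL
  list(calls = calls, summary = summ[order(summ$category), , drop = FALSE])
}
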