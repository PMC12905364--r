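## Local alternative-splicing event enumeration (SUPPA-style seven-type
## taxonomy) over the transcripts of each gene, deduplicated by coordinate
## signature, with known/novel attribution from the structural classifier.

EVENT_TYPES <- c("SE", "A5", "A3", "AF", "AL", "RI", "MX")

event_row <- function(gene, type, chrom, strand, sig, incl, excl) {
  sig_s <- paste(sig, collapse = "-")
  data.frame(
    event_id = paste(type, gene, paste0(chrom, strand), sig_s, sep = ";"),
    gene_id = gene, type = type, chrom = chrom, strand = strand,
    signature = sig_s,
    inclusion = paste(sort(unique(incl)), collapse = ","),
    exclusion = paste(sort(unique(excl)), collapse = ","),
    stringsAsFactors = FALSE)
}

## all events among the transcripts of one gene
gene_events <- function(txs, gene, chrom, strand) {
  out <- list()
  n <- length(txs)
  ids <- vapply(txs, `[[`, character(1), "transcript_id")
  exl <- lapply(txs, `[[`, "exons")
  nex <- vapply(exl, nrow, integer(1))

  ## internal-exon records: cassette exon s with flanking junctions
  cas <- list()
  for (i in seq_len(n)) {
    ex <- exl[[i]]
    k <- nex[i]
    if (k < 3L) next
    for (s in 2L:(k - 1L))
      cas[[length(cas) + 1L]] <- list(
        tx = ids[i], d1 = ex[s - 1L, 2L], as = ex[s, 1L],
        ds = ex[s, 2L], a2 = ex[s + 1L, 1L],
        es = ex[s, 1L], ee = ex[s, 2L])
  }
  ## junction -> transcripts map (genomic left:right)
  jmap <- list()
  jrec <- list()   # junction with flanking exon outer boundaries, for RI
  for (i in seq_len(n)) {
    ex <- exl[[i]]
    k <- nex[i]
    if (k < 2L) next
    for (j in seq_len(k - 1L)) {
      key <- paste(ex[j, 2L], ex[j + 1L, 1L], sep = ":")
      jmap[[key]] <- c(jmap[[key]], ids[i])
      jrec[[length(jrec) + 1L]] <- list(
        tx = ids[i], c1 = ex[j, 1L], d = ex[j, 2L],
        a = ex[j + 1L, 1L], c2 = ex[j + 1L, 2L])
    }
  }

  ## SE: skip junction (d1 -> a2) present in some transcript
  for (r in cas) {
    key <- paste(r$d1, r$a2, sep = ":")
    excl <- jmap[[key]]
    if (is.null(excl)) next
    incl <- vapply(Filter(function(q) q$d1 == r$d1 && q$as == r$as &&
                            q$ds == r$ds && q$a2 == r$a2, cas),
                   `[[`, character(1), "tx")
    out[[length(out) + 1L]] <-
      event_row(gene, "SE", chrom, strand, c(r$d1, r$as, r$ds, r$a2),
                incl, excl)
  }

  ## MX: two cassettes sharing both flanks, non-overlapping
  if (length(cas) >= 2L) {
    flank <- vapply(cas, function(r) paste(r$d1, r$a2, sep = ":"),
                    character(1))
    for (grp in split(seq_along(cas), flank)) {
      if (length(grp) < 2L) next
      for (a in seq_along(grp)) for (b in seq_along(grp)) {
        if (a >= b) next
        ra <- cas[[grp[a]]]; rb <- cas[[grp[b]]]
        if (ra$es < rb$ee && ra$ee > rb$es) next   # overlapping cassettes
        if (ra$es > rb$es) { tmp <- ra; ra <- rb; rb <- tmp }
        out[[length(out) + 1L]] <-
          event_row(gene, "MX", chrom, strand,
                    c(ra$d1, ra$as, ra$ds, ra$a2, rb$d1, rb$as, rb$ds, rb$a2),
                    ra$tx, rb$tx)
      }
    }
  }

  ## A5/A3: junctions sharing one boundary in transcript orientation
  jkeys <- names(jmap)
  if (length(jkeys) >= 2L) {
    parts <- do.call(rbind, strsplit(jkeys, ":", fixed = TRUE))
    left <- as.numeric(parts[, 1L]); right <- as.numeric(parts[, 2L])
    if (strand == "+") { donor <- left; acceptor <- right }
    else { donor <- right; acceptor <- left }
    emit_pairs <- function(shared_vals, type, shared, alt) {
      for (v in unique(shared_vals)) {
        ii <- which(shared_vals == v)
        if (length(ii) < 2L) next
        alts <- sort(alt[ii])
        for (a in seq_along(ii)) for (b in seq_along(ii)) {
          if (a >= b) next
          d2 <- sort(alt[ii[c(a, b)]])
          out[[length(out) + 1L]] <<-
            event_row(gene, type, chrom, strand, c(v, d2[1L], d2[2L]),
                      jmap[[jkeys[ii[a]]]], jmap[[jkeys[ii[b]]]])
        }
      }
    }
    emit_pairs(acceptor, "A5", acceptor, donor)
    emit_pairs(donor, "A3", donor, acceptor)
  }

  ## AF/AL: distinct non-overlapping terminal exons splicing into the same
  ## boundary of a shared inner exon (transcript orientation)
  term <- function(first) {
    recs <- list()
    for (i in seq_len(n)) {
      ex <- exl[[i]]; k <- nex[i]
      if (k < 2L) next
      at_left <- (strand == "+") == first    # terminal exon is leftmost?
      if (at_left)
        recs[[length(recs) + 1L]] <- list(tx = ids[i], s = ex[1L, 1L],
                                          e = ex[1L, 2L], inner = ex[2L, 1L],
                                          outer = ex[1L, 1L])
      else
        recs[[length(recs) + 1L]] <- list(tx = ids[i], s = ex[k, 1L],
                                          e = ex[k, 2L],
                                          inner = ex[k - 1L, 2L],
                                          outer = ex[k, 2L])
    }
    recs
  }
  emit_term <- function(recs, type) {
    if (length(recs) < 2L) return()
    shared <- vapply(recs, `[[`, numeric(1), "inner")
    for (v in unique(shared)) {
      ii <- which(shared == v)
      if (length(ii) < 2L) next
      for (a in seq_along(ii)) for (b in seq_along(ii)) {
        if (a >= b) next
        ra <- recs[[ii[a]]]; rb <- recs[[ii[b]]]
        if (ra$s < rb$e && ra$e > rb$s) next        # overlapping exons
        if (ra$s > rb$s) { tmp <- ra; ra <- rb; rb <- tmp }
        out[[length(out) + 1L]] <<-
          event_row(gene, type, chrom, strand,
                    c(ra$s, ra$e, v, rb$s, rb$e, v), ra$tx, rb$tx)
      }
    }
  }
  emit_term(term(first = TRUE), "AF")
  emit_term(term(first = FALSE), "AL")

  ## RI: one exon spans exactly the two flanking exons plus the intron
  if (length(jrec) > 0L) {
    span_key <- vapply(jrec, function(r) paste(r$c1, r$c2, sep = ":"),
                       character(1))
    for (i in seq_len(n)) {
      ex <- exl[[i]]
      for (s in seq_len(nex[i])) {
        key <- paste(ex[s, 1L], ex[s, 2L], sep = ":")
        hits <- which(span_key == key)
        for (h in hits) {
          r <- jrec[[h]]
          out[[length(out) + 1L]] <-
            event_row(gene, "RI", chrom, strand, c(r$c1, r$d, r$a, r$c2),
                      ids[i], r$tx)
        }
      }
    }
  }

  out
}

#' Enumerate local alternative-splicing events within each gene
#'
#' Scans every gene's transcripts for skipped exons (SE), alternative 5'/3'
#' splice sites (A5/A3, donor/acceptor in transcript orientation),
#' alternative first/last exons (AF/AL), retained introns (RI) and mutually
#' exclusive exons (MX), deduplicated by coordinate signature. Inclusion and
#' exclusion sides of duplicate detections are merged.
#'
#' @param ann An [build_annotation()] object, typically reference plus
#'   observed transcripts (see [merge_observed()]).
#' @param novel_ids Character vector of transcript ids considered novel
#'   (non-FSM/ISM observed transcripts); an event is `novel` iff any
#'   transcript on its inclusion or exclusion side is in this set.
#' @return Data frame: `event_id`, `gene_id`, `type`, `chrom`, `strand`,
#'   `signature`, `inclusion`, `exclusion`, `novelty`.
#' @export
enumerate_events <- function(ann, novel_ids = character()) {
  rows <- list()
  for (gg in rownames(ann$genes)) {
    txs <- ann$tx[names(ann$tx_gene)[ann$tx_gene == gg]]
    strands <- unique(vapply(txs, `[[`, character(1), "strand"))
    if (length(strands) > 1L)
      stop("mixed-strand gene: ", gg, call. = FALSE)
    if (length(txs) < 2L) next
    rows <- c(rows, gene_events(txs, gg, ann$genes[gg, "chrom"], strands))
  }
  if (length(rows) == 0L)
    return(data.frame(event_id = character(), gene_id = character(),
                      type = character(), chrom = character(),
                      strand = character(), signature = character(),
                      inclusion = character(), exclusion = character(),
                      novelty = character(), stringsAsFactors = FALSE))
  ev <- do.call(rbind, rows)
  ## merge duplicate signatures: union of inclusion/exclusion sides
  merge_side <- function(x) paste(sort(unique(unlist(
    strsplit(x, ",", fixed = TRUE)))), collapse = ",")
  agg <- lapply(split(seq_len(nrow(ev)), ev$event_id), function(ii) {
    r <- ev[ii[1L], , drop = FALSE]
    r$inclusion <- merge_side(ev$inclusion[ii])
    r$exclusion <- merge_side(ev$exclusion[ii])
    r
  })
  ev <- do.call(rbind, agg)
  rownames(ev) <- NULL
  touched <- function(incl, excl) {
    any(unlist(strsplit(c(incl, excl), ",", fixed = TRUE)) %in% novel_ids)
  }
  ev$novelty <- ifelse(mapply(touched, ev$inclusion, ev$exclusion),
                       "novel", "known")
  ev[order(ev$event_id), , drop = FALSE]
}

#' Count splicing events by type
#'
#' @param events Output of [enumerate_events()].
#' @param novelty_split Split counts into known/novel columns?
#' @return Data frame with one row per event type (SE, A5, A3, AF, AL, RI,
#'   MX) and columns `known`/`novel` (or a single `count`).
#' @export
count_events <- function(events, novelty_split = TRUE) {
  type <- factor(events$type, levels = EVENT_TYPES)
  if (novelty_split) {
    nov <- factor(events$novelty %||% rep("known", nrow(events)),
                  levels = c("known", "novel"))
    tab <- table(type, nov)
    data.frame(type = rownames(tab), known = as.integer(tab[, "known"]),
               novel = as.integer(tab[, "novel"]), stringsAsFactors = FALSE)
  } else {
    tab <- table(type)
    data.frame(type = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }
}

#' Merge observed transcripts into a reference annotation
#'
#' Observed transcripts adopt the gene of their structural call; calls
#' without a single-gene attribution (fusion, antisense, intergenic) are
#' dropped. Used to enumerate known+novel splice events jointly.
#'
#' @param ann Reference [build_annotation()].
#' @param obs List of observed [transcript_model()]s.
#' @param calls `calls` data frame from [classify_batch()] on `obs`.
#' @return A list: `annotation` (merged) and `novel_ids` (observed
#'   transcripts that are not FSM/ISM), ready for [enumerate_events()].
#' @export
merge_observed <- function(ann, obs, calls) {
  names(obs) <- vapply(obs, `[[`, character(1), "transcript_id")
  keep <- calls[calls$category %in% c("FSM", "ISM", "NIC", "NNC") &
                  !is.na(calls$matched_gene_id), , drop = FALSE]
  extra <- lapply(seq_len(nrow(keep)), function(i) {
    t <- obs[[keep$transcript_id[i]]]
    t$gene_id <- keep$matched_gene_id[i]
    t
  })
  ## drop observed transcripts that duplicate a reference id
  extra <- Filter(function(t) !t$transcript_id %in% names(ann$tx), extra)
  merged <- build_annotation(c(unname(ann$tx), extra))
  list(annotation = merged,
       novel_ids = keep$transcript_id[!keep$category %in% c("FSM", "ISM")])
}
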