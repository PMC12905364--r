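## Seeded generators for synthetic reference annotations and perturbed
## "observed" transcripts with truth labels, emulating a long-read isoform
## discovery experiment: most genes carry one isoform with a heavy
## multi-isoform tail, and observed transcripts are reference copies plus
## structured novelty (skips, site shifts, retained introns, fusions, ...).

#' Default per-gene isoform-count distribution
#'
#' Probability that an annotated gene has k = 1..7 isoforms; most genes have
#' a single isoform with a heavy tail, the shape of per-gene isoform counts
#' in annotated cohorts.
#' @return Numeric probability vector over k = 1..7.
#' @export
default_isoform_distribution <- function() {
  c(0.55, 0.20, 0.10, 0.06, 0.04, 0.03, 0.02)
}

## sample one element of a vector safely (avoids the length-1 sample() trap)
pick1 <- function(v) v[sample.int(length(v), 1L)]

## derive one alternative isoform structure from a base exon matrix;
## returns NULL when the strategy is impossible
derive_isoform <- function(ex, introns_ok = TRUE) {
  k <- nrow(ex)
  strategy <- sample(c("skip", "site", "alt_first", "ri"), 1L,
                     prob = c(0.45, 0.25, 0.15, 0.15))
  if (strategy == "skip" && k >= 3L) {
    drop <- which(stats::runif(k) < 0.4)
    drop <- setdiff(drop, c(1L, k))
    if (length(drop) == 0L) drop <- pick1(2L:(k - 1L))
    return(ex[-drop, , drop = FALSE])
  }
  if (strategy == "site" && k >= 2L) {
    i <- sample(seq_len(k - 1L), 1L)
    delta <- sample(30:60, 1L)
    side <- sample(c("donor", "acceptor"), 1L)
    ex2 <- ex
    if (side == "donor") {
      new_end <- ex[i, 2L] - delta
      if (new_end <= ex[i, 1L] + 20) return(NULL)
      ex2[i, 2L] <- new_end
    } else {
      new_start <- ex[i + 1L, 1L] + delta
      if (new_start >= ex[i + 1L, 2L] - 20) return(NULL)
      ex2[i + 1L, 1L] <- new_start
    }
    return(ex2)
  }
  if (strategy == "alt_first" && k >= 3L) {
    gap <- ex[2L, 1L] - ex[1L, 2L]
    if (gap < 260) return(NULL)
    start <- ex[1L, 2L] + pick1(seq(30L, gap - 230L))
    len <- sample(80:150, 1L)
    return(rbind(c(start, start + len), ex[-1L, , drop = FALSE]))
  }
  if (strategy == "ri" && k >= 4L) {
    i <- pick1(2L:(k - 2L))
    ex2 <- ex[-(i + 1L), , drop = FALSE]
    ex2[i, 2L] <- ex[i + 1L, 2L]
    return(ex2)
  }
  NULL
}

#' Generate a synthetic multi-isoform reference annotation
#'
#' Genes are tiled non-overlapping across synthetic chromosomes on both
#' strands; each gene draws its isoform count from
#' `isoform_count_distribution` and derives additional isoforms from a base
#' exon chain by exon skipping, splice-site variants, alternative first
#' exons and intron retention, so sibling isoforms always share the terminal
#' exon. Deterministic for a fixed seed (byte-identical GTF output).
#'
#' @param n_genes Number of genes (>= 1).
#' @param isoform_count_distribution Probabilities for 1, 2, ... isoforms
#'   per gene.
#' @param seed RNG seed.
#' @param genes_per_chrom Genes tiled per synthetic chromosome.
#' @return An [build_annotation()] object.
#' @export
make_annotation <- function(n_genes,
                            isoform_count_distribution =
                              default_isoform_distribution(),
                            seed = 1L, genes_per_chrom = 25L) {
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  p <- isoform_count_distribution
  if (!is.numeric(p) || any(p < 0) || sum(p) <= 0)
    stop("isoform-count distribution must have positive mass on counts >= 1",
         call. = FALSE)
  p <- p / sum(p)
  with_seed(seed, {
    tx <- list()
    cursor <- 10000
    chrom_i <- 1L
    in_chrom <- 0L
    for (g in seq_len(n_genes)) {
      if (in_chrom >= genes_per_chrom) {
        chrom_i <- chrom_i + 1L; in_chrom <- 0L; cursor <- 10000
      }
      in_chrom <- in_chrom + 1L
      chrom <- paste0("chr", chrom_i)
      strand <- sample(c("+", "-"), 1L)
      n_iso <- sample(seq_along(p), 1L, prob = p)
      n_ex <- 1L + stats::rpois(1L, 6L)
      if (n_iso > 1L) n_ex <- max(n_ex, 4L)
      ex_len <- sample(80:300, n_ex, replace = TRUE)
      intron_len <- if (n_ex > 1L) sample(300:2000, n_ex - 1L,
                                          replace = TRUE) else integer(0)
      start <- cursor + cumsum(c(0, ex_len[-n_ex] + intron_len))
      ex <- cbind(start, start + ex_len)
      gid <- sprintf("G%05d", g)
      chains <- chain_string(list(exons = ex))
      iso_ex <- list(ex)
      tries <- 0L
      while (length(iso_ex) < n_iso && tries < 60L) {
        tries <- tries + 1L
        cand <- derive_isoform(ex)
        if (is.null(cand)) next
        cs <- chain_string(list(exons = cand))
        if (cs %in% chains) next
        chains <- c(chains, cs)
        iso_ex[[length(iso_ex) + 1L]] <- cand
      }
      for (i in seq_along(iso_ex))
        tx[[length(tx) + 1L]] <- transcript_model(
          sprintf("%s.T%d", gid, i), gid, chrom, strand, iso_ex[[i]],
          coding = stats::runif(1) < 0.8)
      cursor <- max(ex[, 2L]) + 10000
    }
    build_annotation(tx)
  })
}

PERTURB_EVENTS <- c("exact_copy", "exon_skip", "alt_donor", "alt_acceptor",
                    "alt_first", "alt_last", "intron_retain",
                    "mutually_exclusive_swap", "novel_site_shift",
                    "truncation", "antisense_copy", "intergenic_fragment",
                    "fusion_join", "intronic_fragment",
                    "exon_intron_fragment")

#' Default perturbation event mix
#'
#' Probabilities over the perturbation event types; reference copies and
#' truncations dominate (the known fraction of a long-read run), the rest
#' generate structured novelty. The two locus-fragment types that yield the
#' `genic`/`genic_intron` classes default to zero.
#' @return Named probability vector.
#' @export
default_event_mix <- function() {
  c(exact_copy = 0.35, truncation = 0.15, exon_skip = 0.10,
    alt_donor = 0.06, alt_acceptor = 0.06, alt_first = 0.05,
    alt_last = 0.05, intron_retain = 0.06, mutually_exclusive_swap = 0.04,
    novel_site_shift = 0.04, antisense_copy = 0.015,
    intergenic_fragment = 0.015, fusion_join = 0.01,
    intronic_fragment = 0, exon_intron_fragment = 0)
}

## index-lookup helpers on an annotation (constructive verification used by
## the generator; intentionally simpler than the classifier)
ann_has_chain <- function(ann, chrom, strand, cs)
  !is.null(ann$idx[[strand_key(chrom, strand)]]$chain_to_tx[[cs]])
ann_has_subchain <- function(ann, chrom, strand, cs)
  any(grepl(cs, ann$idx[[strand_key(chrom, strand)]]$chains, fixed = TRUE))
ann_site_known <- function(ann, chrom, strand, coord, side) {
  idx <- ann$idx[[strand_key(chrom, strand)]]
  coord %in% (if (side == "donor") idx$donors else idx$acceptors)
}

## one perturbation attempt; returns list(exons, strand, chrom, gene,
## template) or NULL
perturb_once <- function(ann, ev, gene_order) {
  pick_tx <- function(min_exons = 1L) {
    ok <- names(ann$tx)[vapply(ann$tx, function(t) nrow(t$exons),
                               integer(1)) >= min_exons]
    if (length(ok) == 0L) return(NULL)
    ann$tx[[sample(ok, 1L)]]
  }
  jitter_ends <- function(ex) {
    k <- nrow(ex)
    if (k < 2L) return(ex)
    ex[1L, 1L] <- max(0, ex[1L, 1L] + sample(-30:30, 1L))
    if (ex[1L, 1L] >= ex[1L, 2L] - 20) ex[1L, 1L] <- ex[1L, 2L] - 50
    ex[k, 2L] <- ex[k, 2L] + sample(-30:30, 1L)
    if (ex[k, 2L] <= ex[k, 1L] + 20) ex[k, 2L] <- ex[k, 1L] + 50
    ex
  }
  ok_novel_chain <- function(t, ex) {
    cs <- chain_string(list(exons = ex))
    cs != "" && !ann_has_chain(ann, t$chrom, t$strand, cs) &&
      !ann_has_subchain(ann, t$chrom, t$strand, cs)
  }
  res <- function(t, ex, strand = t$strand, chrom = t$chrom,
                  gene = t$gene_id)
    list(exons = ex, strand = strand, chrom = chrom, gene = gene,
         template = t$transcript_id)

  switch(ev,
    exact_copy = {
      t <- pick_tx()
      ex <- if (nrow(t$exons) >= 2L) jitter_ends(t$exons) else t$exons
      res(t, ex)
    },
    truncation = {
      t <- pick_tx(3L)
      if (is.null(t)) return(NULL)
      k <- nrow(t$exons)
      ex <- if (stats::runif(1) < 0.5) t$exons[-1L, , drop = FALSE]
            else t$exons[-k, , drop = FALSE]
      cs <- chain_string(list(exons = ex))
      if (ann_has_chain(ann, t$chrom, t$strand, cs)) return(NULL)
      if (!ann_has_subchain(ann, t$chrom, t$strand, cs)) return(NULL)
      res(t, jitter_ends(ex))
    },
    exon_skip = {
      t <- pick_tx(3L)
      if (is.null(t)) return(NULL)
      k <- nrow(t$exons)
      s <- pick1(2L:(k - 1L))
      ex <- t$exons[-s, , drop = FALSE]
      if (!ok_novel_chain(t, ex)) return(NULL)
      ## all sites annotated -> NIC by construction
      res(t, ex)
    },
    alt_donor = ,
    alt_acceptor = ,
    novel_site_shift = {
      t <- pick_tx(2L)
      if (is.null(t)) return(NULL)
      k <- nrow(t$exons)
      i <- pick1(seq_len(k - 1L))
      ex <- t$exons
      delta <- sample(c(-45:-15, 15:45), 1L)
      shift_left <- (ev == "alt_donor") == (t$strand == "+") ||
        ev == "novel_site_shift"
      if (shift_left) {
        newc <- ex[i, 2L] + delta
        if (newc <= ex[i, 1L] + 20 || newc >= ex[i + 1L, 1L] - 20)
          return(NULL)
        side <- if (t$strand == "+") "donor" else "acceptor"
        if (ann_site_known(ann, t$chrom, t$strand, newc, side)) return(NULL)
        ex[i, 2L] <- newc
      } else {
        newc <- ex[i + 1L, 1L] + delta
        if (newc <= ex[i, 2L] + 20 || newc >= ex[i + 1L, 2L] - 20)
          return(NULL)
        side <- if (t$strand == "+") "acceptor" else "donor"
        if (ann_site_known(ann, t$chrom, t$strand, newc, side)) return(NULL)
        ex[i + 1L, 1L] <- newc
      }
      res(t, ex)
    },
    alt_first = ,
    alt_last = {
      t <- pick_tx(2L)
      if (is.null(t)) return(NULL)
      k <- nrow(t$exons)
      at_left <- (ev == "alt_first") == (t$strand == "+")
      ex <- t$exons
      if (at_left) {
        gap <- ex[2L, 1L] - ex[1L, 2L]
        if (k < 2L || gap < 300) return(NULL)
        start <- ex[1L, 2L] + pick1(seq(40L, gap - 160L))
        newex <- c(start, start + sample(80:120, 1L))
        if (newex[2L] >= ex[2L, 1L] - 20) return(NULL)
        if (ann_site_known(ann, t$chrom, t$strand, newex[2L],
                           if (t$strand == "+") "donor" else "acceptor"))
          return(NULL)
        ex <- rbind(newex, ex[-1L, , drop = FALSE])
      } else {
        gap <- ex[k, 1L] - ex[k - 1L, 2L]
        if (gap < 300) return(NULL)
        end <- ex[k, 1L] - pick1(seq(40L, gap - 160L))
        newex <- c(end - sample(80:120, 1L), end)
        if (newex[1L] <= ex[k - 1L, 2L] + 20) return(NULL)
        if (ann_site_known(ann, t$chrom, t$strand, newex[1L],
                           if (t$strand == "+") "acceptor" else "donor"))
          return(NULL)
        ex <- rbind(ex[-k, , drop = FALSE], newex)
      }
      res(t, ex)
    },
    intron_retain = {
      t <- pick_tx(4L)
      if (is.null(t)) return(NULL)
      k <- nrow(t$exons)
      i <- pick1(2L:(k - 2L))
      ex <- t$exons[-(i + 1L), , drop = FALSE]
      ex[i, 2L] <- t$exons[i + 1L, 2L]
      if (!ok_novel_chain(t, ex)) return(NULL)
      res(t, ex)
    },
    mutually_exclusive_swap = {
      t <- pick_tx(3L)
      if (is.null(t)) return(NULL)
      k <- nrow(t$exons)
      s <- pick1(2L:(k - 1L))
      gap <- t$exons[s + 1L, 1L] - t$exons[s, 2L]
      if (gap < 300) return(NULL)
      start <- t$exons[s, 2L] + pick1(seq(40L, gap - 160L))
      newex <- c(start, start + sample(80:120, 1L))
      if (newex[2L] >= t$exons[s + 1L, 1L] - 20) return(NULL)
      if (ann_site_known(ann, t$chrom, t$strand, newex[1L], "donor") ||
          ann_site_known(ann, t$chrom, t$strand, newex[1L], "acceptor") ||
          ann_site_known(ann, t$chrom, t$strand, newex[2L], "donor") ||
          ann_site_known(ann, t$chrom, t$strand, newex[2L], "acceptor"))
        return(NULL)
      ex <- t$exons
      ex[s, ] <- newex
      res(t, ex)
    },
    antisense_copy = {
      t <- pick_tx()
      res(t, t$exons, strand = if (t$strand == "+") "-" else "+")
    },
    intergenic_fragment = {
      g <- ann$genes[sample(nrow(ann$genes), 1L), ]
      start <- g$end + 2000 + sample(0:2000, 1L)
      ex <- matrix(c(start, start + sample(200:600, 1L)), 1L)
      list(exons = ex, strand = sample(c("+", "-"), 1L), chrom = g$chrom,
           gene = NA_character_, template = NA_character_)
    },
    fusion_join = {
      gs <- ann$genes[order(ann$genes$chrom, ann$genes$start), ]
      same <- which(gs$chrom[-1L] == gs$chrom[-nrow(gs)] &
                      gs$strand[-1L] == gs$strand[-nrow(gs)])
      if (length(same) == 0L) return(NULL)
      i <- sample(rep(same, 2L), 1L)   # rep() guards length-1 sample()
      ga <- gs$gene_id[i]; gb <- gs$gene_id[i + 1L]
      ta <- ann$tx[[sort(names(ann$tx_gene)[ann$tx_gene == ga])[1L]]]
      tb <- ann$tx[[sort(names(ann$tx_gene)[ann$tx_gene == gb])[1L]]]
      list(exons = rbind(ta$exons, tb$exons), strand = ta$strand,
           chrom = ta$chrom, gene = paste(sort(c(ga, gb)), collapse = ","),
           template = ta$transcript_id)
    },
    intronic_fragment = {
      t <- pick_tx(2L)
      if (is.null(t)) return(NULL)
      introns <- ann$gene_introns[[t$gene_id]]
      wide <- which(introns[, 2L] - introns[, 1L] >= 300)
      if (length(wide) == 0L) return(NULL)
      i <- sample(rep(wide, 2L), 1L)
      start <- introns[i, 1L] + 50
      ex <- matrix(c(start, min(start + 150, introns[i, 2L] - 50)), 1L)
      res(t, ex)
    },
    exon_intron_fragment = {
      t <- pick_tx(2L)
      if (is.null(t)) return(NULL)
      ge <- ann$gene_exons[[t$gene_id]]
      if (nrow(ge) < 2L) return(NULL)
      i <- sample(rep(seq_len(nrow(ge) - 1L), 2L), 1L)
      ex <- matrix(c(ge[i, 2L] - 60, min(ge[i, 2L] + 90, ge[i + 1L, 1L])),
                   1L)
      if (ex[1L] <= ge[i, 1L]) return(NULL)
      res(t, ex)
    },
    NULL)
}

EVENT_CLASS <- c(exact_copy = "FSM", truncation = "ISM", exon_skip = "NIC",
                 intron_retain = "NIC", alt_donor = "NNC",
                 alt_acceptor = "NNC", alt_first = "NNC", alt_last = "NNC",
                 novel_site_shift = "NNC", mutually_exclusive_swap = "NNC",
                 antisense_copy = "antisense",
                 intergenic_fragment = "intergenic", fusion_join = "fusion",
                 intronic_fragment = "genic_intron",
                 exon_intron_fragment = "genic")

#' Perturb reference transcripts into an observed transcript set
#'
#' Draws `n` observed transcripts from the event mix; each event type
#' produces a structural class by construction (verified against the
#' annotation indexes, with bounded resampling when a template cannot host
#' the event). Terminal exon ends of copies/truncations are jittered to
#' exercise the junction-defined FSM/ISM rules.
#'
#' @param ann Reference [build_annotation()].
#' @param event_mix Named probabilities over [default_event_mix()] names.
#' @param n Number of observed transcripts to draw.
#' @param seed RNG seed.
#' @param max_retries Resampling attempts per draw before skipping with a
#'   warning.
#' @return List: `transcripts` (observed [transcript_model()]s) and `truth`
#'   (data frame: `transcript_id`, `event`, `class`, `gene_id`,
#'   `template`).
#' @export
perturb_transcripts <- function(ann, event_mix = default_event_mix(),
                                n = 500L, seed = 1L, max_retries = 20L) {
  miss <- setdiff(names(event_mix), PERTURB_EVENTS)
  if (length(miss)) stop("unknown event type: ", miss[1], call. = FALSE)
  mix <- event_mix[event_mix > 0]
  with_seed(seed, {
    obs <- list(); truth <- list()
    skipped <- 0L
    for (i in seq_len(n)) {
      ev <- sample(names(mix), 1L, prob = mix)
      cand <- NULL
      for (r in seq_len(max_retries)) {
        cand <- perturb_once(ann, ev, NULL)
        if (!is.null(cand)) break
      }
      if (is.null(cand)) { skipped <- skipped + 1L; next }
      id <- sprintf("obs%05d", i)
      gid <- cand$gene
      if (is.null(gid) || is.na(gid)) gid <- id
      obs[[length(obs) + 1L]] <- transcript_model(
        id, gid, cand$chrom, cand$strand, cand$exons)
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = id, event = ev, class = EVENT_CLASS[[ev]],
        gene_id = cand$gene %||% NA_character_,
        template = cand$template %||% NA_character_,
        stringsAsFactors = FALSE)
    }
    if (skipped > 0L)
      warning(skipped, " draw(s) skipped: no template could host the event")
    list(transcripts = obs, truth = do.call(rbind, truth))
  })
}
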