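# Independent oracles and random-fixture generators. These re-derive
# expected results from first principles (direct list comparison, exhaustive
# pair loops, grid search) and deliberately share no code with the package
# internals they check.

# ---- junction utilities (standalone) ----------------------------------------

o_junctions <- function(t) {
  k <- nrow(t$exons)
  if (k < 2L) return(matrix(numeric(0), ncol = 2))
  cbind(t$exons[-k, 2L], t$exons[-1L, 1L])
}

o_same_chain <- function(a, b) {
  nrow(a) == nrow(b) && nrow(a) > 0 && all(a == b)
}

# is `a` a consecutive sub-list of `b` (proper)?
o_subchain <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || na >= nb) return(FALSE)
  for (off in 0:(nb - na))
    if (all(b[(off + 1):(off + na), , drop = FALSE] == a)) return(TRUE)
  FALSE
}

# ---- brute-force structural classifier --------------------------------------

# refs: plain list of transcript_model; mirrors the spec's rule order
# directly on exon lists.
oracle_classify <- function(q, refs, mono_tol = 50) {
  same <- Filter(function(r) r$chrom == q$chrom && r$strand == q$strand,
                 refs)
  qspan <- c(q$exons[1, 1], q$exons[nrow(q$exons), 2])
  gene_of <- vapply(refs, `[[`, character(1), "gene_id")
  spans <- lapply(split(refs, gene_of), function(g) {
    s <- range(unlist(lapply(g, function(t) t$exons)))
    list(chrom = g[[1]]$chrom, strand = g[[1]]$strand,
         start = s[1], end = s[2], tx = g)
  })
  ov_same <- Filter(function(g) g$chrom == q$chrom &&
                      g$strand == q$strand &&
                      g$start < qspan[2] && g$end > qspan[1], spans)
  ov_opp <- Filter(function(g) g$chrom == q$chrom &&
                     g$strand != q$strand &&
                     g$start < qspan[2] && g$end > qspan[1], spans)
  qj <- o_junctions(q)
  if (length(ov_same) > 0 && nrow(qj) > 0) {
    chains <- lapply(same, o_junctions)
    if (any(vapply(chains, o_same_chain, logical(1), a = qj)))
      return("FSM")
    if (any(vapply(chains, function(c2) o_subchain(qj, c2), logical(1))))
      return("ISM")
    ex_ov_gene <- function(g) {
      any(vapply(g$tx, function(r) {
        for (i in seq_len(nrow(q$exons)))
          if (any(q$exons[i, 1] < r$exons[, 2] &
                  q$exons[i, 2] > r$exons[, 1])) return(TRUE)
        FALSE
      }, logical(1)))
    }
    hit <- Filter(ex_ov_gene, ov_same)
    if (length(hit) >= 2) {
      for (i in seq_len(nrow(qj))) {
        inl <- names(Filter(function(g) g$start <= qj[i, 1] &&
                              qj[i, 1] <= g$end, hit))
        inr <- names(Filter(function(g) g$start <= qj[i, 2] &&
                              qj[i, 2] <= g$end, hit))
        if (length(setdiff(inr, inl)) > 0) return("fusion")
      }
    }
    all_j <- do.call(rbind, chains)
    jset <- if (is.null(all_j) || nrow(all_j) == 0) character(0) else
      paste(all_j[, 1], all_j[, 2])
    if (all(paste(qj[, 1], qj[, 2]) %in% jset)) return("NIC")
    if (q$strand == "+") { don <- 1L; acc <- 2L } else { don <- 2L; acc <- 1L }
    donors <- unique(if (length(jset)) all_j[, don] else numeric(0))
    acceptors <- unique(if (length(jset)) all_j[, acc] else numeric(0))
    if (all(qj[, don] %in% donors) && all(qj[, acc] %in% acceptors))
      return("NIC")
    return("NNC")
  }
  if (length(ov_same) > 0) {
    qs <- qspan[1]; qe <- qspan[2]
    for (r in same)
      if (any(r$exons[, 1] <= qs & qe <= r$exons[, 2])) return("FSM")
    for (r in same)
      if (nrow(r$exons) == 1 && abs(r$exons[1, 1] - qs) <= mono_tol &&
          abs(r$exons[1, 2] - qe) <= mono_tol) return("FSM")
    for (g in ov_same) {
      ge <- do.call(rbind, lapply(g$tx, `[[`, "exons"))
      ge <- ge[order(ge[, 1]), , drop = FALSE]
      # merged exon cover, then introns
      merged <- ge[1, , drop = FALSE]
      for (i in seq_len(nrow(ge))[-1]) {
        j <- nrow(merged)
        if (ge[i, 1] <= merged[j, 2])
          merged[j, 2] <- max(merged[j, 2], ge[i, 2])
        else merged <- rbind(merged, ge[i, , drop = FALSE])
      }
      if (nrow(merged) > 1) {
        introns <- cbind(merged[-nrow(merged), 2], merged[-1, 1])
        if (any(introns[, 1] <= qs & qe <= introns[, 2]))
          return("genic_intron")
      }
    }
    return("genic")
  }
  if (length(ov_opp) > 0) return("antisense")
  "intergenic"
}

# ---- brute-force pairwise splice-event enumeration --------------------------

# returns a sorted character vector of unique "type sig" strings
oracle_events <- function(txs, strand) {
  out <- character(0)
  add <- function(type, sig) out <<- c(out, paste(type,
                                                  paste(sig, collapse = "-")))
  n <- length(txs)
  for (i1 in seq_len(n)) for (i2 in seq_len(n)) {
    if (i1 == i2) next
    e1 <- txs[[i1]]$exons; e2 <- txs[[i2]]$exons
    j1 <- o_junctions(txs[[i1]]); j2 <- o_junctions(txs[[i2]])
    k1 <- nrow(e1)
    # SE
    if (k1 >= 3) for (s in 2:(k1 - 1)) {
      d1 <- e1[s - 1, 2]; as_ <- e1[s, 1]; ds <- e1[s, 2]; a2 <- e1[s + 1, 1]
      if (nrow(j2) > 0 && any(j2[, 1] == d1 & j2[, 2] == a2))
        add("SE", c(d1, as_, ds, a2))
    }
    # MX: cassette in T1 and cassette in T2 sharing flanks, non-overlapping
    if (k1 >= 3 && nrow(e2) >= 3) for (s in 2:(k1 - 1)) {
      for (t in 2:(nrow(e2) - 1)) {
        if (e1[s - 1, 2] != e2[t - 1, 2] || e1[s + 1, 1] != e2[t + 1, 1])
          next
        if (e1[s, 1] < e2[t, 2] && e1[s, 2] > e2[t, 1]) next
        recs <- list(c(e1[s - 1, 2], e1[s, 1], e1[s, 2], e1[s + 1, 1]),
                     c(e2[t - 1, 2], e2[t, 1], e2[t, 2], e2[t + 1, 1]))
        ord <- order(c(e1[s, 1], e2[t, 1]))
        add("MX", c(recs[[ord[1]]], recs[[ord[2]]]))
      }
    }
    # A5/A3
    if (nrow(j1) > 0 && nrow(j2) > 0)
      for (a in seq_len(nrow(j1))) for (b in seq_len(nrow(j2))) {
        l1 <- j1[a, 1]; r1 <- j1[a, 2]; l2 <- j2[b, 1]; r2 <- j2[b, 2]
        if (strand == "+") {
          if (r1 == r2 && l1 != l2) add("A5", c(r1, sort(c(l1, l2))))
          if (l1 == l2 && r1 != r2) add("A3", c(l1, sort(c(r1, r2))))
        } else {
          if (l1 == l2 && r1 != r2) add("A5", c(l1, sort(c(r1, r2))))
          if (r1 == r2 && l1 != l2) add("A3", c(r1, sort(c(l1, l2))))
        }
      }
    # AF/AL
    if (k1 >= 2 && nrow(e2) >= 2) {
      for (first in c(TRUE, FALSE)) {
        at_left <- (strand == "+") == first
        if (at_left) {
          x1 <- e1[1, ]; in1 <- e1[2, 1]
          x2 <- e2[1, ]; in2 <- e2[2, 1]
        } else {
          x1 <- e1[k1, ]; in1 <- e1[k1 - 1, 2]
          x2 <- e2[nrow(e2), ]; in2 <- e2[nrow(e2) - 1, 2]
        }
        if (in1 == in2 && !(x1[1] < x2[2] && x1[2] > x2[1])) {
          recs <- if (x1[1] <= x2[1]) c(x1, in1, x2, in1) else
            c(x2, in1, x1, in1)
          # signature layout: sA eA shared sB eB shared
          add(if (first) "AF" else "AL",
              c(recs[1], recs[2], recs[3], recs[4], recs[5], recs[6]))
        }
      }
    }
    # RI: exon of T1 spanning a junction of T2 with matching outer bounds
    if (nrow(j2) > 0) for (s in seq_len(k1)) {
      for (b in seq_len(nrow(j2))) {
        c1 <- e2[b, 1]; d <- e2[b, 2]; a <- e2[b + 1, 1]; c2 <- e2[b + 1, 2]
        if (e1[s, 1] == c1 && e1[s, 2] == c2 && c1 < d && d < a && a < c2)
          add("RI", c(c1, d, a, c2))
      }
    }
  }
  sort(unique(out))
}

# package event table -> comparable "type sig" strings
pkg_event_set <- function(ev) sort(unique(paste(ev$type, ev$signature)))

# ---- misc oracles -----------------------------------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# grid/optim MLE for a single-feature NB GLM (log link, offsets)
oracle_nb_mle <- function(y, X, offset, alpha) {
  nll <- function(b) {
    mu <- exp(as.numeric(X %*% b) + offset)
    -sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
  o <- optim(rep(0, ncol(X)), nll, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  o$par
}

# DM grid MLE for K = 2 at fixed theta: best LR over a 0.01 proportion grid
oracle_dm_lr_grid <- function(y, groups, theta) {
  grid <- seq(0.01, 0.99, by = 0.01)
  best <- function(yy) max(vapply(grid, function(p)
    isoformshift::dm_loglik(yy, c(p, 1 - p), theta), numeric(1)))
  ll0 <- best(y)
  ll1 <- sum(vapply(split(seq_len(nrow(y)), groups), function(ii)
    best(y[ii, , drop = FALSE]), numeric(1)))
  2 * (ll1 - ll0)
}

# ---- random fixtures --------------------------------------------------------

# small random gene: n_tx isoforms over a shared exon pool
random_gene_tx <- function(gene, chrom, strand, origin, n_tx,
                           n_exons = NULL) {
  n_exons <- n_exons %||% sample(3:6, 1)
  len <- sample(80:200, n_exons, replace = TRUE)
  gap <- sample(150:700, n_exons, replace = TRUE)
  start <- origin + cumsum(gap) + cumsum(c(0, len[-n_exons]))
  pool <- cbind(start, start + len)
  txs <- list()
  chains <- character(0)
  guard <- 0
  while (length(txs) < n_tx && guard < 60) {
    guard <- guard + 1
    keep <- sort(unique(c(1, n_exons,
                          which(runif(n_exons) < 0.75))))
    ex <- pool[keep, , drop = FALSE]
    # occasional splice-site variant
    if (nrow(ex) >= 2 && runif(1) < 0.4) {
      i <- sample.int(nrow(ex) - 1, 1)
      ex[i, 2] <- ex[i, 2] - sample(20:50, 1)
    }
    key <- paste(ex, collapse = ",")
    if (key %in% chains) next
    chains <- c(chains, key)
    txs[[length(txs) + 1]] <- transcript_model(
      sprintf("%s.t%d", gene, length(txs) + 1), gene, chrom, strand, ex)
  }
  txs
}

# random locus with a handful of genes; returns list(refs, ann)
random_locus <- function(n_genes = 3, chrom = "chrT") {
  origin <- 1000
  refs <- list()
  for (g in seq_len(n_genes)) {
    strand <- sample(c("+", "-"), 1)
    txs <- random_gene_tx(sprintf("rg%d", g), chrom, strand, origin,
                          sample(1:3, 1))
    refs <- c(refs, txs)
    origin <- max(unlist(lapply(txs, function(t) t$exons))) +
      sample(3000:6000, 1)
  }
  list(refs = refs, ann = build_annotation(refs))
}

# random query transcript around a locus: mixtures of copies, edits and
# off-locus fragments
random_query <- function(refs) {
  mode <- sample(c("copy", "edit", "mono", "far", "flip"), 1,
                 prob = c(0.25, 0.35, 0.2, 0.1, 0.1))
  r <- refs[[sample.int(length(refs), 1)]]
  ex <- r$exons
  strand <- r$strand
  if (mode == "edit" && nrow(ex) >= 2) {
    op <- sample(c("drop", "shift", "merge"), 1)
    if (op == "drop" && nrow(ex) >= 3) {
      ex <- ex[-sample.int(nrow(ex), 1), , drop = FALSE]
    } else if (op == "shift") {
      i <- sample.int(nrow(ex) - 1, 1)
      d <- sample(c(-9, -6, 6, 9, 40), 1)
      cand <- ex[i, 2] + d
      if (cand > ex[i, 1] + 10 && cand < ex[i + 1, 1] - 10) ex[i, 2] <- cand
    } else if (op == "merge" && nrow(ex) >= 2) {
      i <- sample.int(nrow(ex) - 1, 1)
      ex[i, 2] <- ex[i + 1, 2]
      ex <- ex[-(i + 1), , drop = FALSE]
    }
  } else if (mode == "mono") {
    base <- ex[sample.int(nrow(ex), 1), ]
    kind <- sample(c("inside", "straddle", "intronish"), 1)
    if (kind == "inside") {
      ex <- matrix(c(base[1] + 5, max(base[1] + 25, base[2] - 5)), 1)
    } else if (kind == "straddle") {
      ex <- matrix(c(max(0, base[1] - 70), base[1] + 30), 1)
    } else {
      ex <- matrix(c(base[2] + 40, base[2] + 140), 1)
    }
  } else if (mode == "far") {
    off <- max(unlist(lapply(refs, function(t) t$exons))) + 5000
    ex <- matrix(c(off, off + 300), 1)
  } else if (mode == "flip") {
    strand <- if (strand == "+") "-" else "+"
  }
  transcript_model("q", "q", r$chrom, strand, ex)
}
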