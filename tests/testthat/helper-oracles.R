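# independent oracles used by unit and acceptance tests

# hypergeometric upper tail by direct summation of log-binomial terms
oracleHyperSF <- function(k, N, K, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- k:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# hand-applied Benjamini-Hochberg step-up definition
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    adj[o[r]] <- val
    prev <- val
  }
  adj
}

# per-base bitmap overlap oracle on a single small sequence
oracleOverlapFraction <- function(query, subject, seqlen) {
  mask <- logical(seqlen)
  for (i in seq_along(subject)) {
    mask[GenomicRanges::start(subject)[i]:GenomicRanges::end(subject)[i]] <-
      TRUE
  }
  hit <- vapply(seq_along(query), function(i)
    any(mask[GenomicRanges::start(query)[i]:GenomicRanges::end(query)[i]]),
    logical(1))
  list(n_overlapping = sum(hit), n_total = length(query),
       fraction = if (length(query)) sum(hit) / length(query) else NA_real_)
}

# ---- brute-force inverted-repeat oracle -------------------------------
# Enumerates every anti-diagonal of the sequence-vs-reverse-complement
# comparison, extracts exact-match runs by splitting the matching
# positions on gaps, chains runs across single mismatches flanked by >= 4
# matches, and keeps the chain-level candidates. Parameter filtering is a
# separate step so one chain enumeration serves several threshold settings.
oracleIRChains <- function(seq) {
  n <- nchar(seq)
  sv <- strsplit(seq, "")[[1]]
  cc <- strsplit(chartr("ACGTN", "TGCA?", seq), "")[[1]]
  res <- list()
  for (cdiag in 3:(2L * n - 1L)) {
    pmin_ <- max(1L, cdiag - n)
    pmax_ <- (cdiag - 1L) %/% 2L
    if (pmax_ < pmin_) next
    pidx <- pmin_:pmax_
    m <- sv[pidx] == cc[cdiag - pidx]
    mp <- pidx[m]
    if (length(mp) == 0L) next
    # split matching positions into exact runs on gaps
    gaps <- which(diff(mp) > 1L)
    rstart <- mp[c(1L, gaps + 1L)]
    rend <- mp[c(gaps, length(mp))]
    rlen <- rend - rstart + 1L
    # no run can seed a reportable chain on this diagonal
    if (max(rlen) < 12L) next
    # chain runs over single-mismatch gaps with >= 4 matches on each side
    k <- 1L
    while (k <= length(rstart)) {
      j <- k
      while (j < length(rstart) &&
             rstart[j + 1L] - rend[j] == 2L &&
             rlen[j] >= 4L && rlen[j + 1L] >= 4L) j <- j + 1L
      res[[length(res) + 1L]] <- data.frame(
        c = cdiag, p1 = rstart[k], p2 = rend[j],
        n_matches = sum(rlen[k:j]), max_run = max(rlen[k:j]))
      k <- j + 1L
    }
  }
  if (length(res) == 0L)
    return(data.frame(c = integer(), p1 = integer(), p2 = integer(),
                      n_matches = integer(), max_run = integer()))
  do.call(rbind, res)
}

oracleIRFilter <- function(chains, min_arm, max_loop, min_identity,
                           seed_len = 12L, min_loop = 3L) {
  if (nrow(chains) == 0L)
    return(data.frame(arm_a_start = integer(), arm_a_end = integer(),
                      arm_b_start = integer(), arm_b_end = integer()))
  L <- chains$p2 - chains$p1 + 1L
  loop <- chains$c - 2L * chains$p2 - 1L
  ident <- chains$n_matches / L
  keep <- chains$max_run >= seed_len & L >= min_arm &
    ident >= min_identity & loop >= min_loop & loop <= max_loop
  out <- data.frame(arm_a_start = chains$p1[keep],
                    arm_a_end = chains$p2[keep],
                    arm_b_start = chains$c[keep] - chains$p2[keep],
                    arm_b_end = chains$c[keep] - chains$p1[keep])
  out <- unique(out)
  out[order(out$arm_a_start, out$arm_b_start), , drop = FALSE]
}

# plant an inverted repeat (optionally with arm mismatches) into a random
# host sequence; returns the sequence
plantIR <- function(host, arm_len, loop_len, at, n_mismatch = 0L) {
  arm <- randDNA(arm_len)
  armb <- dsRNAtools::revComp(arm)
  if (n_mismatch > 0L) {
    v <- strsplit(armb, "")[[1]]
    # mismatches away from the ends so flanks stay >= 4
    posns <- seq(6L, arm_len - 6L, length.out = n_mismatch)
    for (p in round(posns)) {
      v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    }
    armb <- paste(v, collapse = "")
  }
  paste0(substr(host, 1, at - 1), arm, randDNA(loop_len), armb,
         substr(host, at + 2 * arm_len + loop_len, nchar(host)))
}
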