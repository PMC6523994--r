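# Independent oracles, coded from the rules directly, never calling the
# implementation they check.

# all-pairs transitive-closure clustering of positions on one strand
oracleCluster <- function(pos, gap) {
  n <- length(pos)
  if (!n) return(list())
  adj <- abs(outer(pos, pos, "-")) <= gap
  comp <- rep(0L, n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  unname(lapply(split(pos, comp), sort))
}

# literal transcription of the five switching criteria
oracleSwitch <- function(p1a, p1b, p2a, p2b, tot1, tot2, de1, de2,
                         requireDe = TRUE) {
  c1 <- (p1a >= 5 && p1b >= 5) || (p2a >= 5 && p2b >= 5)
  c2 <- (tot1 >= 20) || (tot2 >= 20)
  ge2 <- function(num, den) {
    if (den > 0) num / den >= 2 else num > 0   # x/0 = Inf, 0/0 fails
  }
  c3 <- (ge2(p1a, p2a) && ge2(p2b, p1b)) || (ge2(p1b, p2b) && ge2(p2a, p1a))
  c4 <- (abs(p1a - p2a) > 5) && (abs(p1b - p2b) > 5)
  c5 <- if (requireDe) (de1 || de2) else TRUE
  c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
    verdict = c1 && c2 && c3 && c4 && c5)
}

# FASTX-style per-read quality rule, re-evaluated literally
oracleQualityKeep <- function(qualInts, q = 10, p = 50) {
  100 * sum(qualInts >= q) / length(qualInts) >= p
}

# BH step-up, coded literally
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
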