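# shared fixtures and independent oracles

tinyGenome <- function(lengths = c(chr1 = 1e6, chr2 = 1e6), gaps = NULL,
                       segdups = NULL) {
  GenomeModel(lengths, gaps = gaps, segdups = segdups)
}

adjDf <- function(chrom1, pos1, side1, chrom2, pos2, side2, ...) {
  data.frame(chrom1 = chrom1, pos1 = pos1, side1 = side1,
             chrom2 = chrom2, pos2 = pos2, side2 = side2, ...)
}

# symmetric random contact matrix plus its dense form
randomContactMatrix <- function(n = 12, binSize = 25000, density = 0.5) {
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  keep <- stats::runif(nrow(ij)) < density
  ent <- data.frame(i = ij[keep, 1] - 1L, j = ij[keep, 2] - 1L,
                    count = round(stats::runif(sum(keep), 0, 20), 3))
  ContactMatrix(data.frame(name = "c1", length = n * binSize), binSize, ent)
}

# dense double-loop implementation of the four-corner subscore (independent
# oracle: literal translation of the definition)
bruteSubscore <- function(m, s1, e1, s2, e2, w = 5) {
  w1 <- min(w, e1 - s1 + 1); w2 <- min(w, e2 - s2 + 1)
  tot <- 0
  rows <- list(c(s1, s1 + w1 - 1), c(e1 - w1 + 1, e1))
  cols <- list(c(s2, s2 + w2 - 1), c(e2 - w2 + 1, e2))
  for (rr in rows) for (cc in cols)
    for (i in rr[1]:rr[2]) for (j in cc[1]:cc[2])
      tot <- tot + abs(i - j) * m[i, j]
  tot
}

# score-only Gotoh local alignment oracle (match 2, mismatch -1, first gap
# column -1, further columns -0.1)
gotohScore <- function(a, b, match = 2, mismatch = -1, open = -1,
                       ext = -0.1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0 || m == 0) return(0)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1); E <- matrix(NEG, n + 1, m + 1)
  Fm <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] + open, E[i, j - 1] + ext)
    Fm[i, j] <- max(H[i - 1, j] + open, Fm[i - 1, j] + ext)
    s <- if (av[i - 1] == bv[j - 1]) match else mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], Fm[i, j])
    best <- max(best, H[i, j])
  }
  best
}

layoutKey <- function(ly) {
  paste(ly$fragments$fragment, ly$fragments$orientation, collapse = ";")
}

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
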