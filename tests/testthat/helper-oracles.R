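# independent oracles: brute-force implementations kept deliberately separate
# from the package's code paths

# per-base depth array; its mean is the fold-coverage of the scaffold
oracle_depth_mean <- function(alignments, scaffold_id, scaffold_length) {
  depth <- integer(scaffold_length)
  rows <- which(alignments$scaffold_id == scaffold_id)
  for (i in rows) {
    s <- alignments$position[i] + 1L
    e <- s + alignments$aligned_length[i] - 1L
    depth[s:e] <- depth[s:e] + 1L
  }
  mean(depth)
}

# Gotoh global alignment with affine gaps (open 11, extend 1; a gap of
# length L costs 11 + L) and BLOSUM62 scoring, with traceback; identity is
# matches over alignment columns excluding terminal gaps
oracle_nw_identity <- function(a, b, go = 11, ge = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sm <- BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  tM <- tX <- tY <- matrix(0L, n + 1, m + 1)  # 1=M, 2=X(gap in b), 3=Y(gap in a)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    X[i, 1] <- -go - ge * (i - 1)
    tX[i, 1] <- 2L
  }
  for (j in 2:(m + 1)) {
    Y[1, j] <- -go - ge * (j - 1)
    tY[1, j] <- 3L
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sm[av[i - 1], bv[j - 1]]
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- cand[k] + s
      tM[i, j] <- k
      cand <- c(M[i - 1, j] - go - ge, X[i - 1, j] - ge, Y[i - 1, j] - go - ge)
      k <- which.max(cand)
      X[i, j] <- cand[k]
      tX[i, j] <- k
      cand <- c(M[i, j - 1] - go - ge, X[i, j - 1] - go - ge, Y[i, j - 1] - ge)
      k <- which.max(cand)
      Y[i, j] <- cand[k]
      tY[i, j] <- k
    }
  }
  finals <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(finals)
  score <- finals[state]
  # traceback
  i <- n + 1; j <- m + 1
  pa <- character(); pb <- character()
  while (i > 1 || j > 1) {
    if (state == 1L) {
      prev <- tM[i, j]
      pa <- c(av[i - 1], pa); pb <- c(bv[j - 1], pb)
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      prev <- tX[i, j]
      pa <- c(av[i - 1], pa); pb <- c("-", pb)
      i <- i - 1
    } else {
      prev <- tY[i, j]
      pa <- c("-", pa); pb <- c(bv[j - 1], pb)
      j <- j - 1
    }
    state <- prev
  }
  gap <- pa == "-" | pb == "-"
  nong <- which(!gap)
  span <- nong[1]:nong[length(nong)]
  list(score = score,
       identity = 100 * sum(pa[span] == pb[span] & pa[span] != "-") /
         length(span))
}

# brute-force AAI: all-pairs oracle alignments, mutual best hits by score,
# identity/coverage floors, unweighted mean identity
oracle_aai <- function(pa, pb, min_identity = 30, min_rbh = 1) {
  na <- nrow(pa); nb <- nrow(pb)
  score <- matrix(NA_real_, na, nb)
  ident <- matrix(NA_real_, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      r <- oracle_nw_identity(pa$seq[i], pb$seq[j])
      score[i, j] <- r$score
      ident[i, j] <- r$identity
    }
  }
  best_b <- apply(score, 1, which.max)
  best_a <- apply(score, 2, which.max)
  mutual <- which(best_a[best_b] == seq_len(na))
  ids <- ident[cbind(mutual, best_b[mutual])]
  ids <- ids[ids >= min_identity]
  if (length(ids) < min_rbh) return(NA_real_)
  mean(ids)
}

# mean silhouette width for labelled points in a feature matrix
oracle_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force marker tally
oracle_marker_tally <- function(families_observed, marker_set) {
  present <- 0; extra <- 0
  for (f in marker_set) {
    k <- sum(families_observed == f)
    if (k >= 1) present <- present + 1
    if (k > 1) extra <- extra + (k - 1)
  }
  c(completeness = 100 * present / length(marker_set),
    contamination = 100 * extra / length(marker_set))
}
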