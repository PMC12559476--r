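# Independent quadratic dynamic-programming alignment oracles (Gotoh
# affine-gap), used to cross-check the package's alignment-backed
# identity computations. Pure R, deliberately naive.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# global (Needleman-Wunsch) score + identity of one optimal alignment
oracleGlobal <- function(a, b, open = 10, ext = 1) {
  S <- .blosum62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[A[i - 1], B[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
  }
  fin <- c(M = M[n + 1, m + 1], Ix = Ix[n + 1, m + 1], Iy = Iy[n + 1, m + 1])
  state <- names(which.max(fin))
  i <- n + 1; j <- m + 1
  matches <- 0; alen <- 0
  while (i > 1 || j > 1) {
    alen <- alen + 1
    if (state == "M") {
      s <- S[A[i - 1], B[j - 1]]
      if (A[i - 1] == B[j - 1]) matches <- matches + 1
      target <- M[i, j] - s
      prev <- c(M = M[i - 1, j - 1], Ix = Ix[i - 1, j - 1],
                Iy = Iy[i - 1, j - 1])
      state <- names(prev)[which(abs(prev - target) < 1e-6)][1]
      i <- i - 1; j <- j - 1
    } else if (state == "Ix") {
      state <- if (abs(M[i - 1, j] - open - ext - Ix[i, j]) < 1e-6)
        "M" else "Ix"
      i <- i - 1
    } else {
      state <- if (abs(M[i, j - 1] - open - ext - Iy[i, j]) < 1e-6)
        "M" else "Iy"
      j <- j - 1
    }
  }
  list(score = unname(max(fin)), identity = matches / alen)
}

# local (Smith-Waterman) best score + identity of the best local
# alignment, BLAST-default gapping
oracleLocal <- function(a, b, open = 11, ext = 1) {
  S <- .blosum62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-1e9, n + 1, m + 1)
  Iy <- matrix(-1e9, n + 1, m + 1)
  best <- 0; bi <- 1; bj <- 1
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[A[i - 1], B[j - 1]]
    M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                   Iy[i - 1, j - 1] + s)
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    if (M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j }
  }
  ## traceback from the best cell through M until the local start
  i <- bi; j <- bj; state <- "M"
  matches <- 0; alen <- 0
  while (TRUE) {
    if (state == "M") {
      if (M[i, j] <= 0) break
      s <- S[A[i - 1], B[j - 1]]
      alen <- alen + 1
      if (A[i - 1] == B[j - 1]) matches <- matches + 1
      target <- M[i, j] - s
      if (target < 1e-6) break  # alignment starts at this column
      prev <- c(M = M[i - 1, j - 1], Ix = Ix[i - 1, j - 1],
                Iy = Iy[i - 1, j - 1])
      state <- names(prev)[which(abs(prev - target) < 1e-6)][1]
      i <- i - 1; j <- j - 1
    } else if (state == "Ix") {
      alen <- alen + 1
      state <- if (abs(M[i - 1, j] - open - ext - Ix[i, j]) < 1e-6)
        "M" else "Ix"
      i <- i - 1
    } else {
      alen <- alen + 1
      state <- if (abs(M[i, j - 1] - open - ext - Iy[i, j]) < 1e-6)
        "M" else "Iy"
      j <- j - 1
    }
  }
  list(score = best, identity = if (alen > 0) matches / alen else 0)
}
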