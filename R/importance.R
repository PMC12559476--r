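## Descriptive model: rank reference-numbered alignment positions by
## their association with substrate-specific activity. Method: one-hot
## encoded alignment columns, a random-forest classifier, and grouped
## permutation importance (all dummies of a position permuted jointly)
## measured on out-of-bootstrap rows and averaged over bootstrap
## replicates. This is the toolkit's declared interpretation of a
## descriptive residue-importance model; it is configurable and makes no
## mechanistic claim.

.onehotColumns <- function(residues) {
  ## residues: character matrix, sequences x positions
  blocks <- lapply(colnames(residues), function(p) {
    lv <- sort(unique(residues[, p]))
    m <- outer(residues[, p], lv, "==") * 1L
    colnames(m) <- paste0("p", p, ".", lv)
    m
  })
  X <- do.call(cbind, blocks)
  rownames(X) <- rownames(residues)
  groups <- rep(colnames(residues), times = vapply(blocks, ncol, integer(1)))
  list(X = X, groups = groups)
}

#' Rank alignment positions by activity association
#'
#' Fits a classifier on one-hot encoded residues at the profile's
#' reference positions and scores every position by grouped permutation
#' importance: the drop in out-of-bootstrap accuracy when the position's
#' residue identities are permuted across sequences, averaged over
#' `nBoot` bootstrap replicates. Positions that are constant across all
#' enzymes cannot change predictions and score exactly 0.
#'
#' @param profile an [ActiveSiteProfile-class] covering the enzymes (its
#'   columns are the candidate positions).
#' @param dataset a [PairDataset-class] of activity labels.
#' @param substrate optional substrate id: restrict to that substrate's
#'   labels; default pools all pairs.
#' @param nBoot bootstrap replicates (default 20).
#' @param numTrees random-forest size per replicate (default 200).
#' @param seed integer seed; results are deterministic given it.
#' @return a `data.frame` with columns `ref_position`, `score` (mean
#'   importance clamped at 0), `raw_score` (signed mean), `rank`
#'   (1 = most important), and `stability` (fraction of replicates in
#'   which the position lands in the top decile).
#' @export
rankPositions <- function(profile, dataset, substrate = NULL, nBoot = 20L,
                          numTrees = 200L, seed = 1L) {
  stopifnot(is(profile, "ActiveSiteProfile"), is(dataset, "PairDataset"))
  p <- dataset@pairs
  if (!is.null(substrate)) p <- p[p$substrate_id == substrate, , drop = FALSE]
  if (nrow(p) == 0L) stop("no pairs for the requested substrate")
  missing <- setdiff(unique(p$enzyme_id), rownames(profile@residues))
  if (length(missing))
    stop("profile lacks enzyme(s): ", paste(missing, collapse = ", "))
  y <- p$label
  if (length(unique(y)) < 2L)
    stop("no signal to attribute: all labels are equal")
  res <- profile@residues[p$enzyme_id, , drop = FALSE]
  oh <- .onehotColumns(res)
  X <- oh$X
  positions <- colnames(profile@residues)
  top_k <- max(1L, ceiling(length(positions) / 10))

  imp <- matrix(0, nrow = nBoot, ncol = length(positions),
                dimnames = list(NULL, positions))
  in_top <- matrix(FALSE, nrow = nBoot, ncol = length(positions),
                   dimnames = list(NULL, positions))
  n <- nrow(X)
  for (b in seq_len(nBoot)) {
    .withSeed(.mixSeed(seed, b), {
      bag <- sample(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(bag))
      if (length(oob) >= 2L && length(unique(y[bag])) == 2L) {
        fit <- ranger::ranger(x = as.data.frame(X[bag, , drop = FALSE]),
                              y = factor(y[bag], levels = c(0, 1)),
                              num.trees = numTrees,
                              seed = .mixSeed(seed, b, 1L),
                              num.threads = 1L)
        base_pred <- stats::predict(fit, data = as.data.frame(
          X[oob, , drop = FALSE]), num.threads = 1L)$predictions
        base_acc <- mean(base_pred == factor(y[oob], levels = c(0, 1)))
        for (j in seq_along(positions)) {
          cols <- which(oh$groups == positions[j])
          if (length(unique(res[, j])) < 2L) next  # constant: no signal
          Xp <- X[oob, , drop = FALSE]
          perm <- sample(length(oob))
          Xp[, cols] <- Xp[perm, cols, drop = FALSE]
          pp <- stats::predict(fit, data = as.data.frame(Xp),
                               num.threads = 1L)$predictions
          imp[b, j] <- base_acc -
            mean(pp == factor(y[oob], levels = c(0, 1)))
        }
        in_top[b, order(-imp[b, ])[seq_len(top_k)]] <- TRUE
      }
    })
  }
  raw <- colMeans(imp)
  out <- data.frame(ref_position = as.integer(positions),
                    score = pmax(raw, 0), raw_score = raw,
                    stability = colMeans(in_top))
  out$rank <- as.integer(rank(-out$score, ties.method = "first"))
  out <- out[order(out$rank), c("ref_position", "score", "raw_score",
                                "rank", "stability")]
  rownames(out) <- NULL
  out
}

#' Write a position-importance table
#'
#' @param importance the `data.frame` from [rankPositions()].
#' @param path output TSV path.
#' @export
writeImportance <- function(importance, path) {
  out <- importance
  out$score <- sprintf("%.6f", out$score)
  out$raw_score <- sprintf("%.6f", out$raw_score)
  out$stability <- sprintf("%.3f", out$stability)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
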