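## Substrate fingerprints. MACCS substructure keys are computed through
## OpenBabel (ChemmineOB); the circular Morgan/ECFP fingerprint is
## implemented here: no installed R package provides it, and the
## algorithm below is the standard iterative neighbourhood-hashing
## construction, order-invariant by design.

.parseSmiles <- function(smiles, substrate_id = smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e)
      stop("unparsable structure for substrate '", substrate_id, "': ",
           conditionMessage(e), call. = FALSE))
  sdf[[1]]
}

## deterministic integer hashing of an integer vector (31-bit polynomial)
.hashInts <- function(v) {
  h <- 17
  for (x in v) h <- (h * 1000003 + (x %% 2147483647)) %% 2147483647
  as.integer(h)
}

.hashString <- function(s) .hashInts(utf8ToInt(s))

## connection table with aromatic-ring perception; bond order 4 denotes
## an aromatic bond so that different kekulisations hash identically
.connectionTable <- function(mol) {
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    data.frame(a = integer(), b = integer(), order = integer())
  } else {
    data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  ring <- tryCatch(ChemmineR::rings(mol, type = "all", arom = TRUE),
                   error = function(e) list(RINGS = list(),
                                            AROMATIC = logical()))
  arom_atoms <- character()
  if (length(ring$RINGS)) {
    arom_rings <- ring$RINGS[which(ring$AROMATIC)]
    for (rg in arom_rings) {
      idx <- as.integer(sub("^.*_", "", rg))
      for (k in seq_len(nrow(bonds))) {
        if (bonds$a[k] %in% idx && bonds$b[k] %in% idx)
          bonds$order[k] <- 4L
      }
      arom_atoms <- union(arom_atoms, rg)
    }
  }
  arom_flag <- rownames(ab) %in% arom_atoms
  list(elements = elements, bonds = bonds, aromatic = arom_flag, n = n)
}

## Morgan / extended-connectivity fingerprint over the connection table
.ecfpBits <- function(ct, radius, nBits) {
  n <- ct$n
  ## neighbour lists with bond orders
  nbrs <- vector("list", n)
  if (nrow(ct$bonds)) {
    for (k in seq_len(nrow(ct$bonds))) {
      a <- ct$bonds$a[k]; b <- ct$bonds$b[k]; o <- ct$bonds$order[k]
      nbrs[[a]] <- rbind(nbrs[[a]], c(o, b))
      nbrs[[b]] <- rbind(nbrs[[b]], c(o, a))
    }
  }
  degree <- vapply(nbrs, function(x) if (is.null(x)) 0L else nrow(x),
                   integer(1))
  bondsum <- vapply(nbrs, function(x) if (is.null(x)) 0L
                    else as.integer(sum(x[, 1])), integer(1))
  ## round-0 invariant: element, heavy-atom degree, bond-order sum,
  ## aromatic membership
  inv <- vapply(seq_len(n), function(a)
    .hashInts(c(.hashString(ct$elements[a]), degree[a], bondsum[a],
                as.integer(ct$aromatic[a]))), integer(1))
  identifiers <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(a) {
      nb <- nbrs[[a]]
      env <- if (is.null(nb)) integer() else {
        pairs <- cbind(nb[, 1], inv[nb[, 2]])
        ord <- order(pairs[, 1], pairs[, 2])
        as.integer(t(pairs[ord, , drop = FALSE]))
      }
      .hashInts(c(r, inv[a], env))
    }, integer(1))
    identifiers <- c(identifiers, inv)
  }
  bits <- integer(nBits)
  bits[unique(identifiers %% nBits) + 1L] <- 1L
  bits
}

#' Fingerprint a substrate structure
#'
#' Turns a line-notation structure string (SMILES) into a deterministic
#' binary fingerprint. `"maccs"` computes the 167-key MACCS substructure
#' fingerprint (slot 1 is the conventionally unused key 0); `"ecfp"`
#' computes a circular Morgan fingerprint with the given radius folded to
#' `nBits` bits. Both depend only on the molecular graph, so the same
#' molecule written with different atom orderings yields identical bits.
#'
#' @param smiles the structure string.
#' @param type `"maccs"` or `"ecfp"`.
#' @param radius ECFP neighbourhood radius (default 2, i.e. ECFP4-like).
#' @param nBits ECFP bit-vector length (default 2048).
#' @param substrate_id identifier used in error messages.
#' @return an integer 0/1 vector with attributes `fingerprint_type` and
#'   `params`.
#' @examples
#' fp <- fingerprintSubstrate("c1ccccc1C(=O)O", type = "maccs")
#' length(fp)  # 167
#' @export
fingerprintSubstrate <- function(smiles, type = c("maccs", "ecfp"),
                                 radius = 2L, nBits = 2048L,
                                 substrate_id = smiles) {
  type <- match.arg(type)
  if (type == "maccs") {
    mol <- tryCatch(
      ChemmineOB::forEachMol("SMILES", smiles, identity),
      error = function(e)
        stop("unparsable structure for substrate '", substrate_id, "'",
             call. = FALSE))
    raw <- ChemmineOB::fingerprint_OB(mol, "MACCS")
    bits <- as.integer(c(0L, raw[1:166]))
    attr(bits, "fingerprint_type") <- "maccs"
    attr(bits, "params") <- list(n_keys = 167L)
    return(bits)
  }
  mol <- .parseSmiles(smiles, substrate_id)
  bits <- .ecfpBits(.connectionTable(mol), radius = as.integer(radius),
                    nBits = as.integer(nBits))
  attr(bits, "fingerprint_type") <- "ecfp"
  attr(bits, "params") <- list(radius = as.integer(radius),
                               n_bits = as.integer(nBits))
  bits
}

#' Fingerprint a substrate table
#'
#' @param substrates a `data.frame` from [readSubstrateTable()] (columns
#'   `substrate_id`, `smiles`).
#' @inheritParams fingerprintSubstrate
#' @return an integer 0/1 matrix, one row per substrate (rownames the
#'   ids), with attribute `fingerprint_type`.
#' @export
featurizeSubstrates <- function(substrates, type = c("maccs", "ecfp"),
                                radius = 2L, nBits = 2048L) {
  type <- match.arg(type)
  rows <- lapply(seq_len(nrow(substrates)), function(i)
    as.integer(fingerprintSubstrate(substrates$smiles[i], type = type,
                                    radius = radius, nBits = nBits,
                                    substrate_id = substrates$substrate_id[i])))
  m <- do.call(rbind, rows)
  rownames(m) <- substrates$substrate_id
  attr(m, "fingerprint_type") <- type
  m
}

#' Tanimoto similarity of two binary fingerprints
#'
#' @param a,b equal-length 0/1 vectors.
#' @return `|a & b| / |a | b|` (1 when both are all-zero).
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
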